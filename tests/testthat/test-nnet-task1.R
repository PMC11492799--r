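test_that("the architecture grid enumerates the full Cartesian product", {
  grid <- enumerate_grid()
  expect_length(grid, 243L)
  key <- vapply(grid, function(cfg) paste(cfg$cnn1_filters, cfg$cnn2_filters,
                                          cfg$cnn_dense_units,
                                          cfg$bilstm_units,
                                          cfg$bilstm_dense_units),
                character(1))
  expect_false(anyDuplicated(key) > 0)
  expect_true("64 32 32 32 8" %in% key)
})

test_that("disabling both convolution branches is a configuration error", {
  expect_error(task1_config(use_cnn1 = FALSE, use_cnn2 = FALSE),
               "at least one")
})

test_that("an untrained network emits probabilities in [0, 1]", {
  cfg <- tiny_config()
  evo <- random_evo(c(10L, 20L, 32L), n_max = 32L, seed = 1L)
  mm <- matrix(rnorm(3 * 27), 3, 27)
  fit <- llps_net(evo, mm, c(1, 0, 1), config = cfg)
  p <- predict(fit, evo, mm)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, 3L)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_config()
  evo <- random_evo(c(6L, 9L, 12L), n_max = 12L, seed = 2L)
  mm <- matrix(rnorm(3 * 27), 3, 27)
  y <- c(1, 0, 1)
  rng <- phasekit:::local_rng(5L)
  params <- phasekit:::init_params(cfg, rng)
  batch <- phasekit:::stack_evo(evo)
  loss_at <- function(p) {
    phasekit:::bce_loss(phasekit:::task1_forward(p, cfg, batch, mm)$prob, y)
  }
  fw <- phasekit:::task1_forward(params, cfg, batch, mm, keep_cache = TRUE)
  gr <- phasekit:::task1_backward(params, cfg, batch, mm, y, fw)
  eps <- 1e-6
  set.seed(6)
  for (nm in names(gr)) {
    idx <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
    for (ii in idx) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- gr[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("attention gates are per-channel values in [0, 1]", {
  cfg <- tiny_config()
  evo <- random_evo(c(8L, 16L), n_max = 16L, seed = 3L)
  mm <- matrix(rnorm(2 * 27), 2, 27)
  fit <- llps_net(evo, mm, c(1, 0), config = cfg)
  g <- attention_gates(fit, evo, mm)
  expect_equal(dim(g), c(2L, 7L))  # 4 + 3 channels
  expect_true(all(g >= 0 & g <= 1))
})

test_that("prediction is invariant to padding beyond the true length", {
  cfg <- tiny_config()
  evo32 <- random_evo(c(10L, 14L), n_max = 32L, seed = 4L)
  mm <- matrix(rnorm(2 * 27), 2, 27)
  fit <- llps_net(evo32, mm, c(1, 0), config = cfg)
  # same content, twice the zero padding
  evo64 <- lapply(evo32, function(e) {
    v <- matrix(0, 64L, 40L)
    v[seq_len(e$true_length), ] <- e$values[seq_len(e$true_length), ]
    structure(list(values = v, true_length = e$true_length,
                   seq_id = e$seq_id), class = "evo_tensor")
  })
  expect_equal(predict(fit, evo32, mm), predict(fit, evo64, mm),
               tolerance = 1e-12)
})

test_that("all ablation variants build, train and emit valid probabilities", {
  evo <- random_evo(rep(c(8L, 12L), 5L), n_max = 16L, seed = 5L)
  mm <- matrix(rnorm(10 * 27), 10, 27)
  y <- rep(c(1, 0), 5)
  variants <- list(
    full = tiny_config(epochs = 2L),
    no_cnn1 = tiny_config(use_cnn1 = FALSE, epochs = 2L),
    no_cnn2 = tiny_config(use_cnn2 = FALSE, epochs = 2L),
    no_attention = tiny_config(use_attention = FALSE, epochs = 2L)
  )
  for (nm in names(variants)) {
    fit <- llps_net(evo, mm, y, config = variants[[nm]])
    p <- predict(fit, evo, mm)
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), label = nm)
    expect_gte(nrow(fit$history), 1L)
  }
})

test_that("training is deterministic given the seed", {
  evo <- random_evo(rep(c(8L, 12L), 4L), n_max = 16L, seed = 6L)
  mm <- matrix(rnorm(8 * 27), 8, 27)
  y <- rep(c(1, 0), 4)
  cfg <- tiny_config(epochs = 3L, seed = 21L)
  f1 <- llps_net(evo, mm, y, config = cfg)
  f2 <- llps_net(evo, mm, y, config = cfg)
  expect_equal(f1$params, f2$params)
  expect_equal(f1$history, f2$history)
})

test_that("training loss decreases on trivially separable data", {
  set.seed(7)
  n <- 24L
  y <- rep(c(1, 0), n / 2)
  evo <- random_evo(rep(12L, n), n_max = 16L, seed = 7L)
  # inject a strong channel-mean signal
  for (i in seq_len(n)) {
    evo[[i]]$values[1:12, 1:5] <- evo[[i]]$values[1:12, 1:5] + 3 * y[i]
  }
  mm <- matrix(rnorm(n * 27), n, 27) + 2 * y
  cfg <- tiny_config(epochs = 6L, patience = NULL, seed = 3L,
                     learning_rate = 5e-3)
  fit <- llps_net(evo, mm, y, config = cfg)
  h <- fit$history$train_loss
  expect_lt(tail(h, 1), h[1])
})

test_that("restricted grid search ranks configurations with the full metric panel", {
  set.seed(8)
  n <- 24L
  y <- rep(c(1, 0), n / 2)
  evo <- random_evo(rep(10L, n), n_max = 16L, seed = 8L)
  mm <- matrix(rnorm(n * 27), n, 27) + 1.5 * y
  cfgs <- list(tiny_config(epochs = 2L), tiny_config(bilstm_units = 4L, epochs = 2L))
  res <- grid_search_task1(evo, mm, y, configs = cfgs, k = 3L, seed = 2L)
  expect_equal(nrow(res), 2L)
  expect_true(all(c("sn", "sp", "acc", "mcc", "pre", "f1", "auc") %in% names(res)))
  expect_true(all(diff(res$auc) <= 0))
  res2 <- grid_search_task1(evo, mm, y, configs = cfgs, k = 3L, seed = 2L)
  expect_equal(res, res2)
})
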