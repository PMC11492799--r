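# Smaller-scale unit checks of the selection stages; the full planted-signal
# pipeline at study scale runs in the acceptance suite.

make_planted <- function(n = 200L, effect = 1.5, seed = 11L,
                         n_informative = 10L, n_noise = 40L) {
  labels <- rep(c(1L, 0L), each = n / 2)
  gen_feature_table(labels, n_informative = n_informative,
                    n_noise = n_noise, effect = effect, seed = seed)
}

test_that("baseline evaluation scores each family with its dimension", {
  ft <- make_planted(n = 120L, n_noise = 10L)
  tables <- list(fam_a = ft$x[, 1:10], fam_b = ft$x[, 11:20],
                 fam_ab = ft$x)
  res <- baseline_eval(tables, ft$labels, k = 5L, seed = 2L)
  expect_equal(nrow(res), 3L)
  expect_equal(res$dimension, c(10L, 10L, 20L))
  res2 <- baseline_eval(tables, ft$labels, k = 5L, seed = 2L)
  expect_equal(res, res2)
  # duplicated family gives identical rows under the shared fold seed
  res3 <- baseline_eval(list(a = ft$x, b = ft$x), ft$labels, k = 5L, seed = 2L)
  expect_equal(res3[1, -1], res3[2, -1], ignore_attr = TRUE)
  misaligned <- tables
  rownames(misaligned$fam_b) <- rev(rownames(misaligned$fam_b))
  expect_error(baseline_eval(misaligned, ft$labels, k = 5L, seed = 2L),
               "aligned")
})

test_that("recursive elimination recovers planted features and honors targets", {
  ft <- make_planted()
  res <- rfe_stage(ft$x, ft$labels, target_dims = c(40L, 20L, 10L),
                   k = 5L, seed = 11L)
  expect_gte(sum(res$per_dim[["10"]] %in% ft$informative), 8L)
  expect_length(res$per_dim[["20"]], 20L)
  # nestedness of the elimination path
  expect_true(all(res$per_dim[["10"]] %in% res$per_dim[["20"]]))
  # target equal to the full dimension is the identity selection
  res_id <- rfe_stage(ft$x, ft$labels, target_dims = ncol(ft$x),
                      k = 5L, seed = 11L)
  expect_setequal(res_id$selected, colnames(ft$x))
})

test_that("constant features are eliminated first and reported", {
  ft <- make_planted(n = 120L, n_noise = 10L)
  x <- cbind(ft$x, DEAD_001 = rep(1, nrow(ft$x)))
  res <- rfe_stage(x, ft$labels, target_dims = 10L, k = 5L, seed = 3L)
  expect_identical(res$constant_dropped, "DEAD_001")
  expect_false("DEAD_001" %in% res$selected)
})

test_that("split-count importances are integers summing to the total split count", {
  ft <- make_planted(n = 120L)
  fit <- phasekit:::fit_xgb(ft$x, ft$labels)
  imp <- split_count_importance(fit, colnames(ft$x))
  expect_true(all(imp >= 0))
  tree <- xgboost::xgb.model.dt.tree(model = fit)
  expect_equal(sum(imp), sum(tree$Feature != "Leaf"))
})

test_that("importance sweep evaluates nested subsets on a fixed-step curve", {
  ft <- make_planted()
  res <- importance_sweep(ft$x, ft$labels, step = 5L, k = 5L, seed = 4L)
  expect_equal(nrow(res$curve), ceiling(ncol(ft$x) / 5))
  # nestedness: each subset extends the previous
  expect_identical(res$ranking[1:5],
                   res$ranking[seq_len(5)])
  for (i in seq_len(nrow(res$curve) - 1)) {
    a <- res$ranking[seq_len(res$curve$n_features[i])]
    b <- res$ranking[seq_len(res$curve$n_features[i + 1])]
    expect_true(all(a %in% b))
  }
  # planted features dominate the best subset
  expect_gte(sum(ft$informative %in% res$best_features), 8L)
})

test_that("forward selection keeps only strictly improving candidates", {
  ft <- make_planted(n = 160L, n_noise = 20L)
  base <- ft$informative
  # a candidate duplicating a base feature can never strictly improve
  x2 <- cbind(ft$x, DUP_001 = ft$x[, base[1]],
              FRESH_01 = stats::rnorm(nrow(ft$x)) + 2.5 * ft$labels)
  res <- ifs_stage(base, c("DUP_001", "FRESH_01"), x2, ft$labels,
                   k = 5L, seed = 6L)
  expect_false("DUP_001" %in% res$final_features)
  expect_true("FRESH_01" %in% res$final_features)
  # empty candidate list is the identity
  res0 <- ifs_stage(base, character(0), x2, ft$labels, k = 5L, seed = 6L)
  expect_identical(res0$final_features, base)
})

test_that("selection reports have non-increasing dimensions and serialize", {
  ft <- make_planted()
  rep <- select_features(ft$x, ft$labels, target_dims = c(25L, 10L),
                         step = 5L, k = 5L, seed = 8L)
  dims <- vapply(rep$stages, `[[`, numeric(1), "dimension")
  expect_lte(dims[["rfe"]], dims[["baseline"]])
  expect_lte(dims[["importance_sweep"]], dims[["rfe"]])
  expect_gte(dims[["ifs"]], dims[["importance_sweep"]])
  expect_true(all(rep$final_features %in% colnames(ft$x)))
  js <- selection_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$stages$ifs$dimension, dims[["ifs"]])
  # end-to-end determinism
  rep2 <- select_features(ft$x, ft$labels, target_dims = c(25L, 10L),
                          step = 5L, k = 5L, seed = 8L)
  expect_identical(rep$final_features, rep2$final_features)
  expect_equal(rep$stages$ifs$cv_metrics, rep2$stages$ifs$cv_metrics)
})

test_that("the mechanism classifier separates signal, fails null, enforces contract", {
  ft <- make_planted(n = 240L, effect = 2)
  tr <- seq_len(nrow(ft$x)) %% 2 == 0
  fit <- ps_mechanism_xgb(ft$x[tr, ], ft$labels[tr])
  p <- predict(fit, ft$x[!tr, ])
  expect_gte(roc_auc(p, ft$labels[!tr]), 0.9)
  cls <- predict(fit, ft$x[!tr, ], type = "class")
  expect_true(all(cls %in% c("PS-Self", "PS-Part")))
  # permuted labels give chance-level held-out AUC
  rng <- phasekit:::local_rng(13L)
  yp <- ft$labels[rng$sample_perm(length(ft$labels))]
  fitp <- ps_mechanism_xgb(ft$x[tr, ], yp[tr])
  expect_lt(abs(roc_auc(predict(fitp, ft$x[!tr, ]), yp[!tr]) - 0.5), 0.15)
  # feature-name contract
  bad <- ft$x[!tr, -1, drop = FALSE]
  expect_error(predict(fit, bad), "INF_001")
  expect_error(ps_mechanism_xgb(ft$x[tr, ], rep(1, sum(tr))), "single class")
})

test_that("balanced subsampling equalizes class counts deterministically", {
  y <- rep(c(1L, 0L), c(285L, 496L))
  idx <- balance_classes(y, seed = 4L)
  expect_equal(as.integer(table(y[idx])), c(285L, 285L))
  expect_identical(idx, balance_classes(y, seed = 4L))
  expect_false(identical(idx, balance_classes(y, seed = 5L)))
})

test_that("the classifier comparison covers six model families deterministically", {
  ft <- make_planted(n = 100L, n_noise = 10L, effect = 2)
  res <- classifier_zoo(ft$x, ft$labels, k = 3L, seed = 9L)
  expect_equal(nrow(res), 6L)
  expect_true(all(c("sn", "sp", "acc", "mcc", "pre", "f1", "auc") %in%
                    names(res)))
  # strong linear signal: every family should separate well
  expect_true(all(res$auc > 0.9))
  res2 <- classifier_zoo(ft$x, ft$labels, k = 3L, seed = 9L)
  expect_equal(res, res2)
})
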