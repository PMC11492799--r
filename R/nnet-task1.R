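# The LLPS vs non-LLPS classifier: a hybrid network with two parallel
# 1-D convolution branches (kernel widths 3 and 7) over the padded
# evolutionary tensor, squeeze-excitation channel attention on the
# concatenated feature maps, masked global pooling, and a BiLSTM branch
# reading the 27-component multimodal vector as a length-27 scalar
# sequence; branch outputs are concatenated into a dense sigmoid head.
#
# Implemented self-contained in base R: im2col convolutions, BPTT for the
# LSTM, Adam optimization. Gradients are validated against central finite
# differences in the test suite. All pooling statistics are masked to each
# sequence's true length, so predictions are invariant to the amount of
# zero padding.

#' Configuration for the LLPS network
#'
#' The five tunable architecture parameters span the search grid
#' `{16,32,64} x {16,32,64} x {8,16,32} x {16,32,64} x {8,16,32}`
#' (243 combinations); the reference optimum is
#' `(64, 32, 32, 32, 8)`. Training hyperparameters default to Adam with
#' learning rate 1e-3, batch size 32, and early stopping on validation
#' loss with patience 5.
#'
#' @param cnn1_filters,cnn2_filters Filters of the two convolution
#'   branches (kernel widths 3 and 7).
#' @param cnn_dense_units Dense units after the pooled convolution output.
#' @param bilstm_units Hidden units per LSTM direction.
#' @param bilstm_dense_units Dense units after the BiLSTM.
#' @param use_cnn1,use_cnn2,use_attention Ablation switches; at least one
#'   convolution branch must stay enabled.
#' @param se_reduction Squeeze-excitation bottleneck reduction ratio.
#' @param epochs,batch_size,learning_rate,seed Training controls.
#' @param validation_fraction Fraction held out for early stopping
#'   (ignored when `patience` is `NULL`).
#' @param patience Early-stopping patience in epochs; `NULL` disables.
#' @return An object of class `task1_config`.
#' @export
task1_config <- function(cnn1_filters = 64L, cnn2_filters = 32L,
                         cnn_dense_units = 32L, bilstm_units = 32L,
                         bilstm_dense_units = 8L,
                         use_cnn1 = TRUE, use_cnn2 = TRUE,
                         use_attention = TRUE, se_reduction = 4L,
                         epochs = 10L, batch_size = 32L,
                         learning_rate = 1e-3,
                         validation_fraction = 0.15, patience = 5L,
                         seed = 1L) {
  if (!use_cnn1 && !use_cnn2) {
    stop("at least one convolution branch must be enabled", call. = FALSE)
  }
  structure(list(
    cnn1_filters = as.integer(cnn1_filters),
    cnn2_filters = as.integer(cnn2_filters),
    cnn_dense_units = as.integer(cnn_dense_units),
    bilstm_units = as.integer(bilstm_units),
    bilstm_dense_units = as.integer(bilstm_dense_units),
    use_cnn1 = use_cnn1, use_cnn2 = use_cnn2, use_attention = use_attention,
    se_reduction = as.integer(se_reduction),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    validation_fraction = validation_fraction,
    patience = if (is.null(patience)) NULL else as.integer(patience),
    seed = as.integer(seed)
  ), class = "task1_config")
}

#' Enumerate the architecture search grid
#'
#' Full Cartesian product of the five architecture parameter sets, in
#' deterministic order: 3^5 = 243 configurations.
#'
#' @param ... Overrides passed to every [task1_config()] (e.g. `epochs`).
#' @return List of `task1_config` objects.
#' @export
enumerate_grid <- function(...) {
  grid <- expand.grid(
    cnn1_filters = c(16L, 32L, 64L), cnn2_filters = c(16L, 32L, 64L),
    cnn_dense_units = c(8L, 16L, 32L), bilstm_units = c(16L, 32L, 64L),
    bilstm_dense_units = c(8L, 16L, 32L),
    KEEP.OUT.ATTRS = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    task1_config(cnn1_filters = grid$cnn1_filters[i],
                 cnn2_filters = grid$cnn2_filters[i],
                 cnn_dense_units = grid$cnn_dense_units[i],
                 bilstm_units = grid$bilstm_units[i],
                 bilstm_dense_units = grid$bilstm_dense_units[i], ...)
  })
}

# --- parameter initialization --------------------------------------------

glorot <- function(rng, nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(rng$runif(nrow * ncol, -lim, lim), nrow = nrow, ncol = ncol)
}

init_params <- function(config, rng, mm_len = 27L) {
  k1 <- 3L; k2 <- 7L
  F1 <- if (config$use_cnn1) config$cnn1_filters else 0L
  F2 <- if (config$use_cnn2) config$cnn2_filters else 0L
  Fc <- F1 + F2
  Fr <- max(1L, Fc %/% config$se_reduction)
  H <- config$bilstm_units
  Dc <- config$cnn_dense_units; Dl <- config$bilstm_dense_units
  p <- list()
  if (config$use_cnn1) p$Wconv1 <- glorot(rng, k1 * 40L, F1)
  if (config$use_cnn2) p$Wconv2 <- glorot(rng, k2 * 40L, F2)
  if (config$use_attention) {
    p$Wse1 <- glorot(rng, Fc, Fr); p$bse1 <- rep(0, Fr)
    p$Wse2 <- glorot(rng, Fr, Fc); p$bse2 <- rep(0, Fc)
  }
  p$Wcd <- glorot(rng, Fc, Dc); p$bcd <- rep(0, Dc)
  for (dir in c("f", "b")) {
    p[[paste0("Wx_", dir)]] <- glorot(rng, 1L, 4L * H)
    p[[paste0("Wh_", dir)]] <- glorot(rng, H, 4L * H)
    b <- rep(0, 4L * H); b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    p[[paste0("b_", dir)]] <- b
  }
  p$Wld <- glorot(rng, 2L * H, Dl); p$bld <- rep(0, Dl)
  p$Wout <- glorot(rng, Dc + Dl, 1L); p$bout <- 0
  p
}

# --- batch assembly -------------------------------------------------------

# Stack a list of evo_tensor objects into ((B*L) x 40, true-length vector).
stack_evo <- function(evo_list) {
  L <- nrow(evo_list[[1]]$values)
  Xb <- do.call(rbind, lapply(evo_list, `[[`, "values"))
  tl <- vapply(evo_list, `[[`, integer(1), "true_length")
  list(X = Xb, tl = tl, L = L, B = length(evo_list))
}

# im2col for a sample-major stacked batch: returns (B*L) x (k*40).
im2col_batch <- function(X, B, L, k) {
  p <- (k - 1L) %/% 2L
  base <- rep.int((seq_len(B) - 1L) * L, rep.int(L, B))
  r <- rep.int(seq_len(L), B)
  blocks <- vector("list", k)
  for (j in seq_len(k)) {
    o <- j - 1L - p
    src <- r + o
    ok <- src >= 1L & src <= L
    idx <- base + pmin(pmax(src, 1L), L)
    blk <- X[idx, , drop = FALSE]
    if (any(!ok)) blk[!ok, ] <- 0
    blocks[[j]] <- blk
  }
  do.call(cbind, blocks)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Valid-row mask and per-sample grouping for a stacked batch.
batch_mask <- function(tl, B, L) {
  r <- rep.int(seq_len(L), B)
  group <- rep.int(seq_len(B), rep.int(L, B))
  list(valid = r <= tl[group], group = group)
}

# --- forward / backward ---------------------------------------------------

task1_forward <- function(params, config, batch, mm, keep_cache = FALSE) {
  B <- batch$B; L <- batch$L
  msk <- batch_mask(batch$tl, B, L)
  cache <- list()
  A_list <- list(); Z_list <- list(); Xc_list <- list()
  kernels <- c(3L, 7L)
  branches <- c(config$use_cnn1, config$use_cnn2)
  for (j in 1:2) {
    if (!branches[j]) next
    Xc <- im2col_batch(batch$X, B, L, kernels[j])
    Z <- Xc %*% params[[paste0("Wconv", j)]]
    A <- Z * (Z > 0)
    Xc_list[[j]] <- Xc; Z_list[[j]] <- Z; A_list[[j]] <- A
  }
  C <- do.call(cbind, A_list[!vapply(A_list, is.null, logical(1))])
  Fc <- ncol(C)
  # masked mean over valid rows, per sample
  Cv <- C * msk$valid
  s <- rowsum(Cv, msk$group, reorder = TRUE) / batch$tl
  if (config$use_attention) {
    z1_pre <- sweep(s %*% params$Wse1, 2, params$bse1, `+`)
    z1 <- z1_pre * (z1_pre > 0)
    g <- sigmoid(sweep(z1 %*% params$Wse2, 2, params$bse2, `+`))
  } else {
    z1 <- NULL; g <- matrix(1, B, Fc)
  }
  Cg <- C * g[msk$group, , drop = FALSE]
  # masked max pool with argmax bookkeeping
  neg <- min(Cg) - 1
  Cg_m <- Cg; Cg_m[!msk$valid, ] <- neg
  v <- matrix(0, B, Fc); amax <- matrix(0L, B, Fc)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):((b - 1L) * L + batch$tl[b])
    blk <- Cg_m[rows, , drop = FALSE]
    am <- max.col(t(blk), ties.method = "first")
    amax[b, ] <- rows[am]
    v[b, ] <- blk[cbind(am, seq_len(Fc))]
  }
  dcnn_pre <- sweep(v %*% params$Wcd, 2, params$bcd, `+`)
  d_cnn <- dcnn_pre * (dcnn_pre > 0)
  # BiLSTM over the standardized multimodal sequence
  lstm_f <- lstm_forward(params$Wx_f, params$Wh_f, params$b_f, mm,
                         reverse = FALSE)
  lstm_b <- lstm_forward(params$Wx_b, params$Wh_b, params$b_b, mm,
                         reverse = TRUE)
  u <- cbind(lstm_f$h_final, lstm_b$h_final)
  dl_pre <- sweep(u %*% params$Wld, 2, params$bld, `+`)
  d_lstm <- dl_pre * (dl_pre > 0)
  hcat <- cbind(d_cnn, d_lstm)
  logit <- drop(hcat %*% params$Wout) + params$bout
  pr <- sigmoid(logit)
  if (keep_cache) {
    cache <- list(msk = msk, Xc_list = Xc_list, Z_list = Z_list, C = C,
                  s = s, z1 = z1, g = g, Cg = Cg, v = v, amax = amax,
                  dcnn_pre = dcnn_pre, d_cnn = d_cnn, lstm_f = lstm_f,
                  lstm_b = lstm_b, u = u, dl_pre = dl_pre, d_lstm = d_lstm,
                  hcat = hcat, pr = pr)
  }
  list(prob = pr, cache = cache)
}

lstm_forward <- function(Wx, Wh, b, mm, reverse = FALSE) {
  B <- nrow(mm); Tn <- ncol(mm); H <- nrow(Wh)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  for (ti in seq_len(Tn)) {
    t_real <- ord[ti]
    x <- mm[, t_real, drop = FALSE]
    a <- x %*% Wx + h %*% Wh
    a <- sweep(a, 2, b, `+`)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    steps[[ti]] <- list(x = x, i = i, f = f, g = gg, o = o,
                        c = cc, c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h_final = h, steps = steps, ord = ord, H = H)
}

lstm_backward <- function(Wx, Wh, dh_final, fwd) {
  H <- fwd$H; Tn <- length(fwd$steps)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4 * H)
  dh <- dh_final; dc <- matrix(0, nrow(dh), H)
  for (ti in rev(seq_len(Tn))) {
    st <- fwd$steps[[ti]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc <- dc * st$f
    da <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                dg * (1 - st$g^2), do_ * st$o * (1 - st$o))
    dWx <- dWx + t(st$x) %*% da
    dWh <- dWh + t(st$h_prev) %*% da
    db <- db + colSums(da)
    dh <- da %*% t(Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

task1_backward <- function(params, config, batch, mm, y, fw) {
  ch <- fw$cache
  B <- batch$B; L <- batch$L
  grads <- list()
  dlogit <- matrix((fw$prob - y) / B, ncol = 1)
  grads$Wout <- t(ch$hcat) %*% dlogit
  grads$bout <- sum(dlogit)
  dh <- dlogit %*% t(params$Wout)
  Dc <- config$cnn_dense_units
  dd_cnn <- dh[, seq_len(Dc), drop = FALSE] * (ch$dcnn_pre > 0)
  dd_lstm <- dh[, -seq_len(Dc), drop = FALSE] * (ch$dl_pre > 0)
  # CNN dense
  grads$Wcd <- t(ch$v) %*% dd_cnn
  grads$bcd <- colSums(dd_cnn)
  dv <- dd_cnn %*% t(params$Wcd)
  Fc <- ncol(ch$C)
  # max-pool backward
  dCg <- matrix(0, B * L, Fc)
  idx <- cbind(as.vector(ch$amax), rep(seq_len(Fc), each = B))
  dCg[idx] <- as.vector(dv)
  gex <- ch$g[ch$msk$group, , drop = FALSE]
  dC <- dCg * gex
  if (config$use_attention) {
    dg_rows <- dCg * ch$C
    dg <- rowsum(dg_rows, ch$msk$group, reorder = TRUE)
    dsig <- dg * ch$g * (1 - ch$g)
    grads$Wse2 <- t(ch$z1) %*% dsig
    grads$bse2 <- colSums(dsig)
    dz1 <- (dsig %*% t(params$Wse2)) * (ch$z1 > 0)
    grads$Wse1 <- t(ch$s) %*% dz1
    grads$bse1 <- colSums(dz1)
    ds <- dz1 %*% t(params$Wse1)
    dC <- dC + (ds / batch$tl)[ch$msk$group, , drop = FALSE] * ch$msk$valid
  }
  # split into branches
  off <- 0L
  for (j in 1:2) {
    nm <- paste0("Wconv", j)
    if (is.null(params[[nm]])) next
    Fj <- ncol(params[[nm]])
    dA <- dC[, (off + 1L):(off + Fj), drop = FALSE]
    dZ <- dA * (ch$Z_list[[j]] > 0)
    grads[[nm]] <- t(ch$Xc_list[[j]]) %*% dZ
    off <- off + Fj
  }
  # LSTM dense
  grads$Wld <- t(ch$u) %*% dd_lstm
  grads$bld <- colSums(dd_lstm)
  du <- dd_lstm %*% t(params$Wld)
  H <- config$bilstm_units
  gf <- lstm_backward(params$Wx_f, params$Wh_f, du[, seq_len(H), drop = FALSE],
                      ch$lstm_f)
  gb <- lstm_backward(params$Wx_b, params$Wh_b, du[, H + seq_len(H), drop = FALSE],
                      ch$lstm_b)
  grads$Wx_f <- gf$dWx; grads$Wh_f <- gf$dWh; grads$b_f <- gf$db
  grads$Wx_b <- gb$dWx; grads$Wh_b <- gb$dWh; grads$b_b <- gb$db
  grads
}

bce_loss <- function(prob, y, eps = 1e-12) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- user-facing fit ------------------------------------------------------

#' Fit the LLPS vs non-LLPS network
#'
#' Trains the hybrid convolution/BiLSTM network on padded evolutionary
#' tensors and 27-component multimodal vectors by minimizing binary
#' cross-entropy with Adam. Deterministic given the configuration seed
#' (and single-threaded numerics). With `epochs = 0` the model is built
#' and initialized but not trained.
#'
#' @param evo List of `evo_tensor` objects (see [pad_profiles()]), all with
#'   the same padded length.
#' @param mm Numeric matrix, one 27-component multimodal vector per row
#'   (standardized internally; centering/scaling is stored in the model).
#' @param y 0/1 labels (1 = LLPS).
#' @param config A [task1_config()].
#' @return An object of class `llps_net` with elements `params`, `config`,
#'   `history` (per-epoch training and validation loss), `mm_center`,
#'   `mm_scale`, `n_max`.
#' @seealso [predict.llps_net()], [grid_search_task1()]
#' @export
llps_net <- function(evo, mm, y, config = task1_config()) {
  stopifnot(is.list(evo), length(evo) == nrow(mm),
            length(y) == nrow(mm), all(y %in% c(0, 1)))
  if (ncol(mm) != 27L) {
    stop("multimodal matrix must have 27 columns, got ", ncol(mm),
         call. = FALSE)
  }
  y <- as.numeric(y)
  rng <- local_rng(config$seed)
  ctr <- colMeans(mm)
  scl <- apply(mm, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  mm_s <- sweep(sweep(mm, 2, ctr), 2, scl, `/`)
  params <- init_params(config, rng)
  model <- structure(list(params = params, config = config,
                          mm_center = ctr, mm_scale = scl,
                          n_max = nrow(evo[[1]]$values),
                          history = data.frame()), class = "llps_net")
  if (config$epochs == 0L) return(model)

  n <- length(y)
  # Early stopping needs a validation split large enough for a stable loss
  # estimate; below ~30 held-out samples the epoch-to-epoch noise dominates
  # and "best" weights can be an early, underfit epoch, so it is disabled.
  n_val_planned <- round(config$validation_fraction * n)
  use_es <- !is.null(config$patience) && config$validation_fraction > 0 &&
    n_val_planned >= 30L
  if (use_es) {
    n_val <- n_val_planned
    perm <- rng$sample_perm(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    # keep both classes in both splits or fall back to no early stopping
    if (length(unique(y[val_idx])) < 2L || length(unique(y[tr_idx])) < 2L) {
      use_es <- FALSE; tr_idx <- seq_len(n)
    }
  } else {
    tr_idx <- seq_len(n)
  }
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  waited <- 0L
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- tr_idx[rng$sample_perm(length(tr_idx))]
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      batch <- stack_evo(evo[bi])
      fw <- task1_forward(params, config, batch, mm_s[bi, , drop = FALSE],
                          keep_cache = TRUE)
      ep_loss <- ep_loss + bce_loss(fw$prob, y[bi]); nb <- nb + 1L
      grads <- task1_backward(params, config, batch,
                              mm_s[bi, , drop = FALSE], y[bi], fw)
      upd <- adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    val_loss <- NA_real_
    if (use_es) {
      vp <- predict_stacked(params, config, evo[val_idx],
                            mm_s[val_idx, , drop = FALSE])
      val_loss <- bce_loss(vp, y[val_idx])
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = ep)
        waited <- 0L
      } else {
        waited <- waited + 1L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                             val_loss = val_loss)
    if (use_es && waited >= config$patience) break
  }
  if (use_es && best$epoch > 0L) params <- best$params
  model$params <- params
  model$history <- do.call(rbind, hist)
  model
}

predict_stacked <- function(params, config, evo, mm_s, chunk = 64L) {
  n <- length(evo)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    batch <- stack_evo(evo[idx])
    out[idx] <- task1_forward(params, config, batch,
                              mm_s[idx, , drop = FALSE])$prob
  }
  out
}

#' Predict LLPS probability
#'
#' @param object A fitted [llps_net()].
#' @param evo List of `evo_tensor` objects.
#' @param mm Multimodal matrix aligned with `evo`.
#' @param type `"response"` for probabilities, `"class"` for 0/1 calls at
#'   threshold 0.5.
#' @param ... Unused.
#' @return Numeric probabilities (or integer class calls).
#' @export
predict.llps_net <- function(object, evo, mm, type = c("response", "class"),
                             ...) {
  type <- match.arg(type)
  stopifnot(length(evo) == nrow(mm), ncol(mm) == 27L)
  mm_s <- sweep(sweep(mm, 2, object$mm_center), 2, object$mm_scale, `/`)
  p <- predict_stacked(object$params, object$config, evo, mm_s)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
print.llps_net <- function(x, ...) {
  cfg <- x$config
  cat("LLPS network (conv + BiLSTM fusion)\n")
  cat(sprintf("  architecture: CNN1=%s CNN2=%s cnn_dense=%d bilstm=%d lstm_dense=%d attention=%s\n",
              if (cfg$use_cnn1) cfg$cnn1_filters else "off",
              if (cfg$use_cnn2) cfg$cnn2_filters else "off",
              cfg$cnn_dense_units, cfg$bilstm_units, cfg$bilstm_dense_units,
              cfg$use_attention))
  cat(sprintf("  padded length: %d; parameters: %d; epochs trained: %d\n",
              x$n_max, sum(vapply(x$params, length, integer(1))),
              nrow(x$history)))
  invisible(x)
}

#' @export
summary.llps_net <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("training history (loss):\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Channel-attention gates for a batch
#'
#' Returns the squeeze-excitation per-channel gates in `[0, 1]` computed on
#' the given inputs (all ones when attention is disabled).
#'
#' @param object A fitted [llps_net()].
#' @param evo List of `evo_tensor` objects.
#' @param mm Multimodal matrix aligned with `evo`.
#' @return Numeric matrix, samples x channels.
#' @export
attention_gates <- function(object, evo, mm) {
  mm_s <- sweep(sweep(mm, 2, object$mm_center), 2, object$mm_scale, `/`)
  batch <- stack_evo(evo)
  fw <- task1_forward(object$params, object$config, batch, mm_s,
                      keep_cache = TRUE)
  fw$cache$g
}

#' Cross-validated architecture search
#'
#' Evaluates candidate configurations by stratified k-fold cross-validation
#' and ranks them by pooled AUC, breaking ties by sensitivity (the ranking
#' rule used to pick the reference optimum).
#'
#' @param evo,mm,y Dataset as for [llps_net()].
#' @param configs List of [task1_config()] objects; defaults to the full
#'   243-point grid (prohibitive at full data scale — pass a subset for
#'   exploratory runs).
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Data frame, one row per configuration with the seven pooled
#'   metrics, ordered best first.
#' @export
grid_search_task1 <- function(evo, mm, y, configs = enumerate_grid(),
                              k = 10L, seed = 1L) {
  rows <- lapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    folds <- stratified_folds(y, k = k, seed = seed)
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- llps_net(evo[tr], mm[tr, , drop = FALSE], y[tr], config = cfg)
      oof[!tr] <- predict(fit, evo[!tr], mm[!tr, , drop = FALSE])
    }
    m <- metric_set(y, oof)
    data.frame(config = ci, cnn1 = cfg$cnn1_filters, cnn2 = cfg$cnn2_filters,
               cnn_dense = cfg$cnn_dense_units, bilstm = cfg$bilstm_units,
               bilstm_dense = cfg$bilstm_dense_units,
               sn = m[["sn"]], sp = m[["sp"]], acc = m[["acc"]],
               mcc = m[["mcc"]], pre = m[["pre"]], f1 = m[["f1"]],
               auc = m[["auc"]])
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc, -out$sn), , drop = FALSE]
}
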