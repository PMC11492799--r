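# Evaluation kit: confusion-count metrics, rank-based AUC, and the
# stratified k-fold cross-validation harness shared by both tasks.

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, Matthews correlation coefficient,
#' precision and F1 from TP/TN/FP/FN counts. An undefined ratio (zero
#' denominator) is returned as `NA` and named in the `"undefined"`
#' attribute — never a silent 0. MCC with a zero denominator is reported as
#' 0, flagged the same way (the common convention for a degenerate
#' confusion table).
#'
#' @param tp,tn,fp,fn Non-negative integer counts; at least one positive.
#' @return Named numeric vector `c(sn, sp, acc, mcc, pre, f1)` with an
#'   `"undefined"` attribute listing flagged metrics (possibly empty).
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  sn  <- ratio(tp, tp + fn, "sn")
  sp  <- ratio(tn, tn + fp, "sp")
  acc <- (tp + tn) / sum(counts)
  pre <- ratio(tp, tp + fp, "pre")
  f1  <- if (is.na(pre) || is.na(sn) || (pre + sn) == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * pre * sn / (pre + sn)
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else {
    (tp * tn - fp * fn) / mcc_den
  }
  structure(c(sn = sn, sp = sp, acc = acc, mcc = mcc, pre = pre, f1 = f1),
            undefined = unique(undefined))
}

#' Tally a confusion table from labels and thresholded scores
#'
#' @param labels 0/1 (or logical) true labels, 1 = positive class.
#' @param scores Predicted probabilities.
#' @param threshold Decision threshold (default 0.5; `score >= threshold`
#'   calls positive).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  c(tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with tie mid-ranking: the probability that a
#' random positive outranks a random negative, counting ties as 1/2.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metric set from scores
#'
#' Thresholded confusion metrics plus AUC — the seven-metric panel
#' (Sn, Sp, Acc, MCC, Pre, F1, AUC) reported throughout the package.
#'
#' @inheritParams confusion_counts
#' @return Named numeric vector of the seven metrics.
#' @export
metric_set <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, scores, threshold)
  m <- metrics_from_counts(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
  out <- c(m, auc = roc_auc(scores, labels))
  attr(out, "undefined") <- attr(m, "undefined")
  out
}

#' Stratified fold assignment
#'
#' Deterministic given the seed: ids are shuffled within each class and
#' dealt round-robin into `k` folds, so fold sizes differ by at most one
#' and every fold holds both classes when counts allow.
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(k >= 2L)
  if (min(table(labels)) < k) {
    stop("minority class has fewer than k = ", k, " members; cannot stratify",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  ord <- unlist(lapply(sort(unique(labels)), function(cls) {
    idx <- which(labels == cls)
    idx[rng$sample_perm(length(idx))]
  }))
  folds <- integer(length(labels))
  folds[ord] <- rep_len(seq_len(k), length(labels))
  folds
}

#' Stratified k-fold cross-validation
#'
#' Runs a trainer over seed-pinned stratified folds and evaluates
#' out-of-fold predictions. Pooled metrics (computed from the concatenated
#' out-of-fold predictions) are reported as primary; per-fold metrics with
#' mean and standard deviation are also returned.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y 0/1 labels.
#' @param trainer Function `f(x_train, y_train)` returning a fitted object.
#' @param predictor Function `f(fit, x_test)` returning probabilities
#'   (defaults to `predict`).
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param threshold Decision threshold for the confusion metrics.
#' @return List with `pooled` (seven-metric vector), `per_fold` (k x 7
#'   matrix), `fold_mean`, `fold_sd`, `folds` (assignment vector) and
#'   `oof_scores` (out-of-fold probabilities, input order).
#' @export
kfold_cv <- function(x, y, trainer, predictor = function(fit, newx) predict(fit, newx),
                     k = 10L, seed = 1L, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  folds <- stratified_folds(y, k = k, seed = seed)
  oof <- numeric(length(y))
  per_fold <- matrix(NA_real_, nrow = k, ncol = 7,
                     dimnames = list(NULL, c("sn", "sp", "acc", "mcc", "pre", "f1", "auc")))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    fit <- trainer(x[tr, , drop = FALSE], y[tr])
    p <- as.numeric(predictor(fit, x[te, , drop = FALSE]))
    oof[te] <- p
    per_fold[f, ] <- suppressWarnings(metric_set(y[te], p, threshold))
  }
  list(
    pooled    = metric_set(y, oof, threshold),
    per_fold  = per_fold,
    fold_mean = colMeans(per_fold, na.rm = TRUE),
    fold_sd   = apply(per_fold, 2, stats::sd, na.rm = TRUE),
    folds     = folds,
    oof_scores = oof
  )
}

# Seed-scoped RNG helper: draws from an isolated, resumable RNG stream so
# library code never disturbs the caller's .Random.seed.
local_rng <- function(seed) {
  state <- NULL
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    res <- f()
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    res
  }
  list(
    sample_perm = function(n) run(function() sample.int(n)),
    runif  = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm  = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    rlnorm = function(n, meanlog = 0, sdlog = 1) run(function() stats::rlnorm(n, meanlog, sdlog)),
    rgamma = function(n, shape, rate = 1) run(function() stats::rgamma(n, shape, rate = rate)),
    rpois  = function(n, lambda) run(function() stats::rpois(n, lambda)),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      run(function() sample.int(n, size, replace = replace, prob = prob)),
    with_seed = run
  )
}
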