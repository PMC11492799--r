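# Shared fixtures, built in code at test time.

AA <- aa_alphabet()

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

# A small record set with both classes, short padded length.
small_records <- function(n_per_class = 6L, seed = 42L, n_max = 64L) {
  gen_sequences(n_per_class = n_per_class, seed = seed, n_max = n_max)
}

# Tiny AAIndex fixture on disk, returned as (path, table).
tmp_aaindex <- function(n_props = 5L, seed = 7L, include_na = TRUE) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  gen_aaindex_fixture(path, n_props = n_props, include_na = include_na,
                      seed = seed)
  path
}

# Tiny untrained network configuration for structural tests.
tiny_config <- function(...) {
  defaults <- list(cnn1_filters = 4L, cnn2_filters = 3L,
                   cnn_dense_units = 3L, bilstm_units = 3L,
                   bilstm_dense_units = 2L, se_reduction = 2L,
                   epochs = 0L, seed = 11L)
  do.call(task1_config, utils::modifyList(defaults, list(...)))
}

# Random evo tensors with given true lengths at padded length n_max.
random_evo <- function(true_lengths, n_max = 32L, seed = 1L) {
  set.seed(seed)
  lapply(seq_along(true_lengths), function(b) {
    tl <- true_lengths[b]
    v <- matrix(0, n_max, 40L)
    v[seq_len(tl), ] <- rnorm(tl * 40L)
    structure(list(values = v, true_length = tl, seq_id = paste0("s", b)),
              class = "evo_tensor")
  })
}

# Independent trapezoid-rule ROC AUC used as the oracle for roc_auc().
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t),
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
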