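# Transforms that shape evolutionary profiles into the fixed-size tensors
# consumed by the LLPS network.

#' Convert HHsuite match-state scores to frequencies
#'
#' Applies `h' = 2^(-0.001 * h)` elementwise to an integer-coded HMM
#' profile; the `*` sentinel (stored as `Inf`) maps to frequency exactly 0.
#' The transform is strictly decreasing in `h`, with outputs in `(0, 1]`
#' plus the exact 0 of the sentinel.
#'
#' @param raw A [profile_matrix()] of kind `"hmm_raw"`, or a bare numeric
#'   matrix of scores.
#' @return A [profile_matrix()] of kind `"hmm_freq"` (or a bare matrix if a
#'   matrix was supplied).
#' @export
hmm_transform <- function(raw) {
  if (inherits(raw, "profile_matrix")) {
    stopifnot(raw$kind == "hmm_raw")
    freq <- 2^(-0.001 * raw$values)
    freq[is.infinite(raw$values)] <- 0
    profile_matrix(freq, kind = "hmm_freq", seq_id = raw$seq_id)
  } else {
    freq <- 2^(-0.001 * raw)
    freq[is.infinite(raw)] <- 0
    freq
  }
}

#' Stack and zero-pad a PSSM / HMM profile pair
#'
#' Channel-stacks the PSSM (columns 1-20) and the HMM match-state
#' frequencies (columns 21-40) of one sequence and pads with zero rows to a
#' standard length `n_max`, so sequences of unequal length share one tensor
#' shape. Rows beyond the true length are exactly zero.
#'
#' @param pssm A [profile_matrix()] of kind `"pssm"`.
#' @param hmm_freq A [profile_matrix()] of kind `"hmm_freq"` (apply
#'   [hmm_transform()] first) with the same `seq_id` and row count.
#' @param n_max Standard padded length. The reference configuration uses
#'   5000 (an upper bound on admissible sequence length); it is configurable
#'   so the network can run at smaller scales.
#' @param scale_pssm Optional min-max scaling of the PSSM block into
#'   `[0, 1]` (per profile); default `FALSE` passes log-odds scores raw.
#' @return An object of class `evo_tensor`: list with `values`
#'   (`n_max` x 40 matrix), `true_length`, `seq_id`.
#' @export
pad_profiles <- function(pssm, hmm_freq, n_max = 5000L, scale_pssm = FALSE) {
  stopifnot(inherits(pssm, "profile_matrix"), pssm$kind == "pssm",
            inherits(hmm_freq, "profile_matrix"), hmm_freq$kind == "hmm_freq")
  if (!identical(pssm$seq_id, hmm_freq$seq_id)) {
    stop("PSSM and HMM profiles belong to different sequences (",
         pssm$seq_id, " vs ", hmm_freq$seq_id, ")", call. = FALSE)
  }
  L <- nrow(pssm$values)
  if (nrow(hmm_freq$values) != L) {
    stop("PSSM and HMM row counts differ for ", pssm$seq_id, call. = FALSE)
  }
  if (L > n_max) {
    stop("sequence ", pssm$seq_id, " has length ", L,
         " exceeding n_max = ", n_max, call. = FALSE)
  }
  pssm_block <- pssm$values
  if (scale_pssm) {
    rng <- range(pssm_block)
    if (diff(rng) > 0) pssm_block <- (pssm_block - rng[1]) / diff(rng)
  }
  values <- matrix(0, nrow = n_max, ncol = 40L)
  values[seq_len(L), ] <- cbind(pssm_block, hmm_freq$values)
  structure(list(values = values, true_length = L, seq_id = pssm$seq_id),
            class = "evo_tensor")
}

#' @export
print.evo_tensor <- function(x, ...) {
  cat("evo_tensor ", x$seq_id, ": ", nrow(x$values),
      " x 40 (true length ", x$true_length, ")\n", sep = "")
  invisible(x)
}
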