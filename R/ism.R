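# In-silico saturation mutagenesis (ISM): every residue of a sequence is
# mutated to each of the 19 alternatives, the model probability is
# re-predicted, and the absolute probability change is the importance
# score. Position scores are aggregated into near-equal contiguous
# segments ("position ratios") and into an introduced-residue x segment
# map across sequences.

#' Saturation mutagenesis of one sequence against a scorer
#'
#' Evaluates exactly `L x 19` single-residue mutants. The scorer is any
#' deterministic function from a character vector of sequences to
#' probabilities in `[0, 1]` — typically a feature pipeline feeding the
#' mechanism classifier (see [make_ps_scorer()]); the LLPS network can be
#' supplied the same way. The importance score of mutation (i, a) is
#' `|p_ref - p_mut|`; entries where `a` is the reference residue are 0.
#'
#' @param record One-row data frame (or list) with `id` and `sequence`.
#' @param scorer Function `f(sequences) -> probabilities`.
#' @return Object of class `ism_result`: `seq_id`, `score_matrix`
#'   (L x 20, columns = introduced residue in canonical order),
#'   `position_scores` (row sums), `ref_prob`, `sequence`.
#' @export
ism_saturate <- function(record, scorer) {
  seq <- record$sequence
  check_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  ref_prob <- as.numeric(scorer(seq))
  if (length(ref_prob) != 1L || is.na(ref_prob)) {
    stop("scorer failed on the reference sequence of ", record$id,
         call. = FALSE)
  }
  mutants <- character(L * 19L)
  pos_of <- integer(L * 19L); alt_of <- integer(L * 19L)
  kk <- 0L
  for (i in seq_len(L)) {
    for (a in seq_len(20L)) {
      if (AA20[a] == chars[i]) next
      kk <- kk + 1L
      mut <- chars; mut[i] <- AA20[a]
      mutants[kk] <- paste(mut, collapse = "")
      pos_of[kk] <- i; alt_of[kk] <- a
    }
  }
  probs <- tryCatch(as.numeric(scorer(mutants)),
                    error = function(e) stop(
                      "scorer failed on mutants of ", record$id, ": ",
                      conditionMessage(e), call. = FALSE))
  if (length(probs) != L * 19L || anyNA(probs)) {
    bad <- which(is.na(probs))[1]
    stop("scorer returned an invalid probability for mutant at position ",
         pos_of[bad %||% 1L], " substitution ",
         AA20[alt_of[bad %||% 1L]], " of ", record$id, call. = FALSE)
  }
  score <- matrix(0, nrow = L, ncol = 20L,
                  dimnames = list(NULL, AA20))
  score[cbind(pos_of, alt_of)] <- abs(ref_prob - probs)
  structure(list(seq_id = record$id, score_matrix = score,
                 position_scores = rowSums(score), ref_prob = ref_prob,
                 sequence = seq),
            class = "ism_result")
}

#' @export
print.ism_result <- function(x, ...) {
  cat("ISM result ", x$seq_id, ": L = ", length(x$position_scores),
      ", reference probability ", round(x$ref_prob, 4),
      ", total score ", round(sum(x$position_scores), 4), "\n", sep = "")
  invisible(x)
}

# Segment id of each position under the floor partition: contiguous,
# deterministic, sizes differing by at most one; trailing segments are
# empty (score 0) when L < n_segments.
segment_ids <- function(L, n_segments) {
  if (n_segments <= 0) stop("n_segments must be positive", call. = FALSE)
  floor((seq_len(L) - 1) * n_segments / L) + 1L
}

#' Aggregate position scores into segment position ratios
#'
#' Partitions the sequence into `n_segments` contiguous near-equal
#' segments (sizes differ by at most one) and sums the per-position
#' importance scores within each — the "position ratio" vector that gives
#' every sequence a common feature dimension. Sums are conserved: the
#' segment vector totals the position-score total for every `n_segments`.
#'
#' @param result An [ism_saturate()] result.
#' @param n_segments Number of segments (50 for the introduced-residue
#'   map, 25 for the combined regional profile).
#' @return Numeric vector of length `n_segments`.
#' @export
segment_aggregate <- function(result, n_segments = 50L) {
  stopifnot(inherits(result, "ism_result"))
  L <- length(result$position_scores)
  seg <- segment_ids(L, n_segments)
  out <- numeric(n_segments)
  agg <- tapply(result$position_scores, seg, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Introduced-residue by segment importance map
#'
#' For a set of ISM results, sums the scores of substitutions that
#' introduce amino acid `a` within segment `s`, aggregated over sequences:
#' a 20 x `n_segments` map of which residues matter where. Set
#' `residue = "reference"` to attribute scores to the replaced residue
#' instead of the introduced one.
#'
#' @param results List of [ism_saturate()] results.
#' @param n_segments Number of segments (default 50).
#' @param residue Attribute scores to the `"introduced"` (default) or
#'   `"reference"` residue.
#' @return Numeric 20 x `n_segments` matrix, rows in canonical residue
#'   order.
#' @export
aa_position_map <- function(results, n_segments = 50L,
                            residue = c("introduced", "reference")) {
  residue <- match.arg(residue)
  stopifnot(length(results) >= 1L)
  map <- matrix(0, nrow = 20L, ncol = n_segments,
                dimnames = list(AA20, NULL))
  for (res in results) {
    stopifnot(inherits(res, "ism_result"))
    L <- nrow(res$score_matrix)
    seg <- segment_ids(L, n_segments)
    if (residue == "introduced") {
      # sum scores by segment for each introduced residue (column)
      agg <- rowsum(res$score_matrix, seg)
      map[, as.integer(rownames(agg))] <-
        map[, as.integer(rownames(agg)), drop = FALSE] + t(agg)
    } else {
      ref <- strsplit(res$sequence, "")[[1]]
      ps <- res$position_scores
      for (i in seq_len(L)) {
        map[ref[i], seg[i]] <- map[ref[i], seg[i]] + ps[i]
      }
    }
  }
  map
}

#' Export ISM results as a long-format table
#'
#' @param result An [ism_saturate()] result.
#' @return Data frame with columns `seq_id`, `position`, `ref`, `alt`,
#'   `score` (the `L x 19` mutant rows).
#' @export
ism_long <- function(result) {
  stopifnot(inherits(result, "ism_result"))
  L <- nrow(result$score_matrix)
  ref <- strsplit(result$sequence, "")[[1]]
  out <- data.frame(
    seq_id = result$seq_id,
    position = rep(seq_len(L), each = 20L),
    ref = rep(ref, each = 20L),
    alt = rep(AA20, L),
    score = as.vector(t(result$score_matrix)),
    stringsAsFactors = FALSE
  )
  out[out$ref != out$alt, , drop = FALSE]
}

#' Wrap a mechanism classifier as an ISM scorer
#'
#' Builds the scorer closure [ism_saturate()] expects from a fitted
#' [ps_mechanism_xgb()] model and a feature pipeline mapping sequences to
#' the model's feature table.
#'
#' @param model A `ps_xgb` model.
#' @param encoder Function `f(sequences) -> feature matrix` with at least
#'   the model's feature columns.
#' @return Function from a character vector of sequences to PS-Self
#'   probabilities.
#' @export
make_ps_scorer <- function(model, encoder) {
  stopifnot(inherits(model, "ps_xgb"), is.function(encoder))
  function(sequences) {
    feats <- encoder(sequences)
    predict(model, feats)
  }
}
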