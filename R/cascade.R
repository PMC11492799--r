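# The two-stage prediction cascade: a sequence is first scored by the
# LLPS network; only sequences called LLPS (probability >= threshold) are
# passed to the mechanism classifier for the PS-Self / PS-Part call.

#' Two-task prediction cascade
#'
#' For each sequence: predicts `p_llps` from the LLPS network; if
#' `p_llps >= threshold` the mechanism classifier assigns PS-Self or
#' PS-Part with its probability, otherwise the class is `non_LLPS` and
#' the second task is not evaluated. A sequence whose profile or external
#' features are missing yields a failure row (`status` column) and the run
#' continues.
#'
#' @param records Data frame of sequence records.
#' @param evo Named list of `evo_tensor` objects keyed by sequence id.
#' @param provider A [feature_provider()] for the multimodal features.
#' @param task1_model A fitted [llps_net()].
#' @param task2_model A fitted [ps_mechanism_xgb()].
#' @param task2_encoder Function `f(sequences) -> feature matrix`
#'   containing the mechanism model's features.
#' @param threshold LLPS decision threshold (default 0.5).
#' @return Data frame with columns `seq_id`, `p_llps`, `llps_call`,
#'   `p_self`, `mechanism_call`, `status`; one row per input sequence.
#' @export
predict_cascade <- function(records, evo, provider, task1_model, task2_model,
                            task2_encoder, threshold = 0.5) {
  n <- nrow(records)
  out <- data.frame(
    seq_id = records$id, p_llps = NA_real_, llps_call = NA_character_,
    p_self = NA_real_, mechanism_call = NA_character_,
    status = "ok", stringsAsFactors = FALSE
  )
  mm <- matrix(NA_real_, nrow = n, ncol = 27L)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    id <- records$id[i]
    if (is.null(evo[[id]])) {
      out$status[i] <- "missing_profile"; ok[i] <- FALSE; next
    }
    mm_i <- tryCatch(multimodal_vector(records[i, ], provider),
                     error = function(e) NULL)
    if (is.null(mm_i)) {
      out$status[i] <- "missing_feature"; ok[i] <- FALSE; next
    }
    mm[i, ] <- mm_i
  }
  if (any(ok)) {
    p1 <- predict(task1_model, evo[records$id[ok]], mm[ok, , drop = FALSE])
    out$p_llps[ok] <- p1
    out$llps_call[ok] <- ifelse(p1 >= threshold, "LLPS", "non_LLPS")
    gate <- ok & !is.na(out$p_llps) & out$p_llps >= threshold
    if (any(gate)) {
      p2 <- tryCatch({
        feats <- task2_encoder(records$sequence[gate])
        predict(task2_model, feats)
      }, error = function(e) NULL)
      if (is.null(p2)) {
        out$status[gate] <- "missing_feature"
      } else {
        out$p_self[gate] <- p2
        out$mechanism_call[gate] <- ifelse(p2 >= 0.5, "PS-Self", "PS-Part")
      }
    }
  }
  out
}

#' Write a cascade report as TSV
#'
#' Fixed column set, `NA` rendered as empty fields; byte-identical across
#' re-runs with the same inputs.
#'
#' @param report Output of [predict_cascade()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cascade_report <- function(report, path) {
  fmt <- report
  fmt$p_llps <- ifelse(is.na(fmt$p_llps), "", sprintf("%.6f", fmt$p_llps))
  fmt$p_self <- ifelse(is.na(fmt$p_self), "", sprintf("%.6f", fmt$p_self))
  fmt[is.na(fmt)] <- ""
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
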