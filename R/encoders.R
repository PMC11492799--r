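# Per-sequence handcrafted features: amino-acid composition, AAIndex-weighted
# composition, Shannon entropy, Kyte-Doolittle hydropathy, charge patterning,
# and the assembled multimodal / analysis vectors.

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  if (!is_canonical(sequence)) {
    stop("sequence contains non-canonical residues; filter first", call. = FALSE)
  }
  invisible(sequence)
}

#' Amino-acid composition (AAC)
#'
#' The frequency of each of the 20 canonical residues, `f(x) = N(x) / N`
#' where `N` is the sequence length. Components are ordered by the
#' canonical alphabet and sum to 1.
#'
#' @param sequence A validated residue string.
#' @return Named numeric vector of 20 frequencies (`AAC_A` ... `AAC_Y`).
#' @export
aac <- function(sequence) {
  check_sequence(sequence)
  counts <- aa_counts(sequence)
  stats::setNames(counts / sum(counts), paste0("AAC_", AA20))
}

#' AAIndex-weighted composition (AAIndex_AAC)
#'
#' For each retained AAIndex property `j`, the composition-weighted sum
#' `F_j = sum_i f(x_i) * A_ij` over the 20 residues — a fixed-length
#' physicochemical embedding of a variable-length sequence. With the full
#' AAIndex1 release this is a 531-dimensional vector.
#'
#' @param sequence A validated residue string.
#' @param table An `aaindex_table` from [read_aaindex1()].
#' @return Named numeric vector, one component per retained property.
#' @export
aaindex_aac <- function(sequence, table) {
  stopifnot(inherits(table, "aaindex_table"))
  if (!ncol(table$values)) stop("AAIndex table is empty", call. = FALSE)
  if (!identical(rownames(table$values), AA20)) {
    stop("AAIndex table rows do not match the canonical alphabet", call. = FALSE)
  }
  comp <- aac(sequence)
  drop(comp %*% table$values)
}

#' Shannon entropy of the residue composition
#'
#' `H = -sum_i p_i log2 p_i` in bits over the 20-letter composition, with
#' `0 * log2(0)` taken as 0. Bounded by `[0, log2(20)]`.
#'
#' @param sequence A validated residue string.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(sequence) {
  p <- aac(sequence)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mean Kyte-Doolittle hydropathy
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy scale value over all
#' residues of the sequence.
#'
#' @param sequence A validated residue string.
#' @return Mean hydropathy (positive = hydrophobic).
#' @export
kd_hydropathy <- function(sequence) {
  check_sequence(sequence)
  counts <- aa_counts(sequence)
  sum(counts * KD_SCALE[AA20]) / sum(counts)
}

#' Charge-composition features (FCR, NCPR)
#'
#' Fraction of charged residues `FCR = (n_pos + n_neg) / N` and net charge
#' per residue `NCPR = (n_pos - n_neg) / N`, with positives `{K, R}` and
#' negatives `{D, E}`. Histidine counts as positive only when
#' `histidine_charged = TRUE`.
#'
#' @param sequence A validated residue string.
#' @param histidine_charged Treat H as positively charged (default `FALSE`,
#'   the common CIDER convention).
#' @return Named numeric vector `c(FCR, NCPR)`.
#' @export
charge_features <- function(sequence, histidine_charged = FALSE) {
  check_sequence(sequence)
  counts <- stats::setNames(aa_counts(sequence), AA20)
  pos <- AA_POSITIVE
  if (histidine_charged) pos <- c(pos, "H")
  n_pos <- sum(counts[pos]); n_neg <- sum(counts[AA_NEGATIVE])
  n <- sum(counts)
  c(FCR = (n_pos + n_neg) / n, NCPR = (n_pos - n_neg) / n)
}

# --- simplified charge/proline patterning ---------------------------------
# Blob-based mixing parameters in the spirit of the Das-Pappu kappa: the
# sequence is scanned with 5- and 6-residue windows, the variance of the
# windowed charge asymmetry is compared with the overall asymmetry, and the
# two window sizes are averaged. These built-ins exist so synthetic fixtures
# can populate the Kappa/Omega slots; they are NOT the reference CIDER
# implementations and carry no pretension of numerical equivalence.

blob_mixing <- function(indicator_plus, indicator_minus, windows = c(5L, 6L)) {
  n <- length(indicator_plus)
  if (n < max(windows) + 1L) return(0)
  f_plus <- mean(indicator_plus); f_minus <- mean(indicator_minus)
  denom <- f_plus + f_minus
  if (denom == 0) return(0)
  sigma_total <- (f_plus - f_minus)^2 / denom
  per_window <- vapply(windows, function(w) {
    starts <- seq_len(n - w + 1L)
    sig <- vapply(starts, function(s) {
      idx <- s:(s + w - 1L)
      fp <- mean(indicator_plus[idx]); fm <- mean(indicator_minus[idx])
      d <- fp + fm
      if (d == 0) 0 else (fp - fm)^2 / d
    }, numeric(1))
    mean((sig - sigma_total)^2)
  }, numeric(1))
  mean(per_window)
}

#' Simplified charge- and proline-patterning scores (non-reference)
#'
#' Window-based mixing statistics over 5- and 6-residue blobs, averaged:
#' `kappa_simple` contrasts positive (`K`,`R`) against negative (`D`,`E`)
#' residues, `omega_simple` contrasts proline-plus-charged residues against
#' the rest. They order sequences from well-mixed (low) to blocky (high)
#' like the CIDER parameters do, but are simplified stand-ins intended for
#' synthetic fixtures — not the reference implementations.
#'
#' @param sequence A validated residue string.
#' @return Named numeric vector `c(kappa_simple, omega_simple)`.
#' @export
patterning_simple <- function(sequence) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  kappa <- blob_mixing(as.numeric(chars %in% AA_POSITIVE),
                       as.numeric(chars %in% AA_NEGATIVE))
  pro_charge <- as.numeric(chars %in% c("P", AA_POSITIVE, AA_NEGATIVE))
  omega <- blob_mixing(pro_charge, 1 - pro_charge)
  c(kappa_simple = kappa, omega_simple = omega)
}

# --- assembled vectors ----------------------------------------------------

#' Multimodal feature vector (27 components)
#'
#' Concatenation, in fixed order, of the 20 AAC components and the seven
#' phase-separation-related features: IDR fraction, length of the longest
#' PS IDR, PS potential, prion-like-domain score, granule propensity
#' (provider-supplied), then hydropathy and Shannon entropy (computed
#' internally). This is the sequence-level input of the LLPS network's
#' BiLSTM branch.
#'
#' @param record One-row data frame (or list) with `id` and `sequence`.
#' @param provider A [feature_provider()] supplying the five external
#'   features.
#' @return Named numeric vector of length 27.
#' @export
multimodal_vector <- function(record, provider) {
  seq <- record$sequence; id <- record$id
  external <- provider_lookup(provider, id,
                              setdiff(MULTIMODAL_PS_FEATURES,
                                      c("hydropathy", "entropy")))
  c(aac(seq),
    external,
    hydropathy = kd_hydropathy(seq),
    entropy = shannon_entropy(seq))
}

#' Sequence-property analysis vector (12 components)
#'
#' The 12-feature physicochemical panel used to contrast PS-Self, PS-Part
#' and non-PS sequences, in fixed panel order: IDR fraction, LCR score,
#' PLD score, granule propensity, FCR, NCPR, Kappa, Omega, PPII propensity,
#' pi-pi score, hydropathy, Shannon entropy. FCR/NCPR, hydropathy and
#' entropy are computed internally; the rest come from the provider.
#'
#' @inheritParams multimodal_vector
#' @return Named numeric vector of length 12.
#' @export
analysis_vector <- function(record, provider) {
  seq <- record$sequence; id <- record$id
  internal <- c(charge_features(seq),
                hydropathy = kd_hydropathy(seq),
                entropy = shannon_entropy(seq))
  ext_names <- setdiff(ANALYSIS_FEATURES, names(internal))
  external <- provider_lookup(provider, id, ext_names)
  out <- c(external, internal)[ANALYSIS_FEATURES]
  stats::setNames(out, ANALYSIS_FEATURES)
}

#' Build a feature table for a set of records
#'
#' Applies a per-record encoder over a record set and stacks the results
#' into a numeric matrix with sequence ids as row names. Feature-name order
#' is deterministic across runs.
#'
#' @param records Data frame of sequence records.
#' @param encoder Function mapping one record row to a named numeric vector
#'   (e.g. `function(r) aac(r$sequence)` or a closure over
#'   [multimodal_vector()]).
#' @return Numeric matrix, rows = sequence ids, columns = feature names.
#' @export
feature_table <- function(records, encoder) {
  rows <- lapply(seq_len(nrow(records)), function(i) encoder(records[i, ]))
  nm <- names(rows[[1]])
  bad <- which(vapply(rows, function(r) !identical(names(r), nm), logical(1)))
  if (length(bad)) {
    stop("encoder returned inconsistent feature names for record ", bad[1],
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- records$id
  out
}
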