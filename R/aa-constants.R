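# Amino-acid alphabets, residue-column orders of the file dialects the
# package reads, the Kyte-Doolittle hydropathy scale, and the feature-name
# registry shared by the encoders, the selection pipeline and the ISM module.

#' Canonical amino-acid alphabet
#'
#' All matrices and composition vectors in this package use the alphabetical
#' one-letter order `ACDEFGHIKLMNPQRSTVWY`. File readers re-map from each
#' format's native column order to this one at parse time.
#'
#' @return Character vector of the 20 canonical one-letter residue codes.
#' @export
aa_alphabet <- function() AA20

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Native residue-column orders of the supported profile dialects.
PSSM_NATIVE_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]  # PSI-BLAST
HHM_NATIVE_ORDER  <- AA20                                       # HHsuite is alphabetical

# AAIndex1 "I" line lists residues in two rows of ten:
#   A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V
AAINDEX_ROW1 <- strsplit("ARNDCQEGHI", "")[[1]]
AAINDEX_ROW2 <- strsplit("LKMFPSTWYV", "")[[1]]

# Kyte & Doolittle (1982) hydropathy scale, keyed by one-letter code.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Charged residue sets used by FCR/NCPR. Histidine is treated as uncharged
# by default (the common CIDER convention); see charge_features().
AA_POSITIVE <- c("K", "R")
AA_NEGATIVE <- c("D", "E")

# ---------------------------------------------------------------------------
# Feature-name registry
#
# A single authoritative table of feature identities so that the encoders,
# the selection pipeline and the ISM module agree on names. "internal"
# features are computed by this package; "provider" features come from
# third-party phase-separation tools via the TSV / programmatic provider
# interface.

PROVIDER_FEATURES <- c(
  "IDR_fraction", "longest_PS_IDR", "PS_potential", "LCR_score",
  "PLD_forming", "granule_propensity", "pipi_score", "PPII_propensity",
  "Kappa", "Omega"
)

# The seven phase-separation-related features appended to AAC in the
# multimodal vector, in their fixed concatenation order. The first five are
# provider-supplied; hydropathy and entropy are computed internally.
MULTIMODAL_PS_FEATURES <- c(
  "IDR_fraction", "longest_PS_IDR", "PS_potential", "PLD_forming",
  "granule_propensity", "hydropathy", "entropy"
)

# The 12 sequence-property features of the mechanism analysis panel, in
# fixed panel order.
ANALYSIS_FEATURES <- c(
  "IDR_fraction", "LCR_score", "PLD_forming", "granule_propensity",
  "FCR", "NCPR", "Kappa", "Omega", "PPII_propensity", "pipi_score",
  "hydropathy", "entropy"
)

#' Feature-name registry
#'
#' Lists the feature identities shared across the package: the 20 AAC
#' component names, the provider-supplied phase-separation feature names,
#' the 7 PS-related features of the multimodal vector, and the 12-feature
#' analysis panel.
#'
#' @return Named list of character vectors
#'   (`aac`, `provider`, `multimodal_ps`, `analysis`).
#' @export
feature_registry <- function() {
  list(
    aac           = paste0("AAC_", AA20),
    provider      = PROVIDER_FEATURES,
    multimodal_ps = MULTIMODAL_PS_FEATURES,
    analysis      = ANALYSIS_FEATURES
  )
}

# internal helpers --------------------------------------------------------

is_canonical <- function(sequence) {
  !grepl(sprintf("[^%s]", paste(AA20, collapse = "")), sequence)
}

# Tabulate residues of one sequence over the canonical alphabet.
aa_counts <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- table(factor(chars, levels = AA20))
  as.integer(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
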