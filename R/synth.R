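# Synthetic-data generators. Every other module is testable offline against
# fixtures produced here: labeled sequence sets with class-conditional
# length and composition structure, profile files in both supported
# dialects, AAIndex-format fixture files, external-feature tables, and
# planted-signal feature tables for the selection pipeline.

# Background amino-acid frequencies (approximate UniProt proteome-wide
# composition), canonical order.
AA_BACKGROUND <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039,
  G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
  M = 0.024, N = 0.041, P = 0.047, Q = 0.039, R = 0.055,
  S = 0.066, T = 0.054, V = 0.069, W = 0.011, Y = 0.029
)

# Class-conditional composition models. Phase-separating sequences are
# enriched in glycine, proline and polar residues and depleted in
# hydrophobic/aromatic residues relative to folded (non-PS) sequences;
# the non-PS model is the unmodified background.
ps_composition <- function() {
  w <- AA_BACKGROUND
  w[c("G", "P", "S", "Q", "N")] <- w[c("G", "P", "S", "Q", "N")] * 1.8
  w[c("L", "I", "V", "F", "W", "Y", "M")] <-
    w[c("L", "I", "V", "F", "W", "Y", "M")] * 0.55
  w / sum(w)
}

# Class-conditional length models: log-normal with the observed means of
# curated phase-separation (~700 aa) and folded reference (~213 aa) sets.
length_params <- function(mean_len, sdlog = 0.6) {
  c(meanlog = log(mean_len) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate labeled synthetic protein sequences
#'
#' Two classes with distinct length and composition models: the positive
#' (phase-separation-like) class draws lengths from a log-normal with mean
#' ~700 aa and a composition enriched in G/P and polar residues; the
#' negative class has mean length ~213 aa and background composition.
#' Per-sequence compositions are Dirichlet-perturbed around the class
#' model, and lengths are clipped to `[min_len, n_max]`.
#'
#' @param n_per_class Sequences per class.
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param n_max Upper clip for sequence length.
#' @param min_len Lower clip for sequence length.
#' @param labels Two class labels, positive first
#'   (default `c("LLPS", "non_LLPS")`; use `c("PS-Self", "PS-Part")` for
#'   mechanism-task fixtures).
#' @param concentration Dirichlet concentration of per-sequence composition
#'   around the class model (larger = less variation).
#' @return Data frame with columns `id`, `sequence`, `label`.
#' @export
gen_sequences <- function(n_per_class = 100L, seed = 1L, n_max = 5000L,
                          min_len = 50L, labels = c("LLPS", "non_LLPS"),
                          concentration = 150) {
  stopifnot(length(labels) == 2L, n_per_class >= 1L)
  rng <- local_rng(seed)
  models <- list(
    list(label = labels[1], comp = ps_composition(), len = length_params(700)),
    list(label = labels[2], comp = AA_BACKGROUND / sum(AA_BACKGROUND),
         len = length_params(213))
  )
  out <- list()
  for (m in models) {
    lens <- pmin(pmax(round(rng$rlnorm(n_per_class, m$len["meanlog"],
                                       m$len["sdlog"])), min_len), n_max)
    for (i in seq_len(n_per_class)) {
      alpha <- m$comp * concentration
      g <- rng$rgamma(20L, shape = alpha)
      p <- g / sum(g)
      seq_chars <- AA20[rng$sample_int(20L, lens[i], replace = TRUE, prob = p)]
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", m$label), i),
        sequence = paste(seq_chars, collapse = ""),
        label = m$label, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic PSSM / HMM profile pair for one sequence
#'
#' Emulates the statistical shape of real profiles: each row's score is
#' highest at the observed residue's column. PSSM rows are integer log-odds
#' (high at the true residue, noise elsewhere); HMM rows are integer-coded
#' match-state scores `h = round(-1000 * log2(f))` of a Dirichlet frequency
#' vector peaked at the true residue, with near-zero frequencies encoded by
#' the `*` sentinel (`Inf`) so the frequency transform is invertible.
#'
#' @param record One-row data frame with `id` and `sequence`.
#' @param seed Integer seed.
#' @return List with elements `pssm` and `hmm_raw`, both [profile_matrix()].
#' @export
gen_profile_pair <- function(record, seed = 1L) {
  rng <- local_rng(seed)
  chars <- strsplit(record$sequence, "")[[1]]
  L <- length(chars)
  res_col <- match(chars, AA20)
  pssm <- matrix(round(rng$rnorm(L * 20L, mean = -2, sd = 1.2)), nrow = L)
  pssm[cbind(seq_len(L), res_col)] <- pssm[cbind(seq_len(L), res_col)] + 8L
  hmm <- matrix(Inf, nrow = L, ncol = 20L)
  for (i in seq_len(L)) {
    alpha <- rep(0.08, 20L); alpha[res_col[i]] <- 4
    g <- rng$rgamma(20L, shape = alpha)
    f <- g / sum(g)
    keep <- f >= 1e-4
    h <- round(-1000 * log2(f[keep]))
    hmm[i, keep] <- h
  }
  list(
    pssm = profile_matrix(pssm, kind = "pssm", seq_id = record$id),
    hmm_raw = profile_matrix(hmm, kind = "hmm_raw", seq_id = record$id)
  )
}

#' Write synthetic profile fixture files for a record set
#'
#' One `<id>.pssm` (PSI-BLAST ASCII dialect) and one `<id>.hhm` (HHsuite
#' dialect) per sequence, parseable by [read_pssm()] / [read_hhm()].
#'
#' @param records Data frame of sequence records.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `pssm`, `hhm` (file paths),
#'   invisibly.
#' @export
gen_profiles <- function(records, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    pair <- gen_profile_pair(rec, seed = derive_seed(seed, i))
    p_pssm <- file.path(dir, paste0(rec$id, ".pssm"))
    p_hhm <- file.path(dir, paste0(rec$id, ".hhm"))
    write_pssm(pair$pssm, rec$sequence, p_pssm)
    write_hhm(pair$hmm_raw, rec$sequence, p_hhm)
    data.frame(id = rec$id, pssm = p_pssm, hhm = p_hhm,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, paths))
}

derive_seed <- function(seed, i) (as.integer(seed) * 10007L + i) %% 2147483647L

#' Generate a planted-signal feature table
#'
#' Gaussian features for a labeled sample: `n_informative` features whose
#' class means differ by `effect` standard deviations, plus `n_noise`
#' class-independent features. Supports recovery tests of the feature
#' selection pipeline: the returned `informative` names are the ground
#' truth.
#'
#' @param labels 0/1 labels (1 = positive class).
#' @param n_informative Number of signal-carrying features.
#' @param n_noise Number of pure-noise features.
#' @param effect Class-mean shift in standard-deviation units (0 = null).
#' @param seed Integer seed.
#' @param ids Optional row names (defaults to `seq_along(labels)`).
#' @return List with `x` (matrix), `informative` (character vector) and
#'   `labels`.
#' @export
gen_feature_table <- function(labels, n_informative = 10L, n_noise = 90L,
                              effect = 1.5, seed = 1L, ids = NULL) {
  stopifnot(n_informative >= 1L)
  labels <- as.integer(labels)
  n <- length(labels)
  rng <- local_rng(seed)
  inf_names <- sprintf("INF_%03d", seq_len(n_informative))
  noise_names <- if (n_noise > 0) sprintf("NOISE_%03d", seq_len(n_noise)) else character(0)
  x_inf <- matrix(rng$rnorm(n * n_informative), nrow = n) +
    outer(labels, rep(effect, n_informative))
  x_noise <- if (n_noise > 0) matrix(rng$rnorm(n * n_noise), nrow = n) else NULL
  x <- cbind(x_inf, x_noise)
  colnames(x) <- c(inf_names, noise_names)
  rownames(x) <- ids %||% as.character(seq_len(n))
  list(x = x, informative = inf_names, labels = labels)
}

#' Generate a synthetic external-feature provider table
#'
#' Emulates the TSV a batch of third-party phase-separation tools would
#' produce: disorder/LCR/PLD/granule-type scores in `[0, 1]` shifted upward
#' for the positive class, patterning parameters from the built-in
#' simplified calculators, and plausible ranges for the remaining scores.
#'
#' @param records Data frame of labeled sequence records (positive class =
#'   first label encountered unless `positive_label` given).
#' @param seed Integer seed.
#' @param path Optional TSV output path.
#' @param positive_label Label treated as phase-separating.
#' @return Data frame (first column `id`, then the ten provider features).
#'   Written to `path` as TSV when given.
#' @export
gen_provider_table <- function(records, seed = 1L, path = NULL,
                               positive_label = NULL) {
  rng <- local_rng(seed)
  n <- nrow(records)
  pos_label <- positive_label %||% records$label[1]
  is_pos <- as.numeric(records$label == pos_label)
  clamp01 <- function(v) pmin(pmax(v, 0), 1)
  lens <- nchar(records$sequence)
  pat <- t(vapply(records$sequence, patterning_simple, numeric(2)))
  tab <- data.frame(
    id = records$id,
    IDR_fraction = clamp01(0.25 + 0.35 * is_pos + rng$rnorm(n, 0, 0.12)),
    longest_PS_IDR = round(pmax(lens * clamp01(0.1 + 0.25 * is_pos +
                                                 rng$rnorm(n, 0, 0.08)), 0)),
    PS_potential = clamp01(0.3 + 0.3 * is_pos + rng$rnorm(n, 0, 0.12)),
    LCR_score = clamp01(0.2 + 0.3 * is_pos + rng$rnorm(n, 0, 0.1)),
    PLD_forming = clamp01(0.15 + 0.35 * is_pos + rng$rnorm(n, 0, 0.12)),
    granule_propensity = rng$rnorm(n, 0.2 + 0.8 * is_pos, 0.4),
    pipi_score = rng$rnorm(n, 0.5 + 1.2 * is_pos, 0.6),
    PPII_propensity = clamp01(0.35 + 0.1 * is_pos + rng$rnorm(n, 0, 0.08)),
    Kappa = pat[, "kappa_simple"],
    Omega = pat[, "omega_simple"],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Write a miniature AAIndex1-format fixture file
#'
#' A handful of synthetic physicochemical property records in the AAIndex1
#' flat-file dialect, optionally including one record with an `NA` value to
#' exercise the exclusion rule. Accessions are `SYN`-prefixed to mark the
#' file as synthetic.
#'
#' @param path Output path.
#' @param n_props Number of complete property records.
#' @param include_na Also write one record containing an `NA` value.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
gen_aaindex_fixture <- function(path, n_props = 20L, include_na = TRUE,
                                seed = 1L) {
  rng <- local_rng(seed)
  con <- file(path, "w"); on.exit(close(con))
  write_rec <- function(acc, vals) {
    fmt <- ifelse(is.na(vals), "NA", sprintf("%.3f", vals))
    writeLines(c(
      paste("H", acc),
      paste("D synthetic physicochemical property", acc),
      "R",
      "A",
      "* synthetic fixture record",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("   ", paste(sprintf("%7s", fmt[1:10]), collapse = " ")),
      paste0("   ", paste(sprintf("%7s", fmt[11:20]), collapse = " ")),
      "//"
    ), con)
  }
  iline_order <- c(AAINDEX_ROW1, AAINDEX_ROW2)
  for (j in seq_len(n_props)) {
    vals <- round(rng$rnorm(20L, mean = 0, sd = 1), 3)
    names(vals) <- iline_order
    write_rec(sprintf("SYN%05d", j), vals)
  }
  if (include_na) {
    vals <- round(rng$rnorm(20L), 3)
    vals[7] <- NA
    names(vals) <- iline_order
    write_rec(sprintf("SYN%05d", n_props + 1L), vals)
  }
  invisible(path)
}

#' Generate an in-memory dataset for the LLPS network
#'
#' Sequences, profile tensors and multimodal vectors for both classes,
#' ready to train [llps_net()]: class structure enters through sequence
#' length (padding mask), profile composition and the provider features.
#'
#' @param n_per_class Sequences per class.
#' @param n_max Padded tensor length.
#' @param seed Integer seed.
#' @return List with `records`, `evo` (list of [pad_profiles()] tensors),
#'   `mm` (n x 27 multimodal matrix), `y` (0/1, LLPS = 1) and `provider`.
#' @export
gen_task1_dataset <- function(n_per_class = 100L, n_max = 256L, seed = 1L) {
  records <- gen_sequences(n_per_class = n_per_class, seed = seed,
                           n_max = n_max)
  provider <- feature_provider(gen_provider_table(records,
                                                  seed = derive_seed(seed, 9999L)))
  evo <- lapply(seq_len(nrow(records)), function(i) {
    pair <- gen_profile_pair(records[i, ], seed = derive_seed(seed, i))
    pad_profiles(pair$pssm, hmm_transform(pair$hmm_raw), n_max = n_max)
  })
  mm <- feature_table(records, function(r) multimodal_vector(r, provider))
  y <- as.integer(records$label == "LLPS")
  list(records = records, evo = evo, mm = mm, y = y, provider = provider)
}
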