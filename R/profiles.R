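# Evolutionary-profile IO: PSI-BLAST ASCII PSSM and HHsuite .hhm readers
# and writers. Internally every profile is an L x 20 matrix whose columns
# follow the canonical alphabetical residue order; the native column order
# of each dialect is re-mapped at the boundary.

#' Construct a profile matrix
#'
#' @param values Numeric L x 20 matrix.
#' @param kind One of `"pssm"` (log-odds scores), `"hmm_raw"` (HHsuite
#'   integer-coded match-state scores; `Inf` encodes the `*` sentinel for an
#'   unobserved state) or `"hmm_freq"` (match-state frequencies in `[0,1]`).
#' @param seq_id Sequence identifier the profile belongs to.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, kind = c("pssm", "hmm_raw", "hmm_freq"),
                           seq_id = "") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (ncol(values) != 20) {
    stop("profile matrix must have 20 columns, got ", ncol(values),
         call. = FALSE)
  }
  if (kind == "hmm_freq" &&
      (min(values) < 0 || max(values) > 1)) {
    stop("hmm_freq profile values must lie in [0, 1]", call. = FALSE)
  }
  colnames(values) <- AA20
  structure(list(values = values, kind = kind, seq_id = seq_id),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix [", x$kind, "] ", x$seq_id, ": ",
      nrow(x$values), " x 20\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the log-odds block (the first 20 numeric columns) of a
#' PSI-BLAST / POSSUM-style ASCII PSSM and re-maps the columns from the
#' native `ARNDCQEGHILKMFPSTWYV` order to the canonical alphabetical order.
#'
#' @param path Path to the PSSM file.
#' @param seq_id Identifier to attach; defaults to the file base name.
#' @param expected_length Optional sequence length; a mismatch with the row
#'   count raises a consistency error.
#' @return A [profile_matrix()] of kind `"pssm"`.
#' @export
read_pssm <- function(path, seq_id = NULL, expected_length = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  header_at <- find_pssm_header(lines)
  rows <- list(); residues <- character(0)
  for (ln in lines[seq.int(header_at + 1L, length(lines))]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22 || is.na(suppressWarnings(as.integer(tok[1])))) break
    residues <- c(residues, tok[2])
    rows[[length(rows) + 1L]] <- as.numeric(tok[3:22])
  }
  if (!length(rows)) stop("no PSSM rows found in '", path, "'", call. = FALSE)
  values <- do.call(rbind, rows)
  colnames(values) <- PSSM_NATIVE_ORDER
  values <- values[, AA20, drop = FALSE]
  if (!is.null(expected_length) && nrow(values) != expected_length) {
    stop("PSSM '", path, "' has ", nrow(values), " rows but sequence length is ",
         expected_length, call. = FALSE)
  }
  out <- profile_matrix(values, kind = "pssm",
                        seq_id = seq_id %||% sub("\\.[^.]*$", "", basename(path)))
  attr(out, "residues") <- residues
  out
}

find_pssm_header <- function(lines) {
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20 && all(tok[1:20] %in% c(LETTERS))) return(i)
  }
  stop("no PSSM column-header line found", call. = FALSE)
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' Emits the two-block layout read back by [read_pssm()]: the log-odds block
#' in native `ARNDCQEGHILKMFPSTWYV` column order followed by a zero
#' percentage block and two trailing statistics columns.
#'
#' @param profile A [profile_matrix()] of kind `"pssm"`.
#' @param sequence Residue string of matching length (printed in column 2).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, sequence, path) {
  stopifnot(inherits(profile, "profile_matrix"), profile$kind == "pssm")
  values <- profile$values[, PSSM_NATIVE_ORDER, drop = FALSE]
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) != nrow(values)) {
    stop("sequence length does not match profile row count", call. = FALSE)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", PSSM_NATIVE_ORDER), collapse = " "),
           "  ", paste(sprintf("%3s", PSSM_NATIVE_ORDER), collapse = " "))
  ), con)
  for (i in seq_len(nrow(values))) {
    writeLines(paste0(
      sprintf("%5d %s ", i, chars[i]),
      paste(sprintf("%3d", as.integer(round(values[i, ]))), collapse = " "),
      "  ", paste(rep("  0", 20), collapse = " "),
      sprintf("  %5.2f %8.2f", 0, 0)
    ), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read an HHsuite .hhm profile
#'
#' Parses the match-state emission columns of an HHsuite HMM file. The 20
#' emission columns are integer-coded scores `h = -1000 * log2(frequency)`;
#' the `*` sentinel marks an unobserved state and is stored as `Inf`, whose
#' transformed frequency under [hmm_transform()] is exactly 0. HHsuite's
#' column order is already the canonical alphabetical order.
#'
#' @param path Path to a `.hhm` file.
#' @param seq_id Identifier to attach; defaults to the file's `NAME` field.
#' @param expected_length Optional length cross-check.
#' @return A [profile_matrix()] of kind `"hmm_raw"`.
#' @export
read_hhm <- function(path, seq_id = NULL, expected_length = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  name_line <- grep("^NAME ", lines, value = TRUE)
  file_id <- if (length(name_line)) {
    strsplit(trimws(sub("^NAME ", "", name_line[1])), "\\s+")[[1]][1]
  } else sub("\\.[^.]*$", "", basename(path))
  hmm_at <- grep("^HMM\\s", lines)
  if (!length(hmm_at)) stop("no HMM block in '", path, "'", call. = FALSE)
  # Two header lines follow the HMM tag: the transition-state header and the
  # null-model transition line.
  i <- hmm_at[1] + 3L
  rows <- list(); residues <- character(0)
  while (i <= length(lines) && !grepl("^//", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 22) {
      residues <- c(residues, tok[1])
      vals <- tok[3:22]
      num <- suppressWarnings(as.numeric(vals))
      num[vals == "*"] <- Inf
      rows[[length(rows) + 1L]] <- num
    }
    i <- i + 2L  # skip the interleaved transition line
  }
  if (!length(rows)) stop("no match states in '", path, "'", call. = FALSE)
  values <- do.call(rbind, rows)
  if (!is.null(expected_length) && nrow(values) != expected_length) {
    stop("HHM '", path, "' has ", nrow(values), " match states but sequence length is ",
         expected_length, call. = FALSE)
  }
  out <- profile_matrix(values, kind = "hmm_raw", seq_id = seq_id %||% file_id)
  attr(out, "residues") <- residues
  out
}

#' Write an HHM profile in the HHsuite dialect
#'
#' @param profile A [profile_matrix()] of kind `"hmm_raw"` (with `Inf` for
#'   the `*` sentinel).
#' @param sequence Residue string of matching length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hhm <- function(profile, sequence, path) {
  stopifnot(inherits(profile, "profile_matrix"), profile$kind == "hmm_raw")
  values <- profile$values
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) != nrow(values)) {
    stop("sequence length does not match profile row count", call. = FALSE)
  }
  fmt <- function(v) {
    out <- rep("*", length(v))
    fin <- is.finite(v)
    out[fin] <- sprintf("%d", as.integer(round(v[fin])))
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "HHsearch 1.5",
    paste("NAME ", profile$seq_id),
    paste("LENG ", nrow(values), "match states"),
    paste0("HMM    ", paste(AA20, collapse = "\t")),
    paste("      ", "M->M\tM->I\tM->D\tI->M\tI->I\tD->M\tD->D\tNeff\tNeff_I\tNeff_D"),
    paste("      ", paste(rep("0", 10), collapse = "\t"))
  ), con)
  for (i in seq_len(nrow(values))) {
    writeLines(paste0(chars[i], " ", i, "\t",
                      paste(fmt(values[i, ]), collapse = "\t"), "\t", i), con)
    writeLines(paste0("\t", paste(rep("0", 10), collapse = "\t")), con)
  }
  writeLines("//", con)
  invisible(path)
}
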