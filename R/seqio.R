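# Sequence IO: FASTA reading/writing, admission filtering, AAIndex1 parsing.

#' Read protein sequences from a FASTA file
#'
#' Sequence ids are taken from the header up to the first whitespace and
#' residues are uppercased. No alphabet filtering is applied here; use
#' [filter_admissible()] to enforce the admission rules.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `sequence` and `label`
#'   (`NA` unless assigned later), one row per FASTA entry.
#' @seealso [write_fasta()], [filter_admissible()]
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- which(!nzchar(seqs) | !nzchar(ids))
  if (length(bad)) {
    stop("FASTA entry ", bad[1], " ('", names(set)[bad[1]],
         "') has an empty id or sequence", call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), label = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for the sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Filter sequences by the admission rules
#'
#' A sequence is admissible when its length lies in `[min_len, max_len]`
#' and it contains only the 20 canonical residues. Non-canonical letters
#' (`B`, `J`, `O`, `U`, `X`, `Z`, ...) cause rejection rather than silent
#' substitution. Rejection is a result, not an error: the returned object
#' partitions the input and attaches a machine-readable reason per
#' rejected record.
#'
#' @param records Data frame of sequence records (from [read_fasta()] or
#'   [gen_sequences()]).
#' @param min_len,max_len Inclusive length bounds (defaults 50 and 5000).
#' @return List with elements `kept` (admissible records) and `rejected`
#'   (records plus a `reason` column, one of `too_short`, `too_long`,
#'   `invalid_residue`).
#' @export
filter_admissible <- function(records, min_len = 50L, max_len = 5000L) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  len <- nchar(records$sequence)
  valid <- is_canonical(records$sequence)
  reason <- rep(NA_character_, nrow(records))
  reason[!valid] <- "invalid_residue"
  reason[valid & len < min_len] <- "too_short"
  reason[valid & len > max_len] <- "too_long"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Read an AAIndex1 flat file
#'
#' Parses the standard AAIndex1 record format: records delimited by `//`,
#' accession on the `H` line, twenty values on the two lines following the
#' `I` line (residue order `A R N D C Q E G H I` then
#' `L K M F P S T W Y V`). Properties containing any `NA` value are
#' excluded, so the returned table never holds a non-finite value.
#'
#' @param path Path to an AAIndex1-format file.
#' @return An object of class `aaindex_table`: a list with `values`
#'   (20 x P numeric matrix, rows in canonical residue order, columns named
#'   by accession), `dropped` (accessions excluded for NA values) and
#'   `source` (the file name).
#' @export
read_aaindex1 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  recs <- split_aaindex_records(lines)
  cols <- list(); dropped <- character(0)
  for (rec in recs) {
    parsed <- parse_aaindex_record(rec)
    if (is.null(parsed)) next
    if (anyNA(parsed$values)) {
      dropped <- c(dropped, parsed$accession)
      next
    }
    cols[[parsed$accession]] <- parsed$values
  }
  values <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(numeric(0), nrow = 20, ncol = 0)
  }
  rownames(values) <- AA20
  structure(
    list(values = values, dropped = dropped, source = basename(path)),
    class = "aaindex_table"
  )
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat("AAIndex property table (", x$source, ")\n", sep = "")
  cat("  retained properties:", ncol(x$values), "\n")
  if (length(x$dropped)) {
    cat("  dropped (NA values):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

split_aaindex_records <- function(lines) {
  idx <- cumsum(c(TRUE, grepl("^//", lines)[-length(lines)]))
  recs <- split(lines, idx)
  Filter(function(r) any(grepl("^H ", r)), recs)
}

parse_aaindex_record <- function(rec) {
  h <- grep("^H ", rec, value = TRUE)
  if (!length(h)) return(NULL)
  accession <- trimws(sub("^H ", "", h[1]))
  i_at <- grep("^I ", rec)
  if (!length(i_at) || i_at[1] + 2 > length(rec)) {
    stop("truncated AAIndex record '", accession, "'", call. = FALSE)
  }
  vals <- unlist(lapply(rec[i_at[1] + (1:2)], function(l) {
    strsplit(trimws(l), "\\s+")[[1]]
  }))
  if (length(vals) != 20) {
    stop("AAIndex record '", accession, "' has ", length(vals),
         " values, expected 20", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
  if (any(is.na(num) & vals != "NA")) {
    stop("AAIndex record '", accession, "' has unparseable values",
         call. = FALSE)
  }
  # Values arrive in I-line order (two rows of ten); re-map to canonical.
  named <- stats::setNames(num, c(AAINDEX_ROW1, AAINDEX_ROW2))
  list(accession = accession, values = named[AA20])
}
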