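# External-feature provider: phase-separation scores computed by third-party
# tools (disorder predictors, prion-like-domain and granule-propensity
# scorers, CIDER patterning parameters) are consumed, never re-derived.
# Values arrive either as a TSV table keyed by sequence id or as a function.

#' Create an external-feature provider
#'
#' @param source One of: a path to a TSV file (header row = feature names,
#'   first column = sequence id), a data frame / matrix with an `id` column
#'   or row names, or a function `f(ids, feature_names)` returning a numeric
#'   matrix with one row per id.
#' @return An object of class `feature_provider`.
#' @export
feature_provider <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    tab <- utils::read.delim(source, check.names = FALSE,
                             stringsAsFactors = FALSE)
    rownames(tab) <- as.character(tab[[1]])
    tab <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(tab) <- "double"
    structure(list(kind = "table", table = tab), class = "feature_provider")
  } else if (is.data.frame(source) || is.matrix(source)) {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
    if ("id" %in% names(tab)) {
      rownames(tab) <- as.character(tab$id)
      tab$id <- NULL
    }
    tab <- as.matrix(tab)
    storage.mode(tab) <- "double"
    structure(list(kind = "table", table = tab), class = "feature_provider")
  } else if (is.function(source)) {
    structure(list(kind = "function", fun = source), class = "feature_provider")
  } else {
    stop("unsupported provider source", call. = FALSE)
  }
}

#' Query a feature provider
#'
#' @param provider A [feature_provider()].
#' @param ids Character vector of sequence ids.
#' @param feature_names Feature names to retrieve.
#' @return Numeric matrix `length(ids) x length(feature_names)`; for a
#'   single id, a named numeric vector. Missing ids or features raise an
#'   error listing all absentees.
#' @export
provider_lookup <- function(provider, ids, feature_names) {
  stopifnot(inherits(provider, "feature_provider"))
  if (provider$kind == "table") {
    tab <- provider$table
    missing_ids <- setdiff(ids, rownames(tab))
    if (length(missing_ids)) {
      stop("provider is missing ids: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    missing_feats <- setdiff(feature_names, colnames(tab))
    if (length(missing_feats)) {
      stop("provider is missing features: ",
           paste(missing_feats, collapse = ", "), call. = FALSE)
    }
    out <- tab[ids, feature_names, drop = FALSE]
  } else {
    out <- provider$fun(ids, feature_names)
    out <- as.matrix(out)
    if (nrow(out) != length(ids) || ncol(out) != length(feature_names)) {
      stop("provider function returned wrong dimensions", call. = FALSE)
    }
    rownames(out) <- ids; colnames(out) <- feature_names
  }
  if (length(ids) == 1L) {
    stats::setNames(drop(out[1, ]), feature_names)
  } else {
    out
  }
}

#' Zero provider
#'
#' A provider returning 0 for every id and feature — useful for exercising
#' the assembled feature vectors without external scores.
#'
#' @return A [feature_provider()].
#' @export
zero_provider <- function() {
  feature_provider(function(ids, feature_names) {
    matrix(0, nrow = length(ids), ncol = length(feature_names))
  })
}
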