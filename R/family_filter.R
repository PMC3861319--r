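#' Load a gene/protein family-name blacklist
#'
#' Reads a plain-text list (one family name per line; blank lines and `#`
#' comments ignored) and normalizes every name with [normalize_term()].
#' Such lists — e.g. compiled from Wikipedia's protein-family pages — name
#' sets of related genes rather than specific genes and are therefore
#' false positives for identifier-level normalization.
#'
#' @param path Path to the blacklist file (UTF-8).
#' @param stop_words Stop words used for normalization.
#' @return Object of class `family_name_list`: list with `names`, a sorted
#'   character vector of normalized family names. An empty file yields an
#'   empty set with a warning.
#' @export
load_family_list <- function(path, stop_words = gn_stop_words()) {
  if (!file.exists(path)) stop("family blacklist file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  names <- unique(normalize_term(lines, stop_words))
  names <- sort(names[nzchar(names)], method = "radix")
  if (!length(names)) warning("family blacklist '", path, "' is empty")
  structure(list(names = names), class = "family_name_list")
}

#' @export
print.family_name_list <- function(x, ...) {
  cat("Family-name blacklist:", length(x$names), "names\n")
  invisible(x)
}

#' Remove results whose mention is a family name
#'
#' Drops every normalized result whose normalized mention text equals a
#' blacklisted family name — whole-string equality, never substring
#' containment, so a specific gene like "Zinc finger protein 51" survives
#' a blacklist entry "Zinc finger protein". Order is preserved and the
#' filter is idempotent.
#'
#' @param results Decision data frame from [disambiguate_all()] (must
#'   carry a `text` column).
#' @param families A `family_name_list` from [load_family_list()].
#' @param stop_words Stop words used for normalization.
#' @return The surviving subset of `results`.
#' @export
filter_families <- function(results, families,
                            stop_words = gn_stop_words()) {
  if (!nrow(results) || !length(families$names)) return(results)
  norm <- normalize_term(results$text, stop_words)
  out <- results[!(norm %in% families$names), , drop = FALSE]
  rownames(out) <- NULL
  out
}
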