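#' Default stop words for term normalization
#'
#' Short function words considered non-informative when comparing gene names
#' against a synonym lexicon. The default list is deliberately minimal
#' (`of`, `the`, `and`); extend it via the `stop_words` argument of
#' [normalize_term()] and the loaders that accept one.
#'
#' @return Character vector of lower-case stop words.
#' @export
#' @examples
#' gn_stop_words()
gn_stop_words <- function() c("of", "the", "and")

#' Normalize a gene name or context string
#'
#' Canonical form shared by every matcher in the package: lower-case, each
#' hyphen replaced by a single space, whitespace-delimited tokens equal to a
#' stop word (after stripping surrounding punctuation) removed, runs of
#' whitespace collapsed to single spaces, and leading/trailing whitespace
#' stripped. The same normalization is applied symmetrically to lexicon
#' synonyms, mentions and context entities, so that e.g. `"BAT-1"` and
#' `"bat 1"` compare equal. Idempotent.
#'
#' @param raw Character vector of raw strings (may be empty strings).
#' @param stop_words Character vector of lower-case stop words to drop;
#'   defaults to [gn_stop_words()].
#' @return Character vector of normalized strings, same length as `raw`.
#' @export
#' @examples
#' normalize_term("BAT-1")                  # "bat 1"
#' normalize_term("the receptor of TNF")    # "receptor tnf"
normalize_term <- function(raw, stop_words = gn_stop_words()) {
  vapply(as.character(raw), .normalize_one, character(1),
         stop_words = stop_words, USE.NAMES = FALSE)
}

.normalize_one <- function(x, stop_words) {
  if (is.na(x) || !nzchar(x)) return("")
  x <- tolower(x)
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- trimws(x)
  if (!nzchar(x)) return("")
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  # stop-word test strips surrounding punctuation so "of," is still dropped
  bare <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks <- toks[nzchar(toks) & !(bare %in% stop_words)]
  paste(toks, collapse = " ")
}

# Roman numerals 1..20 (lower case); the cap keeps single letters like "c"
# or "l" from being misread as numerals in gene names.
.gn_romans <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x",
                "xi", "xii", "xiii", "xiv", "xv", "xvi", "xvii", "xviii",
                "xix", "xx")

.roman_of <- function(n) {
  if (n >= 1 && n <= 20) .gn_romans[n] else NA_character_
}

.arabic_of <- function(tok) {
  m <- match(tok, .gn_romans)
  if (is.na(m)) NA_integer_ else m
}
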