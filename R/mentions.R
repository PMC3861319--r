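#' Default suffix blocklist for mention pruning
#'
#' Final-token words that mark a tagged span as a gene/protein family or
#' other non-specific name rather than a specific gene (e.g. "SMAD proteins"
#' names a family and carries no single identifier). Compared
#' case-insensitively against the last token of the mention.
#'
#' @return Character vector of lower-case suffix words.
#' @export
gn_suffix_blocklist <- function() {
  c("genes", "proteins", "enzymes", "receptors", "domain", "subunit",
    "cdna", "mrna", "family", "subfamily")
}

#' Default context rules for mention pruning
#'
#' Adjacent-word rules: a mention immediately followed by "cells" most
#' likely names a cell line, and one immediately preceded by "Yeast" hints
#' at a yeast gene; the normalization task targets human genes, so both are
#' pruned. "cells" is matched case-insensitively, "Yeast" with case
#' preserved. Extend or replace via the `context_rules` argument of
#' [prune_mentions()].
#'
#' @return Data frame with columns `position` (`"next"`/`"previous"`),
#'   `word`, `ignore_case`.
#' @export
gn_context_rules <- function() {
  data.frame(position = c("next", "previous"),
             word = c("cells", "Yeast"),
             ignore_case = c(TRUE, FALSE),
             stringsAsFactors = FALSE)
}

#' Read tagged gene mentions from a TSV file
#'
#' Format: `doc_id<TAB>start<TAB>end<TAB>text`, one mention per line, with
#' 0-based half-open character offsets into the abstract.
#'
#' @param path Path to the mention TSV.
#' @return Data frame with columns `doc_id` (character), `start`, `end`
#'   (integer), `text` (character).
#' @export
read_mentions <- function(path) {
  if (!file.exists(path)) stop("mention file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad)) {
    warning("mention line(s) ", paste(bad, collapse = ", "),
            " malformed; skipped")
    f <- f[lengths(f) >= 4L]
  }
  data.frame(doc_id = vapply(f, `[[`, "", 1L),
             start = as.integer(vapply(f, `[[`, "", 2L)),
             end = as.integer(vapply(f, `[[`, "", 3L)),
             text = vapply(f, `[[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Read abstracts from a TSV file
#'
#' Format: `doc_id<TAB>text`, one document per line.
#'
#' @param path Path to the abstract TSV.
#' @return Named character vector: abstract text keyed by document id.
#' @export
read_abstracts <- function(path) {
  if (!file.exists(path)) stop("abstract file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  texts <- vapply(f, function(r) paste(r[-1], collapse = "\t"), character(1))
  stats::setNames(texts, vapply(f, `[[`, "", 1L))
}

#' Validate mention offsets against their abstracts
#'
#' Checks that every mention's 0-based half-open span lies inside its
#' abstract and that the abstract substring equals the mention text.
#'
#' @param mentions Mention data frame (see [read_mentions()]).
#' @param abstracts Named character vector of abstract texts.
#' @return `mentions`, invisibly, if valid; otherwise an error naming the
#'   offending mention.
#' @export
validate_mentions <- function(mentions, abstracts) {
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    txt <- abstracts[[m$doc_id]]
    if (is.null(txt) || is.na(txt)) {
      stop("mention '", m$text, "' refers to unknown document ", m$doc_id)
    }
    if (is.na(m$start) || is.na(m$end) || m$start < 0L || m$end <= m$start ||
        m$end > nchar(txt)) {
      stop("mention '", m$text, "' in document ", m$doc_id,
           " has out-of-range offsets [", m$start, ", ", m$end, ")")
    }
    got <- substr(txt, m$start + 1L, m$end)
    if (!identical(got, m$text)) {
      stop("mention '", m$text, "' in document ", m$doc_id,
           " does not match abstract text at [", m$start, ", ", m$end,
           "): found '", got, "'")
    }
  }
  invisible(mentions)
}

# maximal non-whitespace token adjacent to a span, punctuation stripped;
# `pos` is a 0-based offset: first char after the span, or the span start
.word_after <- function(text, pos) {
  rest <- substring(text, pos + 1L)
  m <- regmatches(rest, regexpr("^[[:space:]]*[^[:space:]]+", rest))
  if (!length(m)) return("")
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", trimws(m))
}

.word_before <- function(text, pos) {
  if (pos <= 0L) return("")
  head <- substring(text, 1L, pos)
  m <- regmatches(head, regexpr("[^[:space:]]+[[:space:]]*$", head))
  if (!length(m)) return("")
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", trimws(m))
}

#' Prune false-positive gene mentions
#'
#' Applies the pre-matching false-positive rules to the tagged mentions of
#' one abstract: a mention is removed when (a) its final token is in the
#' suffix blocklist (family-style names such as "... proteins"), (b) the
#' word immediately after its span matches a `next`-position context rule
#' (e.g. "cells"), or (c) the word immediately before its span matches a
#' `previous`-position rule (e.g. "Yeast"). Order is preserved; the result
#' is always a subset of the input and pruning is idempotent.
#'
#' @param mentions Mention data frame for a single document.
#' @param abstract_text The document's abstract text.
#' @param suffix_blocklist Lower-case final-token blocklist; defaults to
#'   [gn_suffix_blocklist()].
#' @param context_rules Adjacent-word rules; defaults to
#'   [gn_context_rules()].
#' @return The surviving subset of `mentions`.
#' @export
prune_mentions <- function(mentions, abstract_text,
                           suffix_blocklist = gn_suffix_blocklist(),
                           context_rules = gn_context_rules()) {
  if (!nrow(mentions)) return(mentions)
  validate_mentions(mentions,
                    stats::setNames(rep(abstract_text,
                                        length(unique(mentions$doc_id))),
                                    unique(mentions$doc_id)))
  suffix_blocklist <- tolower(suffix_blocklist)
  keep <- vapply(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, ]
    toks <- strsplit(trimws(m$text), "[[:space:]]+")[[1]]
    if (length(toks)) {
      last <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "",
                           toks[[length(toks)]]))
      if (last %in% suffix_blocklist) return(FALSE)
    }
    for (r in seq_len(nrow(context_rules))) {
      rule <- context_rules[r, ]
      adj <- if (rule$position == "next") {
        .word_after(abstract_text, m$end)
      } else {
        .word_before(abstract_text, m$start)
      }
      hit <- if (isTRUE(rule$ignore_case)) {
        tolower(adj) == tolower(rule$word)
      } else {
        adj == rule$word
      }
      if (hit) return(FALSE)
    }
    TRUE
  }, logical(1))
  mentions[keep, , drop = FALSE]
}

#' Pair long forms with their bracketed abbreviations
#'
#' Finds every pair of tagged mentions where the second ("short form") sits
#' inside parentheses immediately after the first ("long form") — only
#' whitespace and the opening bracket between the two spans, and a closing
#' bracket (after optional whitespace) right after the short form — and
#' every alphabetic character of the short form occurs, in order, in the
#' long form (case-insensitive ordered-subsequence test). Such pairs share
#' candidate identifiers downstream in both directions.
#'
#' @param mentions Mention data frame for a single document.
#' @param abstract_text The document's abstract text.
#' @return Data frame with one row per pair: `doc_id`, `long_start`,
#'   `long_end`, `long_text`, `short_start`, `short_end`, `short_text`.
#' @export
pair_abbreviations <- function(mentions, abstract_text) {
  empty <- data.frame(doc_id = character(0),
                      long_start = integer(0), long_end = integer(0),
                      long_text = character(0),
                      short_start = integer(0), short_end = integer(0),
                      short_text = character(0), stringsAsFactors = FALSE)
  n <- nrow(mentions)
  if (n < 2L) return(empty)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      long <- mentions[i, ]
      short <- mentions[j, ]
      if (short$start <= long$end) next
      gap <- substr(abstract_text, long$end + 1L, short$start)
      if (!grepl("^[[:space:]]*\\($", gap)) next
      rest <- substring(abstract_text, short$end + 1L)
      if (!grepl("^[[:space:]]*\\)", rest)) next
      if (!.letters_subsequence(short$text, long$text)) next
      out[[length(out) + 1L]] <- data.frame(
        doc_id = long$doc_id,
        long_start = long$start, long_end = long$end, long_text = long$text,
        short_start = short$start, short_end = short$end,
        short_text = short$text, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# do the alphabetic characters of `short` occur, in order, in `long`?
.letters_subsequence <- function(short, long) {
  s <- strsplit(gsub("[^a-z]", "", tolower(short)), "")[[1]]
  l <- strsplit(tolower(long), "")[[1]]
  if (!length(s)) return(FALSE)
  pos <- 0L
  for (ch in s) {
    found <- FALSE
    while (pos < length(l)) {
      pos <- pos + 1L
      if (l[[pos]] == ch) {
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}
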