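#' Generate orthographic variants of a gene name
#'
#' Expands a name into the set of spelling variants used for exact
#' dictionary lookup: the normalized form itself, space-deleted forms
#' (each internal space removed singly, and all removed), space-inserted
#' forms at every letter-digit boundary, and forms with each standalone
#' Arabic numeral 1-20 replaced by its Roman numeral and vice versa. The
#' transformations are closed over each other (e.g. `"ABC 1"` also yields
#' `"abc1"` and `"abc i"`); everything is lower-case because matching is
#' case-insensitive. The set always contains `normalize_term(name)`.
#'
#' @param name Non-empty string.
#' @param stop_words Stop words used for normalization.
#' @param max_variants Safety cap on the closure size.
#' @return Character vector of variant strings (sorted, unique).
#' @export
#' @examples
#' generate_variants("ABC 1")  # includes "abc1" and "abc i"
generate_variants <- function(name, stop_words = gn_stop_words(),
                              max_variants = 64L) {
  base <- normalize_term(name, stop_words)
  seen <- character(0)
  queue <- base
  while (length(queue) && length(seen) < max_variants) {
    s <- queue[[1]]
    queue <- queue[-1]
    if (s %in% seen) next
    seen <- c(seen, s)
    fresh <- unique(c(.space_deletions(s), .digit_boundary_spacings(s),
                      .roman_arabic_swaps(s)))
    queue <- c(queue, setdiff(fresh, c(seen, queue)))
  }
  sort(unique(seen), method = "radix")
}

.space_deletions <- function(s) {
  pos <- which(strsplit(s, "")[[1]] == " ")
  if (!length(pos)) return(character(0))
  single <- vapply(pos, function(p) {
    paste0(substr(s, 1L, p - 1L), substring(s, p + 1L))
  }, character(1))
  unique(c(single, gsub(" ", "", s, fixed = TRUE)))
}

.digit_boundary_spacings <- function(s) {
  a <- gsub("([a-z])([0-9])", "\\1 \\2", s)
  b <- gsub("([0-9])([a-z])", "\\1 \\2", s)
  both <- gsub("([0-9])([a-z])", "\\1 \\2", a)
  setdiff(unique(c(a, b, both)), s)
}

.roman_arabic_swaps <- function(s) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (!length(toks)) return(character(0))
  out <- character(0)
  for (k in seq_along(toks)) {
    tok <- toks[[k]]
    repl <- NULL
    if (grepl("^[0-9]+$", tok)) {
      n <- as.integer(tok)
      if (n >= 1L && n <= 20L) repl <- .roman_of(n)
    } else if (tok %in% .gn_romans) {
      repl <- as.character(.arabic_of(tok))
    }
    if (!is.null(repl)) {
      t2 <- toks
      t2[[k]] <- repl
      out <- c(out, paste(t2, collapse = " "))
    }
  }
  unique(out)
}

# canonical empty candidate table
.empty_candidates <- function() {
  data.frame(gene_id = character(0), matched_synonym = character(0),
             method = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# sort candidates by descending score then ascending (numeric-aware) gene id
.sort_candidates <- function(cand) {
  if (!nrow(cand)) return(cand)
  num <- suppressWarnings(as.numeric(cand$gene_id))
  ord <- order(-cand$score, is.na(num), num, cand$gene_id, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Exact dictionary lookup with orthographic variants
#'
#' Looks up every [generate_variants()] form of the mention in the
#' lexicon's inverted index (which is keyed by normalized synonyms), so
#' hyphen/space/Roman-numeral variation and case differences still match
#' exactly. Each hit scores 1.0.
#'
#' @param mention_text Mention surface string.
#' @param lexicon A `synonym_lexicon` from [load_lexicon()].
#' @return Candidate data frame (`gene_id`, `matched_synonym`, `method`,
#'   `score`), one row per distinct gene id; empty when nothing matches.
#' @export
exact_match <- function(mention_text, lexicon) {
  vars <- generate_variants(mention_text, lexicon$stop_words)
  hit_ids <- character(0)
  hit_syn <- character(0)
  for (v in vars) {
    ids <- lexicon$inverted[[v]]
    if (is.null(ids)) next
    new <- setdiff(ids, hit_ids)
    hit_ids <- c(hit_ids, new)
    hit_syn <- c(hit_syn, rep(v, length(new)))
  }
  if (!length(hit_ids)) return(.empty_candidates())
  .sort_candidates(data.frame(gene_id = hit_ids, matched_synonym = hit_syn,
                              method = "exact", score = 1,
                              stringsAsFactors = FALSE))
}

#' Approximate dictionary lookup by Jaro-Winkler similarity
#'
#' Brute-force scan: computes the Jaro-Winkler similarity between the
#' normalized mention and every normalized synonym in the lexicon, keeps
#' per gene id the best-scoring synonym, and returns the ids whose best
#' score reaches `threshold`, sorted by descending score then ascending
#' gene id and capped at `top_k`. Intended as a fallback for mentions with
#' no exact match.
#'
#' @inheritParams exact_match
#' @param threshold Minimum similarity in (0, 1].
#' @param top_k Maximum number of candidate ids returned.
#' @return Candidate data frame as in [exact_match()], `method` set to
#'   `"approximate"`.
#' @export
approximate_match <- function(mention_text, lexicon, threshold = 0.9,
                              top_k = 10L) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("approximate_match(): threshold must be in (0, 1]")
  }
  q <- normalize_term(mention_text, lexicon$stop_words)
  keys <- names(lexicon$inverted)
  if (!nzchar(q) || !length(keys)) return(.empty_candidates())
  sims <- vapply(keys, function(k) jaro_winkler(q, k), numeric(1),
                 USE.NAMES = FALSE)
  keep <- which(sims >= threshold)
  if (!length(keep)) return(.empty_candidates())
  best_score <- list()
  best_syn <- list()
  for (i in keep) {
    for (id in lexicon$inverted[[keys[[i]]]]) {
      if (is.null(best_score[[id]]) || sims[[i]] > best_score[[id]]) {
        best_score[[id]] <- sims[[i]]
        best_syn[[id]] <- keys[[i]]
      }
    }
  }
  ids <- names(best_score)
  cand <- .sort_candidates(data.frame(
    gene_id = ids,
    matched_synonym = unlist(best_syn[ids], use.names = FALSE),
    method = "approximate",
    score = unlist(best_score[ids], use.names = FALSE),
    stringsAsFactors = FALSE))
  utils::head(cand, top_k)
}

#' Match a set of mentions against the lexicon
#'
#' Runs [exact_match()] on every mention and, when enabled, falls back to
#' [approximate_match()] for mentions with no exact hit.
#'
#' @param mentions Mention data frame (possibly spanning documents).
#' @param lexicon A `synonym_lexicon`.
#' @param approximate Use the approximate fallback for exact-match misses?
#' @param threshold,top_k Passed to [approximate_match()].
#' @return List of candidate sets, one per mention, each a list with
#'   `mention` (one-row data frame) and `candidates` (candidate data frame).
#' @export
match_mentions <- function(mentions, lexicon, approximate = TRUE,
                           threshold = 0.9, top_k = 10L) {
  lapply(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, , drop = FALSE]
    cand <- exact_match(m$text, lexicon)
    if (!nrow(cand) && isTRUE(approximate)) {
      cand <- approximate_match(m$text, lexicon, threshold, top_k)
    }
    list(mention = m, candidates = cand)
  })
}

#' Share candidates across long-form/abbreviation pairs
#'
#' For every abbreviation pair, the long form and the short form end up
#' with the union of both candidate lists (per gene id, the higher score
#' and its provenance are kept) — an identifier established for either
#' member carries over to the other, and vice versa.
#'
#' @param candidate_sets Candidate sets from [match_mentions()].
#' @param pairs Abbreviation pairs from [pair_abbreviations()] (rows may
#'   span documents).
#' @return The candidate sets with unified candidate lists.
#' @export
propagate_abbreviations <- function(candidate_sets, pairs) {
  if (is.null(pairs) || !nrow(pairs)) return(candidate_sets)
  key <- vapply(candidate_sets, function(cs) {
    paste(cs$mention$doc_id, cs$mention$start, cs$mention$end, sep = "\r")
  }, character(1))
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    i <- match(paste(p$doc_id, p$long_start, p$long_end, sep = "\r"), key)
    j <- match(paste(p$doc_id, p$short_start, p$short_end, sep = "\r"), key)
    if (is.na(i) || is.na(j)) next
    merged <- .union_candidates(candidate_sets[[i]]$candidates,
                                candidate_sets[[j]]$candidates)
    candidate_sets[[i]]$candidates <- merged
    candidate_sets[[j]]$candidates <- merged
  }
  candidate_sets
}

.union_candidates <- function(a, b) {
  both <- rbind(a, b)
  if (!nrow(both)) return(.empty_candidates())
  # per gene id keep the max score; on ties prefer exact provenance
  pref <- order(-both$score, both$method != "exact")
  both <- both[pref, , drop = FALSE]
  both <- both[!duplicated(both$gene_id), , drop = FALSE]
  .sort_candidates(both)
}
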