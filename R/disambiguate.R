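#' Build per-document entity contexts
#'
#' The disambiguation context of a document is the set of all biomedical
#' named entities detected in its abstract — here, all mentions surviving
#' pruning, including the mention being disambiguated itself — each
#' normalized with [normalize_term()]. Duplicate entity strings are
#' deduplicated by default.
#'
#' @param mentions Mention data frame (all surviving mentions, any number
#'   of documents).
#' @param stop_words Stop words used for normalization.
#' @param dedup Drop duplicate normalized entity strings per document?
#' @return Named list: document id -> list with `doc_id` and `entities`
#'   (character vector of normalized entity strings).
#' @export
build_contexts <- function(mentions, stop_words = gn_stop_words(),
                           dedup = TRUE) {
  out <- list()
  for (doc in unique(mentions$doc_id)) {
    ent <- normalize_term(mentions$text[mentions$doc_id == doc], stop_words)
    ent <- ent[nzchar(ent)]
    if (isTRUE(dedup)) ent <- unique(ent)
    out[[doc]] <- list(doc_id = doc, entities = ent)
  }
  out
}

#' Select one identifier for an ambiguous mention
#'
#' Resolution proceeds in strict precedence order: (1) a single candidate
#' is returned as-is; (2) otherwise, if the gene2pubmed links of the
#' document intersect the candidate ids in exactly one id, that curated
#' link decides; (3) otherwise the candidate whose extended semantic
#' information (gene_info fields) has the highest [semantic_similarity()]
#' to the document's entity context wins. Candidates missing from
#' gene_info score 0. Ties break by ascending numeric gene id, making the
#' decision fully deterministic.
#'
#' @param cand A candidate set: list with `mention` (one-row data frame)
#'   and `candidates` (non-empty candidate data frame).
#' @param context List with `doc_id` and `entities` (see
#'   [build_contexts()]).
#' @param gene_info Gene metadata data frame from [load_gene_info()], or
#'   `NULL` (every candidate then scores 0 and the tie-break decides).
#' @param g2p A `gene2pubmed_index`, or `NULL` to skip rule (2).
#' @param mode Similarity mode, `"munkres"` or `"sum_all"`.
#' @param stop_words Stop words used for normalization.
#' @return One-row data frame (`doc_id`, `start`, `end`, `text`,
#'   `gene_id`, `score`, `decided_by`); `decided_by` is one of
#'   `"unique_candidate"`, `"gene2pubmed"`, `"similarity"`.
#' @export
disambiguate <- function(cand, context, gene_info = NULL, g2p = NULL,
                         mode = c("munkres", "sum_all"),
                         stop_words = gn_stop_words()) {
  mode <- match.arg(mode)
  cc <- cand$candidates
  if (is.null(cc) || !nrow(cc)) {
    stop("disambiguate(): empty candidate set for mention '",
         cand$mention$text, "'")
  }
  if (nrow(cc) == 1L) {
    return(.decision(cand$mention, cc$gene_id[[1]], cc$score[[1]],
                     "unique_candidate"))
  }
  if (!is.null(g2p)) {
    linked <- intersect(cc$gene_id, g2p_lookup(g2p, context$doc_id))
    if (length(linked) == 1L) {
      return(.decision(cand$mention, linked, NA_real_, "gene2pubmed"))
    }
  }
  sims <- vapply(cc$gene_id, function(id) {
    rec <- gene_info_record(gene_info, id)
    if (is.null(rec)) 0 else {
      semantic_similarity(rec, context$entities, mode, stop_words)
    }
  }, numeric(1))
  ids <- cc$gene_id
  num <- suppressWarnings(as.numeric(ids))
  ord <- order(-sims, is.na(num), num, ids, method = "radix")
  best <- ord[[1]]
  .decision(cand$mention, ids[[best]], sims[[best]], "similarity")
}

.decision <- function(mention, gene_id, score, decided_by) {
  data.frame(doc_id = mention$doc_id, start = mention$start,
             end = mention$end, text = mention$text,
             gene_id = gene_id, score = score, decided_by = decided_by,
             stringsAsFactors = FALSE)
}

#' Disambiguate every candidate set of a corpus
#'
#' Applies [disambiguate()] per mention. Mentions with an empty candidate
#' set produce no normalized output and are dropped; output order follows
#' input order. Every document represented in `candidate_sets` must have a
#' context.
#'
#' @param candidate_sets Candidate sets from [match_mentions()] /
#'   [propagate_abbreviations()].
#' @param contexts Named list of contexts from [build_contexts()].
#' @inheritParams disambiguate
#' @return Data frame of decisions, one row per mention with candidates
#'   (see [disambiguate()]).
#' @export
disambiguate_all <- function(candidate_sets, contexts, gene_info = NULL,
                             g2p = NULL, mode = c("munkres", "sum_all"),
                             stop_words = gn_stop_words()) {
  mode <- match.arg(mode)
  rows <- list()
  for (cs in candidate_sets) {
    if (is.null(cs$candidates) || !nrow(cs$candidates)) next
    ctx <- contexts[[cs$mention$doc_id]]
    if (is.null(ctx)) {
      stop("disambiguate_all(): no context for document ",
           cs$mention$doc_id)
    }
    rows[[length(rows) + 1L]] <- disambiguate(cs, ctx, gene_info, g2p,
                                              mode, stop_words)
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), text = character(0),
                      gene_id = character(0), score = numeric(0),
                      decided_by = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
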