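#' Pipeline configuration
#'
#' Bundles the input paths, stage toggles and parameters of a
#' normalization run. The pipeline is deterministic: no configuration
#' field involves randomness, and re-running on identical inputs yields
#' identical output.
#'
#' @param lexicon,abstracts,mentions Required input paths (synonym
#'   lexicon, abstracts TSV, mention TSV).
#' @param gene_info,gene2pubmed,blacklist Optional resource paths.
#' @param approximate Enable the approximate-matching fallback?
#' @param approximate_threshold Jaro-Winkler acceptance threshold.
#' @param top_k Candidate cap for approximate matching.
#' @param mode Disambiguation similarity mode (`"munkres"`/`"sum_all"`).
#' @param use_gene2pubmed Apply the gene2pubmed shortcut (when a
#'   gene2pubmed path is configured)?
#' @param use_filter Apply the family-name blacklist filter? Requires
#'   `blacklist`.
#' @param stop_words,suffix_blocklist,context_rules Normalization and
#'   pruning parameters (see [gn_stop_words()], [gn_suffix_blocklist()],
#'   [gn_context_rules()]).
#' @param dedup_context Deduplicate context entity strings per document?
#' @return Object of class `gn_config`.
#' @export
gn_config <- function(lexicon, abstracts, mentions, gene_info = NULL,
                      gene2pubmed = NULL, blacklist = NULL,
                      approximate = TRUE, approximate_threshold = 0.9,
                      top_k = 10L, mode = c("munkres", "sum_all"),
                      use_gene2pubmed = TRUE, use_filter = TRUE,
                      stop_words = gn_stop_words(),
                      suffix_blocklist = gn_suffix_blocklist(),
                      context_rules = gn_context_rules(),
                      dedup_context = TRUE) {
  mode <- match.arg(mode)
  cfg <- structure(list(
    lexicon = lexicon, abstracts = abstracts, mentions = mentions,
    gene_info = gene_info, gene2pubmed = gene2pubmed,
    blacklist = blacklist, approximate = isTRUE(approximate),
    approximate_threshold = as.numeric(approximate_threshold),
    top_k = as.integer(top_k), mode = mode,
    use_gene2pubmed = isTRUE(use_gene2pubmed),
    use_filter = isTRUE(use_filter), stop_words = stop_words,
    suffix_blocklist = suffix_blocklist, context_rules = context_rules,
    dedup_context = isTRUE(dedup_context)), class = "gn_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  if (cfg$use_filter && is.null(cfg$blacklist)) {
    stop("gn_config(): filtering is enabled but no blacklist path is configured")
  }
  if (cfg$approximate_threshold <= 0 || cfg$approximate_threshold > 1) {
    stop("gn_config(): approximate_threshold must be in (0, 1]")
  }
  invisible(cfg)
}

#' @export
print.gn_config <- function(x, ...) {
  cat("Normalization pipeline configuration\n")
  cat("  lexicon:    ", x$lexicon, "\n")
  cat("  abstracts:  ", x$abstracts, "\n")
  cat("  mentions:   ", x$mentions, "\n")
  cat("  stages: prune -> abbrev -> exact",
      if (x$approximate) "-> approximate" else "",
      "-> disambiguate(", x$mode, ")",
      if (x$use_filter) "-> filter" else "", "\n")
  invisible(x)
}

#' Write / read a pipeline configuration file
#'
#' The configuration round-trips losslessly through a YAML file.
#'
#' @param cfg A `gn_config`.
#' @param path File path.
#' @return `write_gn_config()` returns `path` invisibly;
#'   `read_gn_config()` returns the reconstructed `gn_config`.
#' @export
write_gn_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$context_rules <- lapply(seq_len(nrow(cfg$context_rules)), function(i) {
    as.list(cfg$context_rules[i, ])
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_gn_config
#' @export
read_gn_config <- function(path) {
  lst <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(lst$context_rules, function(r) {
    data.frame(position = r$position, word = r$word,
               ignore_case = r$ignore_case, stringsAsFactors = FALSE)
  }))
  gn_config(lexicon = lst$lexicon, abstracts = lst$abstracts,
            mentions = lst$mentions, gene_info = lst$gene_info,
            gene2pubmed = lst$gene2pubmed, blacklist = lst$blacklist,
            approximate = lst$approximate,
            approximate_threshold = lst$approximate_threshold,
            top_k = lst$top_k, mode = lst$mode,
            use_gene2pubmed = lst$use_gene2pubmed,
            use_filter = lst$use_filter,
            stop_words = unlist(lst$stop_words),
            suffix_blocklist = unlist(lst$suffix_blocklist),
            context_rules = rules, dedup_context = lst$dedup_context)
}

#' Run the normalization pipeline end to end
#'
#' Executes prune -> abbreviation pairing -> exact matching ->
#' (approximate matching) -> disambiguation -> (family filter) over a
#' corpus and returns per-mention decisions, deduplicated
#' identifier-level predictions, and a per-stage mention accounting.
#'
#' @param cfg A [gn_config()].
#' @param dump_dir Optional directory for per-stage intermediate TSV
#'   dumps.
#' @return Object of class `gn_result`: list with `predictions` (data
#'   frame `doc_id`, `gene_id`, `text` — one row per distinct
#'   document/identifier pair), `decisions` (per-mention decision data
#'   frame), and `report` (data frame `stage`, `n_in`, `n_out`).
#' @export
gn_run <- function(cfg, dump_dir = NULL) {
  stopifnot(inherits(cfg, "gn_config"))
  .validate_config(cfg)
  abstracts <- read_abstracts(cfg$abstracts)
  mentions <- read_mentions(cfg$mentions)
  validate_mentions(mentions, abstracts)
  report <- list()
  note <- function(stage, n_in, n_out) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)
  }

  pruned_list <- list()
  pairs_list <- list()
  for (doc in unique(mentions$doc_id)) {
    dm <- mentions[mentions$doc_id == doc, , drop = FALSE]
    pm <- prune_mentions(dm, abstracts[[doc]], cfg$suffix_blocklist,
                         cfg$context_rules)
    pruned_list[[doc]] <- pm
    pairs_list[[doc]] <- pair_abbreviations(pm, abstracts[[doc]])
  }
  pruned <- do.call(rbind, c(pruned_list,
                             list(mentions[0, , drop = FALSE])))
  rownames(pruned) <- NULL
  pairs <- do.call(rbind, pairs_list)
  note("prune", nrow(mentions), nrow(pruned))

  lex <- load_lexicon(cfg$lexicon, cfg$stop_words)
  cand <- match_mentions(pruned, lex, cfg$approximate,
                         cfg$approximate_threshold, cfg$top_k)
  cand <- propagate_abbreviations(cand, pairs)
  n_matched <- sum(vapply(cand, function(cs) nrow(cs$candidates) > 0L,
                          logical(1)))
  note("match", nrow(pruned), n_matched)

  contexts <- build_contexts(pruned, cfg$stop_words, cfg$dedup_context)
  gene_info <- if (!is.null(cfg$gene_info)) load_gene_info(cfg$gene_info)
  g2p <- if (cfg$use_gene2pubmed && !is.null(cfg$gene2pubmed)) {
    load_gene2pubmed(cfg$gene2pubmed)
  }
  decisions <- disambiguate_all(cand, contexts, gene_info, g2p, cfg$mode,
                                cfg$stop_words)
  note("disambiguate", n_matched, nrow(decisions))

  final <- decisions
  if (cfg$use_filter) {
    fam <- load_family_list(cfg$blacklist, cfg$stop_words)
    final <- filter_families(decisions, fam, cfg$stop_words)
    note("filter", nrow(decisions), nrow(final))
  }

  predictions <- final[!duplicated(paste(final$doc_id, final$gene_id,
                                         sep = "\t")),
                       c("doc_id", "gene_id", "text"), drop = FALSE]
  rownames(predictions) <- NULL
  report <- do.call(rbind, report)

  if (!is.null(dump_dir)) {
    if (!dir.exists(dump_dir)) dir.create(dump_dir, recursive = TRUE)
    dump <- function(df, name) {
      utils::write.table(df, file.path(dump_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    dump(pruned, "pruned_mentions.tsv")
    dump(.dump_candidates(cand), "candidates.tsv")
    dump(decisions, "decisions.tsv")
    dump(final, "filtered.tsv")
    dump(report, "stage_report.tsv")
  }
  structure(list(predictions = predictions, decisions = final,
                 report = report), class = "gn_result")
}

.dump_candidates <- function(candidate_sets) {
  rows <- lapply(candidate_sets, function(cs) {
    if (!nrow(cs$candidates)) return(NULL)
    data.frame(doc_id = cs$mention$doc_id, mention = cs$mention$text,
               gene_id = cs$candidates$gene_id,
               method = cs$candidates$method,
               score = cs$candidates$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(0), mention = character(0),
                      gene_id = character(0), method = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.gn_result <- function(x, ...) {
  cat("Gene normalization result:", nrow(x$predictions),
      "predictions in", length(unique(x$predictions$doc_id)),
      "documents\n")
  cat("Stage report:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
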