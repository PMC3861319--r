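#' Load a gene synonym lexicon
#'
#' Reads a tab-separated lexicon (`gene_id<TAB>synonym1<TAB>synonym2...`,
#' one gene per line; a gene id may recur on several lines) and builds both
#' the forward map (gene id to its raw synonyms) and the inverted index
#' (normalized synonym to the set of gene ids carrying it). Synonym keys are
#' normalized with [normalize_term()], so lookup is case-, hyphen- and
#' stop-word-insensitive. Lines with fewer than two non-empty fields are
#' skipped with a warning naming the line number. Entries and index keys are
#' stored in a canonical sorted order, so loading is independent of line
#' order.
#'
#' @param path Path to the lexicon TSV (UTF-8).
#' @param stop_words Stop words used for normalization.
#' @return Object of class `synonym_lexicon`: list with `entries` (named
#'   list gene_id -> character vector of raw synonyms), `inverted` (named
#'   list normalized synonym -> character vector of gene ids) and
#'   `stop_words`.
#' @export
load_lexicon <- function(path, stop_words = gn_stop_words()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2L) {
      warning(sprintf("lexicon line %d has fewer than 2 fields; skipped", i))
      next
    }
    id <- f[[1]]
    entries[[id]] <- unique(c(entries[[id]], f[-1]))
  }
  # canonical order: ids numeric-aware, synonyms lexicographic
  entries <- entries[order_gene_ids(names(entries))]
  entries <- lapply(entries, function(s) sort(s, method = "radix"))
  inverted <- list()
  for (id in names(entries)) {
    keys <- unique(normalize_term(entries[[id]], stop_words))
    for (k in keys[nzchar(keys)]) inverted[[k]] <- c(inverted[[k]], id)
  }
  if (length(inverted)) {
    inverted <- inverted[sort(names(inverted), method = "radix")]
  }
  inverted <- lapply(inverted, function(ids) unique(ids)[order_gene_ids(unique(ids))])
  structure(list(entries = entries, inverted = inverted,
                 stop_words = stop_words),
            class = "synonym_lexicon")
}

#' @export
print.synonym_lexicon <- function(x, ...) {
  cat("Synonym lexicon:", length(x$entries), "gene ids,",
      length(x$inverted), "normalized synonym keys\n")
  invisible(x)
}

# deterministic gene-id ordering: numeric where possible, then lexicographic
order_gene_ids <- function(ids) {
  if (!length(ids)) return(integer(0))
  num <- suppressWarnings(as.numeric(ids))
  order(is.na(num), num, ids, method = "radix")
}

#' Load EntrezGene-style gene_info metadata
#'
#' Reads an NCBI `gene_info`-dialect TSV and keeps, per gene identifier, the
#' four fields used as extended semantic information: Symbol, chromosome,
#' map_location and description. A header line beginning `#` is parsed for
#' column names (matched case-insensitively; `GeneID`/`gene_id` both
#' accepted); without a header the standard NCBI column layout is assumed
#' (GeneID, Symbol, chromosome, map_location, description at positions 2, 3,
#' 7, 8, 9). The NCBI placeholder `-` becomes the empty string. When a gene
#' id occurs on several rows the last row wins, with a warning.
#'
#' @param path Path to the gene_info TSV.
#' @return Data frame with character columns `gene_id`, `symbol`,
#'   `chromosome`, `map_location`, `description`, one row per gene id,
#'   row names set to `gene_id`.
#' @export
load_gene_info <- function(path) {
  if (!file.exists(path)) stop("gene_info file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(.gene_info_frame(character(0), character(0), character(0),
                            character(0), character(0)))
  }
  wanted <- c(gene_id = "gene_id", symbol = "symbol", chromosome = "chromosome",
              map_location = "map_location", description = "description")
  if (startsWith(lines[[1]], "#")) {
    header <- tolower(strsplit(sub("^#[[:space:]]*", "", lines[[1]]),
                               "\t", fixed = TRUE)[[1]])
    header[header == "geneid"] <- "gene_id"
    idx <- match(names(wanted), header)
    if (anyNA(idx)) {
      stop("gene_info is missing required column(s): ",
           paste(names(wanted)[is.na(idx)], collapse = ", "))
    }
    body <- lines[-1]
  } else {
    idx <- c(2L, 3L, 7L, 8L, 9L)  # NCBI gene_info column positions
    body <- lines
  }
  rows <- strsplit(body, "\t", fixed = TRUE)
  get_col <- function(k) {
    vapply(rows, function(r) if (length(r) >= idx[k]) r[[idx[k]]] else "",
           character(1))
  }
  gene_id <- get_col(1L)
  keep <- nzchar(gene_id)
  df <- .gene_info_frame(gene_id[keep], get_col(2L)[keep], get_col(3L)[keep],
                         get_col(4L)[keep], get_col(5L)[keep])
  if (anyDuplicated(df$gene_id)) {
    dups <- unique(df$gene_id[duplicated(df$gene_id)])
    warning("duplicate gene_info rows for gene id(s) ",
            paste(dups, collapse = ", "), "; last row wins")
    df <- df[!duplicated(df$gene_id, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- df$gene_id
  df
}

.gene_info_frame <- function(gene_id, symbol, chromosome, map_location,
                             description) {
  blank <- function(x) ifelse(x == "-", "", x)
  data.frame(gene_id = gene_id, symbol = blank(symbol),
             chromosome = blank(chromosome),
             map_location = blank(map_location),
             description = blank(description),
             stringsAsFactors = FALSE)
}

# one gene's record (one-row data frame), or NULL if absent
gene_info_record <- function(gene_info, gene_id) {
  if (is.null(gene_info)) return(NULL)
  i <- match(gene_id, gene_info$gene_id)
  if (is.na(i)) NULL else gene_info[i, , drop = FALSE]
}

#' Load an EntrezGene-style gene2pubmed index
#'
#' Reads the NCBI `gene2pubmed` dialect (`tax_id<TAB>GeneID<TAB>PubMed_ID`;
#' the tax_id column may be absent, in which case rows are
#' `GeneID<TAB>PubMed_ID`). Header lines beginning `#` are skipped. Builds
#' the reverse index from PubMed id to the set of gene ids annotated to it.
#'
#' @param path Path to the gene2pubmed TSV.
#' @return Object of class `gene2pubmed_index`.
#' @export
load_gene2pubmed <- function(path) {
  if (!file.exists(path)) stop("gene2pubmed file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  links <- list()
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2L) next
    if (length(f) >= 3L) {
      gid <- f[[2]]; pmid <- f[[3]]
    } else {
      gid <- f[[1]]; pmid <- f[[2]]
    }
    links[[pmid]] <- c(links[[pmid]], gid)
  }
  links <- lapply(links, function(ids) unique(ids)[order_gene_ids(unique(ids))])
  gene2pubmed_index(links)
}

#' Construct a gene2pubmed index from a list of links
#'
#' @param links Named list: PubMed id -> character vector of gene ids.
#' @return Object of class `gene2pubmed_index`.
#' @export
gene2pubmed_index <- function(links = list()) {
  structure(list(links = links), class = "gene2pubmed_index")
}

#' Look up the gene ids linked to a PubMed id
#'
#' @param g2p A `gene2pubmed_index`.
#' @param pubmed_id Single PubMed id string.
#' @return Character vector of gene ids; empty (never an error) for an
#'   unknown PubMed id.
#' @export
g2p_lookup <- function(g2p, pubmed_id) {
  ids <- g2p$links[[as.character(pubmed_id)]]
  if (is.null(ids)) character(0) else ids
}

#' @export
print.gene2pubmed_index <- function(x, ...) {
  cat("gene2pubmed index:", length(x$links), "PubMed ids\n")
  invisible(x)
}
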