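#' Specification for a synthetic normalization corpus
#'
#' Describes a toy corpus with planted structure exercising every pipeline
#' stage: a synonym lexicon, gene_info metadata, gene2pubmed links, a
#' family-name blacklist, abstracts with tagged mention spans, and gold
#' annotations (both identifier-level and per-mention). Genes are
#' synthesized from pronounceable stems with numbered symbols
#' (`"BOKAT3"`-style), multiword long names and chromosome/map-location
#' metadata. A subset of genes is grouped under shared alias names; a
#' mention rendered as such an alias is ambiguous, and the generator then
#' plants the true gene's symbol and map location as additional tagged
#' entities in the same abstract, so the intended identifier is always
#' recoverable from the context alone.
#'
#' @param n_genes Number of ordinary genes (family-decoy genes come extra).
#' @param n_docs Number of documents.
#' @param ambiguity_rate Fraction of mention slots rendered as a shared
#'   alias (>= 2 candidate identifiers after exact matching).
#' @param variant_rate Fraction of mention slots rendered as an
#'   orthographic variant (hyphen/space/Roman-numeral/case) of the symbol,
#'   still reachable by exact matching with variants.
#' @param fuzzy_rate Fraction of mention slots rendered as a perturbed
#'   long name reachable only by approximate matching.
#' @param family_rate Per-slot probability of planting an additional
#'   family-name decoy mention (blacklisted; excluded from gold).
#' @param g2p_rate Fraction of documents receiving gene2pubmed links for
#'   their gold genes.
#' @param seed Integer random seed; identical seeds reproduce identical
#'   corpora byte for byte.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 60L, n_docs = 40L, ambiguity_rate = 0.3,
                         variant_rate = 0.3, fuzzy_rate = 0.15,
                         family_rate = 0.1, g2p_rate = 0.2, seed = 1L) {
  rates <- c(ambiguity_rate, variant_rate, fuzzy_rate, family_rate, g2p_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("fixture_spec(): all rates must lie in [0, 1]")
  }
  if (ambiguity_rate + variant_rate + fuzzy_rate > 1) {
    stop("fixture_spec(): ambiguity_rate + variant_rate + fuzzy_rate must not exceed 1")
  }
  if (n_genes < 1L || n_docs < 1L) {
    stop("fixture_spec(): counts must be positive")
  }
  structure(list(n_genes = as.integer(n_genes), n_docs = as.integer(n_docs),
                 ambiguity_rate = ambiguity_rate,
                 variant_rate = variant_rate, fuzzy_rate = fuzzy_rate,
                 family_rate = family_rate, g2p_rate = g2p_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic normalization corpus
#'
#' Writes the full file set consumed by the pipeline (`lexicon.tsv`,
#' `gene_info.tsv`, `gene2pubmed.tsv`, `blacklist.txt`, `abstracts.tsv`,
#' `mentions.tsv`, `gold.tsv`, `gold_mentions.tsv`) plus a `manifest.tsv`
#' with an MD5 checksum per file. See [fixture_spec()] for the planted
#' structure. Generation is fully deterministic given the seed.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Object of class `fixture_manifest`: list with `dir`, `paths`
#'   (named file paths) and `manifest` (data frame `file`, `md5`, `bytes`).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  genes <- .fx_make_genes(spec)
  fam <- .fx_make_families(spec, genes)
  corpus <- .fx_make_docs(spec, genes, fam)

  paths <- c(lexicon = "lexicon.tsv", gene_info = "gene_info.tsv",
             gene2pubmed = "gene2pubmed.tsv", blacklist = "blacklist.txt",
             abstracts = "abstracts.tsv", mentions = "mentions.tsv",
             gold = "gold.tsv", gold_mentions = "gold_mentions.tsv")
  paths <- stats::setNames(file.path(out_dir, paths), names(paths))

  all_genes <- rbind(genes$table, fam$table)
  lex_lines <- vapply(seq_len(nrow(all_genes)), function(i) {
    syns <- unique(c(all_genes$symbol[i], all_genes$long_name[i],
                     strsplit(all_genes$aliases[i], "|", fixed = TRUE)[[1]]))
    syns <- syns[nzchar(syns)]
    paste(c(all_genes$gene_id[i], syns), collapse = "\t")
  }, character(1))
  writeLines(lex_lines, paths[["lexicon"]], useBytes = TRUE)

  gi_header <- "#tax_id\tgene_id\tsymbol\tlocustag\tsynonyms\tdbxrefs\tchromosome\tmap_location\tdescription"
  gi_lines <- paste("9606", all_genes$gene_id, all_genes$symbol, "-", "-",
                    "-", all_genes$chromosome, all_genes$map_location,
                    all_genes$description, sep = "\t")
  writeLines(c(gi_header, gi_lines), paths[["gene_info"]], useBytes = TRUE)

  writeLines(c("#tax_id\tGeneID\tPubMed_ID", corpus$g2p_lines),
             paths[["gene2pubmed"]], useBytes = TRUE)
  writeLines(c("# synthetic protein family names", fam$names),
             paths[["blacklist"]], useBytes = TRUE)
  writeLines(corpus$abstract_lines, paths[["abstracts"]], useBytes = TRUE)
  writeLines(corpus$mention_lines, paths[["mentions"]], useBytes = TRUE)
  writeLines(corpus$gold_lines, paths[["gold"]], useBytes = TRUE)
  writeLines(corpus$gold_mention_lines, paths[["gold_mentions"]],
             useBytes = TRUE)

  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(dir = out_dir, paths = paths, manifest = manifest),
            class = "fixture_manifest")
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat("Synthetic corpus in", x$dir, "—", nrow(x$manifest), "files\n")
  invisible(x)
}

# pronounceable unique upper-case stems, varied first letters
.fx_stems <- function(n, taken = character(0)) {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 100000L) stop("stem generation exhausted")
    s <- paste0(sample(cons, 1), sample(vow, 1), sample(cons, 1),
                sample(vow, 1), sample(cons, 1))
    s <- toupper(s)
    if (!(s %in% c(out, taken))) out <- c(out, s)
  }
  out
}

.fx_middles <- c("mediated kinase", "binding factor", "transport regulator",
                 "signal transducer", "growth modulator", "repair ligase",
                 "membrane anchor", "splicing cofactor")

.fx_map_location <- function(chrom) {
  paste0(chrom, sample(c("p", "q"), 1),
         sample(10:39, 1) / 10)
}

.fx_make_genes <- function(spec) {
  n <- spec$n_genes
  stems <- .fx_stems(n)
  nums <- sample(1:9, n, replace = TRUE)
  middles <- sample(.fx_middles, n, replace = TRUE)
  chroms <- sample(1:22, n, replace = TRUE)
  tab <- data.frame(
    gene_id = as.character(1000L + seq_len(n)),
    stem = stems,
    num = nums,
    symbol = paste0(stems, nums),
    long_name = paste(tolower(stems), middles, nums),
    chromosome = as.character(chroms),
    map_location = vapply(chroms, .fx_map_location, character(1)),
    aliases = "",
    description = "",
    stringsAsFactors = FALSE)
  tab$description <- paste(tab$long_name, "isoform precursor")

  # alias groups of 3 genes sharing a synonym => planted ambiguity
  n_groups <- max(1L, n %/% 10L)
  group_members <- split(seq_len(min(n, 3L * n_groups)),
                         rep(seq_len(n_groups), each = 3L)[seq_len(min(n, 3L * n_groups))])
  group_members <- group_members[lengths(group_members) >= 2L]
  alias_stems <- .fx_stems(length(group_members), taken = stems)
  groups <- list()
  for (k in seq_along(group_members)) {
    idx <- group_members[[k]]
    alias <- paste0(alias_stems[[k]], sample(1:9, 1))
    # within a group, metadata must discriminate: chromosomes with
    # distinct leading digits (so map-location strings of the wrong
    # members share no prefix with the planted one) and distinct
    # long-name templates
    ch <- sample(2:9, length(idx))
    mid <- sample(.fx_middles, length(idx))
    for (q in seq_along(idx)) {
      i <- idx[[q]]
      tab$chromosome[i] <- as.character(ch[[q]])
      tab$map_location[i] <- .fx_map_location(ch[[q]])
      tab$long_name[i] <- paste(tolower(tab$stem[i]), mid[[q]], tab$num[i])
      tab$description[i] <- paste(tab$long_name[i], "isoform precursor")
      tab$aliases[i] <- alias
    }
    groups[[k]] <- list(alias = alias, members = tab$gene_id[idx])
  }
  list(table = tab, groups = groups)
}

.fx_make_families <- function(spec, genes) {
  n_fam <- if (spec$family_rate > 0) {
    max(1L, round(spec$n_genes * spec$family_rate / 2))
  } else 0L
  if (n_fam == 0L) {
    tab <- genes$table[0, , drop = FALSE]
    return(list(names = character(0), table = tab))
  }
  stems <- .fx_stems(n_fam, taken = genes$table$stem)
  shapes <- c("finger protein", "helix factor", "loop kinase",
              "barrel channel")
  fam_names <- paste(tolower(stems), sample(shapes, n_fam, replace = TRUE))
  # each family has one specific member gene: "<family name> <number>"
  nums <- sample(2:9, n_fam, replace = TRUE)
  member <- paste(fam_names, nums)
  chroms <- sample(1:22, n_fam, replace = TRUE)
  tab <- data.frame(
    gene_id = as.character(5000L + seq_len(n_fam)),
    stem = stems,
    num = nums,
    symbol = member,
    long_name = member,
    chromosome = as.character(chroms),
    map_location = vapply(chroms, .fx_map_location, character(1)),
    aliases = "",
    description = paste(member, "specific member"),
    stringsAsFactors = FALSE)
  list(names = fam_names, table = tab)
}

.fx_make_docs <- function(spec, genes, fam) {
  tab <- genes$table
  groups <- genes$groups
  grouped_idx <- which(tab$aliases != "")
  plain_pool <- seq_len(nrow(tab))
  fillers <- c("We examined ", "Expression of ", "Analysis focused on ",
               "The study measured ", "Reporter assays implicated ",
               "Sequencing revealed ", "Immunoblots detected ")
  closers <- c(" in patient samples.", " in transfected lines.",
               " during differentiation.", " under oxidative stress.",
               " across all replicates.", " in the cohort.")

  abstract_lines <- character(0)
  mention_lines <- character(0)
  gold_lines <- character(0)
  gold_mention_lines <- character(0)
  g2p_lines <- character(0)

  for (d in seq_len(spec$n_docs)) {
    doc_id <- as.character(9000000L + d)
    text <- ""
    add <- function(s) text <<- paste0(text, s)
    tag <- function(surface, gene_id) {
      start <- nchar(text)
      add(surface)
      mention_lines <<- c(mention_lines,
                          paste(doc_id, start, start + nchar(surface),
                                surface, sep = "\t"))
      gold_mention_lines <<- c(gold_mention_lines,
                               paste(doc_id, start, start + nchar(surface),
                                     surface,
                                     if (is.na(gene_id)) "-" else gene_id,
                                     sep = "\t"))
      invisible(NULL)
    }

    n_slots <- sample(2:4, 1)
    doc_gold <- character(0)
    used_genes <- integer(0)
    used_groups <- integer(0)
    for (s in seq_len(n_slots)) {
      u <- stats::runif(1)
      # a group is eligible only if none of its members has been mentioned
      # in this document yet (and vice versa below): the planted context
      # must stay discriminating, so no independent evidence for a wrong
      # candidate may coexist with an ambiguous mention of its group
      avail_groups <- setdiff(seq_along(groups), used_groups)
      avail_groups <- avail_groups[vapply(avail_groups, function(k) {
        !any(match(groups[[k]]$members, tab$gene_id) %in% used_genes)
      }, logical(1))]
      if (u < spec$ambiguity_rate && length(avail_groups)) {
        # ambiguous slot: mention = shared alias; plant the true gene's
        # symbol and map location as context entities
        gk <- if (length(avail_groups) == 1L) avail_groups else {
          sample(avail_groups, 1)
        }
        used_groups <- c(used_groups, gk)
        g <- groups[[gk]]
        true_id <- sample(g$members, 1)
        i <- match(true_id, tab$gene_id)
        used_genes <- c(used_genes, match(g$members, tab$gene_id))
        add(sample(fillers, 1))
        tag(g$alias, true_id)
        add(sample(closers, 1))
        add(" The locus maps to ")
        tag(tab$map_location[i], true_id)
        add(" near ")
        tag(tab$symbol[i], true_id)
        add(", encoding ")
        tag(tab$long_name[i], true_id)
        add(". ")
        doc_gold <- c(doc_gold, true_id)
        used_genes <- c(used_genes, i)
        next
      }
      avail <- setdiff(plain_pool, used_genes)
      if (!length(avail)) next
      i <- if (length(avail) == 1L) avail else sample(avail, 1)
      used_genes <- c(used_genes, i)
      add(sample(fillers, 1))
      if (u < spec$ambiguity_rate + spec$fuzzy_rate) {
        # fuzzy slot: perturbed long name, approximate matching only
        toks <- strsplit(tab$long_name[i], " ", fixed = TRUE)[[1]]
        toks[[length(toks) - 1L]] <- paste0(toks[[length(toks) - 1L]], "s")
        tag(paste(toks, collapse = " "), tab$gene_id[i])
      } else if (u < spec$ambiguity_rate + spec$fuzzy_rate +
                 spec$variant_rate) {
        surface <- switch(sample(4L, 1),
                          paste0(tab$stem[i], "-", tab$num[i]),
                          paste(tab$stem[i], tab$num[i]),
                          paste(tab$stem[i], toupper(.roman_of(tab$num[i]))),
                          tolower(tab$symbol[i]))
        tag(surface, tab$gene_id[i])
      } else if (stats::runif(1) < 0.2) {
        # long form with bracketed abbreviation
        tag(tab$long_name[i], tab$gene_id[i])
        add(" (")
        tag(tab$symbol[i], tab$gene_id[i])
        add(")")
      } else {
        tag(tab$symbol[i], tab$gene_id[i])
      }
      add(sample(closers, 1))
      add(" ")
      doc_gold <- c(doc_gold, tab$gene_id[i])
    }

    # family-name decoys: blacklisted surfaces that only approximate
    # matching can (wrongly) link to the specific member gene
    if (length(fam$names)) {
      n_decoy <- stats::rbinom(1, n_slots, spec$family_rate)
      for (k in seq_len(n_decoy)) {
        fname <- sample(fam$names, 1)
        add("Members of the ")
        tag(fname, NA)
        add(" class were reviewed. ")
      }
    }
    # occasional pre-matching false positives exercising the pruning rules
    if (stats::runif(1) < 0.15) {
      decoy <- paste0(.fx_stems(1, taken = tab$stem), " proteins")
      add("Broadly, ")
      tag(decoy, NA)
      add(" were dysregulated. ")
    }
    if (stats::runif(1) < 0.15) {
      decoy <- .fx_stems(1, taken = tab$stem)
      add("Cultured ")
      tag(decoy, NA)
      add(" cells served as control. ")
    }

    abstract_lines <- c(abstract_lines, paste(doc_id, text, sep = "\t"))
    doc_gold <- unique(doc_gold)
    gold_lines <- c(gold_lines, paste(doc_id, doc_gold, sep = "\t"))
    if (stats::runif(1) < spec$g2p_rate && length(doc_gold)) {
      g2p_lines <- c(g2p_lines,
                     paste("9606", doc_gold, doc_id, sep = "\t"))
    }
  }
  list(abstract_lines = abstract_lines, mention_lines = mention_lines,
       gold_lines = gold_lines, gold_mention_lines = gold_mention_lines,
       g2p_lines = g2p_lines)
}
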