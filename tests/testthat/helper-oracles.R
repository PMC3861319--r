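# independent brute-force oracle for the assignment problem: enumerate all
# permutations of the padded square matrix and take the best total
perm_matrix <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1L) matrix(1L, 1, 1) else {
      prev <- perm_matrix(n - 1L)
      do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, prev + (prev >= k))
      }))
    }
    cache[[key]] <<- p
    p
  }
})

brute_force_max_assignment <- function(w) {
  nr <- nrow(w)
  nc <- ncol(w)
  n <- max(nr, nc)
  pw <- matrix(0, n, n)
  pw[seq_len(nr), seq_len(nc)] <- w
  P <- perm_matrix(n)
  # linear indices of cell (row i, column P[r, i]) for every permutation r
  idx <- matrix(rep(seq_len(n), each = nrow(P)), nrow(P)) + (P - 1L) * n
  max(rowSums(matrix(pw[as.vector(idx)], nrow(P))))
}

rand_string <- function(len, alphabet = letters[1:8]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# write lines to a throwaway file and return its path
tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f, useBytes = TRUE)
  f
}

# tiny two-gene lexicon used across matching tests
tiny_lexicon <- function() {
  load_lexicon(tmp_lines(c(
    "7919\tBAT-1\tHLA-B associated transcript 1",
    "10212\tBAT1L\tDDX39",
    "6046\tABC 1\tABC transporter 1",
    "6047\tserum/glucocorticoid regulated kinase")))
}

# one-document corpus written to files, for pipeline-level tests
write_tiny_corpus <- function(dir = tempfile("corpus")) {
  dir.create(dir)
  #                     0         1         2         3
  #                     0123456789012345678901234567890123456789
  text <- "We studied BAT-1 at 6p21.3 and SMAD proteins in HeLa cells."
  stopifnot(substr(text, 12, 16) == "BAT-1")
  paths <- list(
    abstracts = file.path(dir, "abstracts.tsv"),
    mentions = file.path(dir, "mentions.tsv"),
    lexicon = file.path(dir, "lexicon.tsv"),
    gene_info = file.path(dir, "gene_info.tsv"),
    blacklist = file.path(dir, "blacklist.txt"))
  writeLines(paste("101", text, sep = "\t"), paths$abstracts)
  writeLines(c("101\t11\t16\tBAT-1",
               "101\t31\t44\tSMAD proteins",
               "101\t48\t52\tHeLa"),
             paths$mentions)
  writeLines("7919\tBAT1\tHLA-B associated transcript 1", paths$lexicon)
  writeLines(c("#tax_id\tgene_id\tsymbol\tlocustag\tsynonyms\tdbxrefs\tchromosome\tmap_location\tdescription",
               "9606\t7919\tBAT1\t-\t-\t-\t6\t6p21.3\tHLA-B associated transcript 1"),
             paths$gene_info)
  writeLines("Zinc finger protein", paths$blacklist)
  paths
}
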