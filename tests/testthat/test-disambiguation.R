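mk_candset <- function(ids, text = "M1", doc = "d1", scores = 1) {
  cand <- data.frame(gene_id = ids,
                     matched_synonym = rep(tolower(text), length(ids)),
                     method = rep("exact", length(ids)),
                     score = rep(scores, length.out = length(ids)),
                     stringsAsFactors = FALSE)
  list(mention = data.frame(doc_id = doc, start = 0L, end = nchar(text),
                            text = text, stringsAsFactors = FALSE),
       candidates = cand)
}

mk_ctx <- function(entities, doc = "d1") {
  list(doc_id = doc, entities = normalize_term(entities))
}

test_that("rule precedence is unique -> gene2pubmed -> similarity", {
  gi <- data.frame(gene_id = c("5", "9"), symbol = c("AAA1", "BBB2"),
                   chromosome = c("1", "2"), map_location = c("1p1", "2q2"),
                   description = c("aaa factor", "bbb factor"),
                   stringsAsFactors = FALSE)
  ctx <- mk_ctx(c("m1", "bbb2", "2q2"))
  # (1) single candidate wins regardless of resources
  one <- disambiguate(mk_candset("5"), ctx, gi,
                      gene2pubmed_index(list(d1 = "9")))
  expect_identical(one$gene_id, "5")
  expect_identical(one$decided_by, "unique_candidate")
  # (2) singleton gene2pubmed intersection beats similarity
  two <- disambiguate(mk_candset(c("5", "9")), ctx, gi,
                      gene2pubmed_index(list(d1 = "5")))
  expect_identical(two$gene_id, "5")
  expect_identical(two$decided_by, "gene2pubmed")
  # (3) non-singleton intersection falls through to similarity
  three <- disambiguate(mk_candset(c("5", "9")), ctx, gi,
                        gene2pubmed_index(list(d1 = c("5", "9"))))
  expect_identical(three$gene_id, "9")
  expect_identical(three$decided_by, "similarity")
  # without g2p the similarity argmax decides the same way
  expect_identical(disambiguate(mk_candset(c("5", "9")), ctx, gi)$gene_id, "9")
  expect_error(disambiguate(mk_candset(character(0)), ctx, gi), "empty")
})

test_that("missing gene_info records score zero and ties break numerically", {
  ctx <- mk_ctx("nothing shared")
  # no gene_info at all: every candidate scores 0, lowest numeric id wins
  res <- disambiguate(mk_candset(c("30", "4")), ctx, gene_info = NULL)
  expect_identical(res$gene_id, "4")
  expect_identical(res$score, 0)
})

test_that("the BAT1 worked example resolves to 7919", {
  ex <- bat1_example()
  for (mode in c("munkres", "sum_all")) {
    res <- disambiguate(ex$candidates, ex$context, ex$gene_info, mode = mode)
    expect_identical(res$gene_id, "7919")
  }
  munk <- disambiguate(ex$candidates, ex$context, ex$gene_info)
  expect_identical(munk$decided_by, "similarity")
  expect_gte(munk$score, 2)  # symbol and map location match exactly
})

test_that("disambiguate_all drops empty sets, keeps order, needs contexts", {
  ctx <- list(d1 = mk_ctx("m1"))
  sets <- list(mk_candset("5", text = "M1"),
               mk_candset(character(0), text = "M2"),
               mk_candset("7", text = "M3"))
  out <- disambiguate_all(sets, ctx)
  expect_identical(out$gene_id, c("5", "7"))
  expect_identical(unique(out$decided_by), "unique_candidate")
  expect_identical(nrow(disambiguate_all(list(), ctx)), 0L)
  orphan <- list(mk_candset("5", doc = "other"))
  expect_error(disambiguate_all(orphan, ctx), "no context")
})

test_that("planted ambiguity is fully recovered on a synthetic corpus", {
  dir <- tempfile("planted")
  man <- generate_fixture(fixture_spec(n_genes = 40, n_docs = 25,
                                       ambiguity_rate = 0.5,
                                       fuzzy_rate = 0, seed = 7L), dir)
  ab <- read_abstracts(man$paths[["abstracts"]])
  mn <- read_mentions(man$paths[["mentions"]])
  lex <- load_lexicon(man$paths[["lexicon"]])
  gi <- load_gene_info(man$paths[["gene_info"]])
  pruned <- do.call(rbind, lapply(unique(mn$doc_id), function(d) {
    prune_mentions(mn[mn$doc_id == d, ], ab[[d]])
  }))
  cand <- match_mentions(pruned, lex)
  ctx <- build_contexts(pruned)
  truth <- utils::read.delim(man$paths[["gold_mentions"]], header = FALSE,
                             col.names = c("doc_id", "start", "end", "text",
                                           "gene_id"),
                             colClasses = "character")
  amb <- vapply(cand, function(cs) nrow(cs$candidates) >= 2L, logical(1))
  expect_gt(sum(amb), 10)
  dec <- disambiguate_all(cand[amb], ctx, gi, NULL, mode = "munkres")
  key <- paste(dec$doc_id, dec$start, dec$end)
  want <- truth$gene_id[match(key, paste(truth$doc_id, truth$start,
                                         truth$end))]
  expect_identical(dec$gene_id, want)
  # determinism: identical inputs give identical decisions
  dec2 <- disambiguate_all(cand[amb], ctx, gi, NULL, mode = "munkres")
  expect_identical(dec, dec2)
})
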