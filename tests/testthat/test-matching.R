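test_that("variant generation covers spacing and Roman/Arabic rules", {
  v <- generate_variants("ABC 1")
  expect_true(all(c("abc 1", "abc1", "abc i") %in% v))
  expect_identical(generate_variants("TNF"), "tnf")
  expect_true("type 4 collagen" %in% generate_variants("type IV collagen"))
  expect_true("bat 1" %in% generate_variants("BAT-1"))
  # normalized input always a member; closure includes digit-boundary split
  expect_true("bat1" %in% generate_variants("BAT-1"))
  expect_true("bat i" %in% generate_variants("BAT1"))
})

test_that("exact matching finds ids through variants, case-insensitively", {
  lex <- tiny_lexicon()
  hit <- exact_match("BAT-1", lex)
  expect_identical(hit$gene_id, "7919")
  expect_identical(hit$method, "exact")
  expect_identical(hit$score, 1)
  expect_identical(nrow(exact_match("zzz", lex)), 0L)
  expect_identical(exact_match("abc1", lex)$gene_id, "6046")
  expect_identical(exact_match("ABC I", lex)$gene_id, "6046")
})

test_that("exact matching is symmetric under variants and unions ids", {
  lex <- load_lexicon(tmp_lines(c("1\tGSY 2", "2\tGSY2", "9\tGSY II")))
  hits <- exact_match("GSY-2", lex)
  expect_setequal(hits$gene_id, c("1", "2", "9"))
  # candidate-set invariants: unique ids, sorted by score then id
  expect_false(any(duplicated(hits$gene_id)))
  expect_identical(hits$gene_id, c("1", "2", "9"))
})

test_that("approximate matching scores against every synonym", {
  lex <- tiny_lexicon()
  hit <- approximate_match("serum- and glucocorticoid-induced protein kinase",
                           lex, threshold = 0.75)
  expect_identical(hit$gene_id[[1]], "6047")
  expect_identical(hit$method[[1]], "approximate")
  # identical string at threshold 1.0
  self <- approximate_match("DDX39", lex, threshold = 1)
  expect_identical(self$gene_id, "10212")
  expect_equal(self$score, 1)
  expect_identical(nrow(approximate_match("qqqq", lex, threshold = 1)), 0L)
  expect_error(approximate_match("x", lex, threshold = 0), "threshold")
})

test_that("approximate matching is monotone in the threshold", {
  lex <- load_lexicon(tmp_lines(paste0(1:30, "\t",
                                       c(outer(c("kin", "rec", "fac"),
                                               1:10, paste0)))))
  set.seed(55)
  for (q in c("kin1", "kinn2", "rec 3", "facc10", "xyz")) {
    lo <- approximate_match(q, lex, threshold = 0.7)
    hi <- approximate_match(q, lex, threshold = 0.92)
    expect_true(all(hi$gene_id %in% lo$gene_id))
  }
})

test_that("abbreviation propagation unifies candidate sets both ways", {
  lex <- tiny_lexicon()
  mentions <- data.frame(doc_id = "d", start = c(0L, 30L), end = c(20L, 34L),
                         text = c("HLA-B associated transcript 1", "BAT1L"),
                         stringsAsFactors = FALSE)
  mentions$end <- mentions$start + nchar(mentions$text)
  cand <- match_mentions(mentions, lex, approximate = FALSE)
  expect_identical(cand[[1]]$candidates$gene_id, "7919")
  expect_identical(cand[[2]]$candidates$gene_id, "10212")
  pairs <- data.frame(doc_id = "d", long_start = 0L,
                      long_end = mentions$end[[1]],
                      long_text = mentions$text[[1]],
                      short_start = 30L, short_end = mentions$end[[2]],
                      short_text = "BAT1L", stringsAsFactors = FALSE)
  out <- propagate_abbreviations(cand, pairs)
  expect_setequal(out[[1]]$candidates$gene_id, c("7919", "10212"))
  expect_identical(out[[1]]$candidates, out[[2]]$candidates)
  # empty-with-empty stays empty; propagation without pairs is identity
  expect_identical(propagate_abbreviations(cand, pairs[0, ]), cand)
})

test_that("match_mentions falls back to approximate only on exact misses", {
  lex <- tiny_lexicon()
  mentions <- data.frame(doc_id = "d", start = 0L, end = 5L,
                         text = "DDX39x", stringsAsFactors = FALSE)
  with_fallback <- match_mentions(mentions, lex, approximate = TRUE,
                                  threshold = 0.9)
  expect_identical(with_fallback[[1]]$candidates$method, "approximate")
  without <- match_mentions(mentions, lex, approximate = FALSE)
  expect_identical(nrow(without[[1]]$candidates), 0L)
})
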