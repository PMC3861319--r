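mk_mentions <- function(text, surfaces, doc = "d1") {
  rows <- lapply(surfaces, function(s) {
    start <- as.integer(regexpr(s, text, fixed = TRUE)[[1]]) - 1L
    stopifnot(start >= 0L)
    data.frame(doc_id = doc, start = start, end = start + nchar(s),
               text = s, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("pruning removes family suffixes and context-rule hits", {
  text <- "Yeast SGK1 and SMAD proteins affect BAT1 while HeLa cells divide."
  m <- mk_mentions(text, list("SGK1", "SMAD proteins", "BAT1", "HeLa"))
  kept <- prune_mentions(m, text)
  expect_identical(kept$text, "BAT1")
  # subset, order preserved, idempotent
  expect_true(all(kept$text %in% m$text))
  expect_identical(prune_mentions(kept, text), kept)
})

test_that("pruning rules are configurable and case handling is honoured", {
  text <- "The yeast ABC1 data and TNF receptors were compared."
  m <- mk_mentions(text, list("ABC1", "TNF receptors"))
  # default rule is case-preserving "Yeast": lower-case "yeast" passes
  kept <- prune_mentions(m, text)
  expect_identical(kept$text, "ABC1")
  rules <- data.frame(position = "previous", word = "yeast",
                      ignore_case = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(prune_mentions(m, text, context_rules = rules)), 0L)
  # suffix comparison is case-insensitive on the token
  text2 <- "Many GROWTH GENES respond."
  m2 <- mk_mentions(text2, list("GROWTH GENES"))
  expect_identical(nrow(prune_mentions(m2, text2)), 0L)
})

test_that("offset validation names the offending mention", {
  text <- "short text"
  bad <- data.frame(doc_id = "d1", start = 0L, end = 99L, text = "short",
                    stringsAsFactors = FALSE)
  expect_error(prune_mentions(bad, text), "out-of-range")
  shifted <- data.frame(doc_id = "d1", start = 1L, end = 6L, text = "short",
                        stringsAsFactors = FALSE)
  expect_error(prune_mentions(shifted, text), "does not match")
})

test_that("abbreviation pairing applies the bracket and subsequence rules", {
  text <- "We found tumor necrosis factor (TNF) and interleukin 2 (IL-2) here."
  m <- mk_mentions(text, list("tumor necrosis factor", "TNF",
                              "interleukin 2", "IL-2"))
  pairs <- pair_abbreviations(m, text)
  expect_identical(nrow(pairs), 2L)
  expect_setequal(pairs$short_text, c("TNF", "IL-2"))
  expect_identical(pairs$long_text[pairs$short_text == "TNF"],
                   "tumor necrosis factor")
  # ordering and same-document invariants
  expect_true(all(pairs$long_end < pairs$short_start))
})

test_that("abbreviation pairing rejects non-pairs", {
  text <- "BAT1 (see Methods) and unrelated (XYZQ) span."
  m1 <- mk_mentions(text, list("BAT1"))
  expect_identical(nrow(pair_abbreviations(m1, text)), 0L)
  # bracketed but not a letter-subsequence of the long form
  m2 <- mk_mentions(text, list("unrelated", "XYZQ"))
  expect_identical(nrow(pair_abbreviations(m2, text)), 0L)
})

test_that("mention and abstract files round-trip", {
  text <- "Alpha BAT1 beta."
  ab <- tmp_lines(paste("77", text, sep = "\t"))
  mn <- tmp_lines("77\t6\t10\tBAT1")
  abstracts <- read_abstracts(ab)
  mentions <- read_mentions(mn)
  expect_identical(abstracts[["77"]], text)
  expect_identical(mentions$text, "BAT1")
  expect_silent(validate_mentions(mentions, abstracts))
  expect_identical(nrow(read_mentions(tmp_lines(character(0)))), 0L)
})
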