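test_that("Jaro and Jaro-Winkler reproduce hand-derived values", {
  expect_equal(jaro_similarity("MARTHA", "MARHTA"), 0.944444, tolerance = 1e-4)
  expect_equal(jaro_winkler("MARTHA", "MARHTA"), 0.961111, tolerance = 1e-4)
  expect_equal(jaro_winkler("DIXON", "DICKSONX"), 0.813333, tolerance = 1e-4)
  expect_identical(jaro_similarity("abc", "abc"), 1)
  expect_identical(jaro_similarity("abc", "xyz"), 0)
  expect_identical(jaro_winkler("x", "x"), 1)
  expect_identical(jaro_similarity("", ""), 1)
  expect_identical(jaro_similarity("", "abc"), 0)
})

test_that("similarity kernel is symmetric, bounded, prefix-boosted", {
  set.seed(202)
  for (k in 1:400) {
    s1 <- rand_string(sample(1:10, 1))
    s2 <- rand_string(sample(1:10, 1))
    j <- jaro_similarity(s1, s2)
    jw <- jaro_winkler(s1, s2)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_gte(jw, j); expect_lte(jw, 1)
    expect_equal(jaro_similarity(s2, s1), j, tolerance = 1e-12)
    expect_equal(jaro_winkler(s2, s1), jw, tolerance = 1e-12)
    if (identical(s1, s2)) {
      expect_identical(jw, 1)
    } else {
      expect_lt(jw, 1)
    }
  }
  expect_error(jaro_winkler("a", "b", p = 0.3), "0.25")
})

test_that("munkres assignment equals brute force on random matrices", {
  set.seed(303)
  for (k in 1:120) {
    nr <- sample(1:6, 1)
    nc <- sample(1:6, 1)
    w <- matrix(runif(nr * nc), nr, nc)
    a <- munkres_max_assignment(w)
    expect_equal(a$total_weight, brute_force_max_assignment(w),
                 tolerance = 1e-9)
    expect_equal(nrow(a$pairs), min(nr, nc))
    # matching property: no row or column reused
    expect_false(any(duplicated(a$pairs[, 1])))
    expect_false(any(duplicated(a$pairs[, 2])))
    expect_equal(sum(w[a$pairs]), a$total_weight, tolerance = 1e-9)
  }
})

test_that("munkres assignment agrees with an independent LSAP solver", {
  set.seed(304)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    w <- matrix(runif(n * n), n, n)
    ours <- munkres_max_assignment(w)$total_weight
    ref <- sum(w[cbind(seq_len(n),
                       as.integer(clue::solve_LSAP(w, maximum = TRUE)))])
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("degenerate assignments are handled", {
  empty <- munkres_max_assignment(matrix(numeric(0), 0, 0))
  expect_identical(nrow(empty$pairs), 0L)
  expect_identical(empty$total_weight, 0)
  one <- munkres_max_assignment(matrix(0.37, 1, 1))
  expect_equal(one$total_weight, 0.37)
  expect_equal(munkres_max_assignment(matrix(c(4, 2, 1, 3), 2, 2))$total_weight, 7)
})

test_that("semantic similarity discriminates matching from disjoint contexts", {
  rec <- list(symbol = "BAT1", chromosome = "6", map_location = "6p21.3",
              description = "HLA-B associated transcript 1")
  ctx_hit <- normalize_term(c("bat1", "6p21.3", "unrelated factor"))
  ctx_miss <- normalize_term(c("zzq9", "14q32", "unrelated factor"))
  hit <- semantic_similarity(rec, ctx_hit, mode = "munkres")
  miss <- semantic_similarity(rec, ctx_miss, mode = "munkres")
  expect_gte(hit, 2)  # two exact field matches contribute 1.0 each
  expect_gt(hit, miss)
  expect_identical(semantic_similarity(rec, character(0)), 0)
  empty_rec <- list(symbol = "", chromosome = "", map_location = "",
                    description = "")
  expect_identical(semantic_similarity(empty_rec, ctx_hit), 0)
})

test_that("sum_all dominates munkres and munkres is context-order invariant", {
  set.seed(404)
  rec <- list(symbol = "abc1", chromosome = "7", map_location = "7q21",
              description = "abc transporter 1")
  for (k in 1:25) {
    ctx <- vapply(seq_len(sample(1:6, 1)), function(i) {
      rand_string(sample(1:8, 1))
    }, character(1))
    mk <- semantic_similarity(rec, ctx, mode = "munkres")
    sa <- semantic_similarity(rec, ctx, mode = "sum_all")
    expect_gte(sa, mk - 1e-12)
    perm <- sample(ctx)
    expect_equal(semantic_similarity(rec, perm, mode = "munkres"), mk,
                 tolerance = 1e-9)
  }
})
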