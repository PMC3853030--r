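# Plain-R greedy scan written independently from the C++ closure: walk the
# candidates in order, keep each whose distance to all kept so far is >= dmin.
r_greedy <- function(seed, cand, dmin, distfun) {
  acc <- seed
  for (w in cand) {
    if (length(acc) == 0 ||
        all(distfun(rep(w, length(acc)), acc) >= dmin)) {
      acc <- c(acc, w)
    }
  }
  acc
}

test_that("greedy closure matches an independent reimplementation on small
          pools", {
  cand <- enumerate_candidates(4)
  for (metric in c("seqlev", "levenshtein", "hamming")) {
    distfun <- switch(metric, seqlev = seqlev_distance,
                      levenshtein = levenshtein_distance,
                      hamming = hamming_distance)
    got <- greedy_closure(NULL, cand, dmin = 3, metric = metric)
    expect_equal(got$sequence, r_greedy(character(0), cand, 3, distfun))
    seed <- got$sequence[1:2]
    got2 <- greedy_closure(seed, cand, dmin = 3, metric = metric)
    expect_equal(got2$sequence,
                 unique(c(seed, r_greedy(seed, cand, 3, distfun))))
  }
})

test_that("the published 4-barcode example is a valid seqlev code", {
  code <- example_code()
  v <- verify_code(code)
  expect_true(v$valid)
  expect_equal(nrow(v$violations), 0L)
  d <- outer(code$sequence, code$sequence, seqlev_distance)
  expect_true(all(d[upper.tri(d)] >= 3))
})

test_that("verify_code reports every violating pair and filter failure", {
  bad <- barcode_set(c("TTCC", "ACAC", "ACAA"), metric = "seqlev", dmin = 3,
                     verify = FALSE)
  v <- verify_code(bad)
  expect_false(v$valid)
  expect_true(nrow(v$violations) >= 1)
  expect_true(all(v$violations$distance < 3))
  # a barcode violating the chemical policy is flagged too
  bad2 <- barcode_set(c("TTCC", "AAAA"), metric = "seqlev", dmin = 3,
                      verify = FALSE)
  v2 <- verify_code(bad2)
  expect_equal(v2$filter_failures$sequence, "AAAA")
  # constructor refuses invalid sets when verify = TRUE
  expect_error(barcode_set(c("TTCC", "ACAC", "ACAA"), "seqlev", dmin = 3),
               "invariants")
})

test_that("code rate follows log2(size) / 2n", {
  expect_equal(code_rate(188, n = 8), log2(188) / 16)
  expect_equal(round(code_rate(188, n = 8), 3), 0.472)
  expect_equal(round(code_rate(552, n = 8), 3), 0.569)
  expect_equal(code_rate(1, n = 5), 0)
})

test_that("greedy closure degenerate and error cases", {
  seed <- c("TTCC", "ACAC")
  out <- greedy_closure(seed, character(0), dmin = 3, metric = "seqlev")
  expect_equal(out$sequence, seed)
  expect_error(greedy_closure(c("TTCC", "TTCA"), character(0), 3, "seqlev"),
               "invalid seed")
})

test_that("any subset of a valid code is valid", {
  code <- greedy_closure(NULL, enumerate_candidates(5), 3, "seqlev")
  set.seed(409)
  sub <- code[sort(sample(nrow(code), 5)), ]
  expect_true(verify_code(sub)$valid)
})

test_that("code sizes order hamming >= levenshtein >= seqlev at fixed n and
          dmin", {
  for (n in 4:8) {
    cand <- enumerate_candidates(n)
    sizes <- vapply(c("hamming", "levenshtein", "seqlev"), function(metric) {
      nrow(greedy_closure(NULL, cand, 3, metric))
    }, integer(1))
    expect_true(sizes[["hamming"]] >= sizes[["levenshtein"]])
    expect_true(sizes[["levenshtein"]] >= sizes[["seqlev"]])
  }
})

test_that("code rate of greedy seqlev codes is non-decreasing for n = 5..8", {
  rates <- vapply(5:8, function(n) {
    code_rate(greedy_closure(NULL, enumerate_candidates(n), 3, "seqlev"))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("the evolutionary search is reproducible and never below its own
          greedy baseline", {
  cand <- enumerate_candidates(5)
  set.seed(410)
  a <- evolutionary_search(5, 1, "seqlev", budget = 15, candidates = cand)
  set.seed(410)
  b <- evolutionary_search(5, 1, "seqlev", budget = 15, candidates = cand)
  expect_equal(a$sequence, b$sequence)
  expect_true(verify_code(a)$valid)
  expect_true(attr(a, "evaluations") <= 15)
  # best-so-far trace is non-decreasing
  expect_true(all(diff(attr(a, "best_trace")) >= 0))
  # degenerate search: a single evaluation is one greedy closure of a seed
  set.seed(411)
  one <- evolutionary_search(5, 1, "seqlev", population = 1, budget = 1,
                             candidates = cand)
  expect_true(verify_code(one)$valid)
  expect_equal(attr(one, "evaluations"), 1L)
  # early stop at a target size
  set.seed(412)
  tgt <- evolutionary_search(5, 1, "seqlev", budget = 50, target_size = 10,
                             candidates = cand)
  expect_gte(nrow(tgt), 10)
  expect_error(evolutionary_search(1, 1, "seqlev"), "no candidates")
})

test_that("tidy and glance expose the code metadata", {
  code <- example_code()
  td <- tidy(code)
  expect_s3_class(td, "tbl_df")
  expect_equal(names(td), c("id", "sequence"))
  gl <- glance(code)
  expect_equal(gl$size, 4L)
  expect_equal(gl$metric, "seqlev")
  expect_equal(gl$k, 1L)
  expect_equal(gl$context_k, 1L)
  # classic Levenshtein codes only guarantee k in context at dmin = 4k + 1
  lev5 <- barcode_set(c("AAAAAAAA", "CCCCCCCC"), "levenshtein", dmin = 5,
                      policy = NULL)
  expect_equal(attr(lev5, "k"), 2L)
  expect_equal(attr(lev5, "context_k"), 1L)
})
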