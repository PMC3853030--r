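test_that("worked-example distances match the published values", {
  # Hamming
  expect_equal(hamming_distance("ACT", "ACG"), 1L)
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4L)
  expect_error(hamming_distance("ACG", "AC"), "equal length")

  # classic Levenshtein
  expect_equal(levenshtein_distance("", "ACG"), 3L)
  expect_equal(levenshtein_distance("CAGG", "CGTC"), 3L)
  expect_equal(levenshtein_distance("CGTC", "CGGC"), 1L)
  expect_equal(levenshtein_distance("CAGG", "CGGC"), 2L)
  expect_equal(levenshtein_distance("GCG", "GC"), 1L)

  # presumed-word-length table for the received read "CGGCA"
  expect_equal(levenshtein_distance("CAGG", c("CGG", "CGGC", "CGGCA")),
               c(1L, 2L, 3L))
  expect_equal(levenshtein_distance("CGTC", c("CGG", "CGGC", "CGGCA")),
               c(2L, 1L, 2L))

  # Sequence-Levenshtein
  expect_equal(seqlev_distance("CAGG", "CGTC"), 2L)
  expect_equal(seqlev_distance("AC", "ACGT"), 0L)
  expect_equal(seqlev_distance("TTCC", "TCCATGCATA"), 1L)
  expect_equal(seqlev_distance("ACAC", "TCCATGCATA"), 2L)
  expect_equal(seqlev_distance("CGAA", "TCCATGCATA"), 3L)
  expect_equal(seqlev_distance("TAGG", "TCCATGCATA"), 3L)
})

test_that("the DP matrix satisfies its structural invariants and matches a
          recursive oracle", {
  set.seed(402)
  for (r in 1:50) {
    a <- rand_word(sample(0:6, 1))
    b <- rand_word(sample(0:6, 1))
    m <- levenshtein_matrix(a, b)
    expect_equal(m[1, ], 0:nchar(b), ignore_attr = TRUE)
    expect_equal(m[, 1], 0:nchar(a), ignore_attr = TRUE)
    # cell[i][j] >= |i - j| and adjacent cells differ by at most 1
    ij <- abs(outer(0:nchar(a), 0:nchar(b), "-"))
    expect_true(all(m >= ij))
    if (nrow(m) > 1) expect_true(all(abs(diff(m)) <= 1))
    if (ncol(m) > 1) expect_true(all(abs(t(diff(t(m)))) <= 1))
    # every cell is the distance between the corresponding prefixes
    expect_equal(m[nrow(m), ncol(m)], oracle_lev(a, b))
    i <- sample(0:nchar(a), 1); j <- sample(0:nchar(b), 1)
    expect_equal(m[i + 1, j + 1], oracle_lev(substr(a, 1, i), substr(b, 1, j)))
  }
})

test_that("seqlev distance equals the brute-force prefix-minimum oracle", {
  # exhaustive over all word pairs up to length 4
  words <- unlist(lapply(0:4, all_words))
  pairs <- expand.grid(a = words, b = words, stringsAsFactors = FALSE)
  got <- seqlev_distance(pairs$a, pairs$b)
  want <- mapply(oracle_seqlev, pairs$a, pairs$b)
  expect_equal(got, unname(want))

  # sampled pairs at length 5 against the fully independent recursion
  set.seed(403)
  for (r in 1:40) {
    a <- rand_word(5); b <- rand_word(sample(0:5, 1))
    expect_equal(seqlev_distance(a, b), oracle_seqlev(a, b, lev = oracle_lev))
  }
})

test_that("seqlev distance is a metric under the prefix-equivalence
          convention", {
  set.seed(404)
  n <- 10000
  a <- rand_words(n, 1:12); b <- rand_words(n, 1:12)
  dab <- seqlev_distance(a, b)
  expect_equal(dab, seqlev_distance(b, a))                     # symmetry
  # identity of indiscernibles: d = 0 iff one word is a prefix of the other
  is_prefix <- startsWith(a, b) | startsWith(b, a)
  expect_equal(dab == 0L, is_prefix)
  expect_equal(seqlev_distance(a, a), rep(0L, n))

  # triangle inequality on the domain the codes live in: equal-length words
  # (exhaustive up to length 3, sampled beyond)
  for (len in 1:3) {
    w <- all_words(len)
    g <- expand.grid(a = w, b = w, c = w, stringsAsFactors = FALSE)
    expect_true(all(seqlev_distance(g$a, g$b) <=
                      seqlev_distance(g$a, g$c) + seqlev_distance(g$c, g$b)))
  }
  for (len in c(5, 8, 12)) {
    aa <- rand_words(3000, len); bb <- rand_words(3000, len)
    cc <- rand_words(3000, len)
    expect_true(all(seqlev_distance(aa, bb) <=
                      seqlev_distance(aa, cc) + seqlev_distance(cc, bb)))
  }
  # collapsing to a common short prefix can break the triangle inequality:
  # prefix-equivalence is not transitive, so the "metric" lives on words of
  # a fixed barcode length, not on all of sequence space
  expect_equal(seqlev_distance("AC", "A"), 0L)
  expect_equal(seqlev_distance("A", "AG"), 0L)
  expect_gt(seqlev_distance("AC", "AG"), 0L)
})

test_that("dominance and equal-length orderings hold", {
  set.seed(405)
  n <- 5000
  a <- rand_words(n, 0:10); b <- rand_words(n, 0:10)
  dsl <- seqlev_distance(a, b); dl <- levenshtein_distance(a, b)
  expect_true(all(dsl <= dl))
  expect_true(all(dl <= pmax(nchar(a), nchar(b))))
  # equal lengths: no-indel path bounds the edit distance from above
  a8 <- rand_words(2000, 8); b8 <- rand_words(2000, 8)
  expect_true(all(hamming_distance(a8, b8) >= levenshtein_distance(a8, b8)))
})

test_that("any single edit moves a word by seqlev distance at most 1", {
  set.seed(406)
  for (r in 1:40) {
    w <- rand_word(sample(1:10, 1))
    for (v in enumerate_corruptions(w, 1)) {
      expect_lte(seqlev_distance(w, v), 1L)
    }
  }
})

test_that("empty words are handled: distance to empty is the other length,
          seqlev distance is 0", {
  expect_equal(levenshtein_distance("", ""), 0L)
  expect_equal(levenshtein_distance("ACGT", ""), 4L)
  expect_equal(seqlev_distance("", "ACGT"), 0L)
  expect_equal(seqlev_distance("ACGT", ""), 0L)
})
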