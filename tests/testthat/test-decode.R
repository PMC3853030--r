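test_that("the worked decoding example recovers barcode, distance and
          boundary", {
  code <- example_code()
  for (win in c("bounded", "full")) {
    res <- sl_decode("TCCATGCATA", code, window = win)
    expect_equal(res$barcode, "TTCC")
    expect_equal(res$distance, 1L)
    expect_equal(res$boundary, 3L)
    expect_equal(as.character(res$status), "unique")
  }
  # uncorrupted read: exact prefix, boundary n
  res0 <- sl_decode("TTCCATGCATA", code)
  expect_equal(res0$barcode, "TTCC")
  expect_equal(res0$distance, 0L)
  expect_equal(res0$boundary, 4L)
})

test_that("classic fixed-length decoding reproduces the deletion failure", {
  codeL <- barcode_set(c("CAGG", "CGTC"), "levenshtein", dmin = 3,
                       policy = NULL)
  # "CAGG|CA..." loses its second base: the read "CGGCA..." is now closer
  # to the wrong codeword
  res <- classic_decode_fixed_length("CGGCA", codeL)
  expect_equal(res$barcode, "CGTC")
  expect_equal(res$distance, 1L)
  # an uncorrupted read decodes to its own barcode at distance 0
  res0 <- classic_decode_fixed_length("CAGGCA", codeL)
  expect_equal(res0$barcode, "CAGG")
  expect_equal(res0$distance, 0L)
})

test_that("hamming decoding corrects any single substitution of a dmin=3
          code", {
  code <- barcode_set(c("AAA", "CCC", "GGG", "TTT"), "hamming", dmin = 3,
                      policy = NULL)
  # exhaustive: every codeword, position and alternative base
  for (i in seq_len(nrow(code))) {
    w <- code$sequence[i]
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(w, pos, pos))) {
      mut <- w; substr(mut, pos, pos) <- b
      res <- hamming_decode(paste0(mut, "ACGT"), code)
      expect_equal(res$matched_index, i)
      expect_equal(res$distance, 1L)
      expect_equal(res$boundary, 3L)
    }
  }
})

test_that("decoders validate their inputs", {
  code <- example_code()
  expect_error(sl_decode("TC", code), "shorter than n - k")
  expect_error(sl_decode("TCCATGCATA", code[0, ]), "empty code")
  expect_error(classic_decode_fixed_length("TCCATGCATA", code), "levenshtein")
  expect_error(hamming_decode("TCCATGCATA", code), "hamming")
  codeL <- barcode_set(c("CAGG", "CGTC"), "levenshtein", dmin = 3,
                       policy = NULL)
  expect_error(classic_decode_fixed_length("CAGG", codeL), "shorter")
})

test_that("every <=k corruption with adversarial context decodes to the
          original codeword", {
  # the guarantee theorem, exhaustively on a generated n=5, k=1 code
  code <- greedy_closure(NULL, enumerate_candidates(5), 3, "seqlev")
  n <- attr(code, "n"); k <- attr(code, "k")
  for (i in seq_len(nrow(code))) {
    corr <- enumerate_corruptions(code$sequence[i], k)
    fills <- pmax(n + k - nchar(corr), 0L)
    reads <- unlist(lapply(seq_along(corr), function(j) {
      if (fills[j] == 0) return(corr[j])
      paste0(corr[j], all_words(fills[j]))
    }))
    res <- sl_decode(substr(reads, 1, n + k), code)
    expect_true(all(res$matched_index == i))
    expect_true(all(res$status == "unique"))
    expect_true(all(res$distance <= k))
  }
})

test_that("recovered boundary equals n + insertions - deletions of the
          decoder's optimal script", {
  code <- greedy_closure(NULL, enumerate_candidates(6), 3, "seqlev")
  n <- attr(code, "n")
  set.seed(413)
  trials <- 300
  idx <- sample.int(nrow(code), trials, replace = TRUE)
  mut <- mutate_exact(code$sequence[idx], 1)
  reads <- substr(paste0(mut$mutated, rand_words(trials, 8)), 1, n + 6)
  res <- sl_decode(reads, code, window = "full")
  ok <- res$status == "unique"
  expect_true(all(res$matched_index[ok] == idx[ok]))
  # internal consistency: the boundary is the indel balance of the optimal
  # edit script of the matched barcode against the read
  for (i in which(ok)) {
    s <- sl_traceback(res$barcode[i], reads[i])
    expect_equal(res$boundary[i], n + s$n_ins - s$n_del)
  }
  # the decoder's explanation is never worse than the true corruption
  expect_true(all(res$distance[ok] <= 1))
  # agreement with the true generating script: exact unless an equal-cost
  # alternative script explains the read (terminal indels and context
  # mimicry are information-theoretically undecidable, ~15-25% at n = 6)
  agree <- res$boundary[ok] == (n + mut$n_ins - mut$n_del)[ok]
  expect_gt(mean(agree), 0.6)
  # where they disagree, an equal-or-cheaper optimal script with the
  # reported balance exists (already pinned by the consistency loop above)
})

test_that("the bounded window never changes decisions at distance <= k", {
  code <- greedy_closure(NULL, enumerate_candidates(6), 3, "seqlev")
  set.seed(414)
  idx <- sample.int(nrow(code), 400, replace = TRUE)
  mut <- mutate_exact(code$sequence[idx], 1)
  reads <- substr(paste0(mut$mutated, rand_words(400, 10)), 1, 12)
  bounded <- sl_decode(reads, code, window = "bounded")
  full <- sl_decode(reads, code, window = "full")
  sel <- full$distance <= attr(code, "k")
  expect_equal(bounded$matched_index[sel], full$matched_index[sel])
  expect_equal(as.character(bounded$status[sel]),
               as.character(full$status[sel]))
})
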