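test_that("simulation 1 reproduces the qualitative failure pattern of
          fixed-length decoding", {
  set.seed(422)
  cand <- enumerate_candidates(8)
  dl3 <- greedy_closure(NULL, cand, 3, "levenshtein")
  dl5 <- greedy_closure(NULL, cand, 5, "levenshtein")
  rep <- simulation1(dl3, dl5, trials = 4000)
  expect_equal(nrow(rep), 3L)
  expect_true(all(rep$n_correct + rep$n_wrong + rep$n_ambiguous == rep$trials))
  # dmin=3 fails near the 1/4 adverse-base level on single indels
  expect_gt(rep$failure_rate[1], 0.18)
  expect_lt(rep$failure_rate[1], 0.32)
  # dmin=5 always corrects one error in context...
  expect_equal(rep$failure_rate[2], 0)
  # ...and fails near (1/4)^2 on two indels
  expect_gt(rep$failure_rate[3], 0.03)
  expect_lt(rep$failure_rate[3], 0.12)
  expect_lt(rep$failure_rate[3], rep$failure_rate[1])
})

test_that("simulation 2 finds zero failures for valid codes and catches an
          invalid one", {
  for (n in c(5, 6)) {
    code <- greedy_closure(NULL, enumerate_candidates(n), 3, "seqlev")
    r <- simulation2(code)
    expect_equal(r$n_wrong + r$n_ambiguous, 0L)
    expect_equal(r$n_correct, r$trials)
  }
  # a two-error-correcting code, exhaustively over two-edit corruptions
  code5 <- greedy_closure(NULL, enumerate_candidates(8), 5, "seqlev")
  r5 <- simulation2(code5)
  expect_equal(r5$n_wrong + r5$n_ambiguous, 0L)
  # sanity inversion: a pair at seqlev distance 2 only pretends dmin = 3
  bad <- barcode_set(c("ACAC", "ACGA"), "seqlev", dmin = 3, policy = NULL,
                     verify = FALSE)
  rbad <- simulation2(bad)
  expect_gt(rbad$n_wrong + rbad$n_ambiguous, 0)
  expect_gt(nrow(attr(rbad, "failures")), 0)
})

test_that("simulation 3 is perfect at p = 0 and degrades monotonically in p", {
  set.seed(423)
  cand <- enumerate_candidates(6)
  codes <- list(sl = greedy_closure(NULL, cand, 3, "seqlev"),
                lev = greedy_closure(NULL, cand, 3, "levenshtein"))
  rep <- simulation3(codes, p_grid = c(0, 0.2, 0.4, 0.6), trials = 1500)
  expect_true(all(rep$n_correct + rep$n_wrong + rep$n_ambiguous == rep$trials))
  at0 <- rep[rep$p_or_e == 0, ]
  expect_true(all(at0$n_correct == at0$trials))
  # non-increasing correct rate in p, within 3 binomial standard errors
  for (cd in unique(rep$code)) {
    r <- rep[rep$code == cd, ]
    rate <- r$n_correct / r$trials
    se <- sqrt(pmax(rate * (1 - rate), 1e-6) / r$trials)
    expect_true(all(diff(rate) <= 3 * (se[-1] + se[-length(se)])))
  }
  # empirical mutation load matches mu = p * n
  for (i in seq_len(nrow(rep))) {
    n <- rep$n[i]; p <- rep$p_or_e[i]
    se <- sqrt(n * p * (1 - p) / rep$trials[i])
    expect_lt(abs(rep$mean_mutations[i] - p * n), 3 * se + 1e-9)
  }
})

test_that("simulation reports are reproducible bit for bit from the seed", {
  cand <- enumerate_candidates(6)
  dl3 <- greedy_closure(NULL, cand, 3, "levenshtein")
  dl5 <- greedy_closure(NULL, enumerate_candidates(8), 5, "levenshtein")
  set.seed(424); a <- simulation1(dl3, dl5, trials = 500)
  set.seed(424); b <- simulation1(dl3, dl5, trials = 500)
  expect_equal(a, b)
  sl <- greedy_closure(NULL, cand, 3, "seqlev")
  set.seed(425); c1 <- simulation3(list(sl = sl), p_grid = 0.3, trials = 500)
  set.seed(425); c2 <- simulation3(list(sl = sl), p_grid = 0.3, trials = 500)
  expect_equal(c1, c2)
})

test_that("simulation reports tidy and plot", {
  set.seed(426)
  sl <- greedy_closure(NULL, enumerate_candidates(5), 3, "seqlev")
  rep <- simulation3(list(sl = sl), p_grid = c(0.1, 0.3), trials = 300)
  td <- tidy(rep)
  expect_false(inherits(td, "simulation_report"))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
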