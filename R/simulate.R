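# The three simulation studies: classic-code failure in DNA context,
# exhaustive guarantee verification, and per-base error sweeps.

new_simulation_report <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("simulation_report", class(df))
  df
}

#' @export
tidy.simulation_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "simulation_report")
  out
}

arm_row <- function(scenario, label, meta, p_or_e, trials, n_correct,
                    n_wrong, n_ambiguous, mean_mutations) {
  tibble::tibble(
    scenario = scenario, code = label, metric = meta$metric, n = meta$n,
    dmin = meta$dmin, p_or_e = p_or_e, trials = trials,
    n_correct = n_correct, n_wrong = n_wrong, n_ambiguous = n_ambiguous,
    failure_rate = (n_wrong + n_ambiguous) / trials,
    mean_mutations = mean_mutations
  )
}

# Embed mutated barcodes in reads of total length m (uniform random sample
# sequence appended; truncated to m if the mutated barcode overruns).
embed_in_reads <- function(mutated, m) {
  need <- pmax(m - nchar(mutated), 0L)
  suffix <- c_random_words(length(mutated), max(need))
  reads <- paste0(mutated, substr(suffix, 1L, need))
  substr(reads, 1L, m)
}

#' Simulation 1: classic Levenshtein codes in DNA context
#'
#' Assesses fixed-length decoding of classic Levenshtein codes when the
#' barcode is embedded in a longer read. Per trial a codeword is drawn
#' uniformly, corrupted with `e` random edits (indels only by default — the
#' failure mode under study is the boundary shift), embedded in a read of
#' length `m` with random sample sequence, and decoded with
#' [classic_decode_fixed_length()]. Three arms are run: the `dmin = 3` code
#' with 1 error, and the `dmin = 5` code with 1 and with 2 errors.
#'
#' The `dmin = 3` single-indel failure rate converges near 1/4 — the
#' probability that the sample base sliding into the decoding window is the
#' adverse one — and the `dmin = 5` two-indel rate near (1/4)^2 = 0.0625.
#' `dmin = 5` corrects any single error in context.
#'
#' @param code_dl3 A `barcode_set`, metric `"levenshtein"`, `dmin = 3`.
#' @param code_dl5 A `barcode_set`, metric `"levenshtein"`, `dmin = 5`.
#' @param trials Trials per arm.
#' @param m Read length; default `n + 6`.
#' @param mix Mutation-type weights (see [mutate_exact()]); default pure
#'   indel.
#' @return A `simulation_report` tibble with one row per arm.
#' @export
simulation1 <- function(code_dl3, code_dl5, trials = 1e5, m = NULL,
                        mix = c(sub = 0, ins = 1, del = 1)) {
  m3 <- code_meta(code_dl3); m5 <- code_meta(code_dl5)
  stopifnot(m3$metric == "levenshtein", m3$dmin == 3,
            m5$metric == "levenshtein", m5$dmin == 5, trials >= 1)
  arms <- list(list(code = code_dl3, meta = m3, e = 1L),
               list(code = code_dl5, meta = m5, e = 1L),
               list(code = code_dl5, meta = m5, e = 2L))
  rows <- lapply(arms, function(a) {
    mm <- m %||% (a$meta$n + 6L)
    idx <- sample.int(nrow(a$code), trials, replace = TRUE)
    mut <- mutate_exact(a$code$sequence[idx], a$e, mix = mix)
    reads <- embed_in_reads(mut$mutated, mm)
    dec <- classic_decode_fixed_length(reads, a$code)
    correct <- dec$matched_index == idx
    arm_row("simulation1",
            sprintf("levenshtein dmin=%d n=%d", a$meta$dmin, a$meta$n),
            a$meta, p_or_e = a$e, trials = trials,
            n_correct = sum(correct), n_wrong = sum(!correct),
            n_ambiguous = 0L,
            mean_mutations = mean(mut$n_sub + mut$n_ins + mut$n_del))
  })
  new_simulation_report(dplyr::bind_rows(rows))
}

#' Simulation 2: exhaustive guarantee check for Sequence-Levenshtein codes
#'
#' For every codeword (or a subsample), every corruption by at most `k`
#' edits, and every sample-sequence continuation filling the decoding
#' window, verifies that [sl_decode()] recovers the original codeword. For a
#' valid code with `dmin = 2k + 1` the expected failure count is zero — this
#' is the error-correction guarantee made exhaustive.
#'
#' Continuations enumerate all `4^min(fill, k + 1)` choices of the first
#' window-filling sample bases (the positions that can interact with the
#' barcode) and pad any remainder cyclically with `ACGT`; for `k = 1` this
#' covers every possible window content.
#'
#' @param code A `barcode_set` with metric `"seqlev"` and `dmin >= 3`.
#' @param codewords Optional: number of codewords to subsample (for large
#'   codes), or an index vector. Default: all.
#' @return A one-row `simulation_report`; the failing reads (if any) are in
#'   `attr(, "failures")`.
#' @export
simulation2 <- function(code, codewords = NULL) {
  meta <- code_meta(code)
  stopifnot(meta$metric == "seqlev", meta$dmin >= 3)
  k <- meta$k
  window <- meta$n + k
  sel <- seq_len(nrow(code))
  if (!is.null(codewords)) {
    sel <- if (length(codewords) == 1 && codewords < nrow(code)) {
      sort(sample(sel, codewords))
    } else {
      as.integer(codewords)
    }
  }
  reads <- character(0); expected <- integer(0)
  for (i in sel) {
    corr <- enumerate_corruptions(code$sequence[i], k)
    fills <- pmax(window - nchar(corr), 0L)
    r <- unlist(lapply(seq_along(corr), function(j) {
      paste0(corr[j], window_continuations(fills[j], k))
    }))
    r <- unique(substr(r, 1L, window))
    reads <- c(reads, r)
    expected <- c(expected, rep(i, length(r)))
  }
  dec <- sl_decode(reads, code, max_distance = k, window = "bounded")
  correct <- !is.na(dec$matched_index) & dec$matched_index == expected
  fail <- !correct
  out <- arm_row("simulation2",
                 sprintf("seqlev dmin=%d n=%d", meta$dmin, meta$n),
                 meta, p_or_e = k, trials = length(reads),
                 n_correct = sum(correct),
                 n_wrong = sum(fail & dec$status != "ambiguous"),
                 n_ambiguous = sum(dec$status == "ambiguous"),
                 mean_mutations = NA_real_)
  out <- new_simulation_report(out)
  attr(out, "failures") <- tibble::tibble(
    read = reads[fail], expected = code$sequence[expected[fail]],
    matched = dec$barcode[fail], status = dec$status[fail]
  )
  out
}

window_continuations <- function(fill, k) {
  if (fill == 0) return("")
  en <- min(fill, k + 1L)
  combos <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), en),
                                        stringsAsFactors = FALSE))
  pad <- substr(strrep("ACGT", ceiling(fill / 4)), 1L, fill - en)
  paste0(combos, pad)
}

#' Simulation 3: per-base mutation sweep across code families
#'
#' Draws codewords from each code, mutates every barcode base independently
#' with probability `p` ([mutate_per_base()]), embeds the result in a random
#' read, and decodes in best-effort mode (any unique minimum accepted, since
#' more than `k` errors may have occurred). Reports the correct-decoding
#' fraction per code and `p` — the basis for comparing Sequence-Levenshtein,
#' classic Levenshtein, Hamming/linear and uncorrected codes under
#' realistic multi-error channels.
#'
#' @param codes A (preferably named) list of `barcode_set` objects.
#' @param p_grid Numeric vector of per-base mutation probabilities.
#' @param trials Trials per code/p cell.
#' @param m Read length; default `n + 6` per code.
#' @return A `simulation_report` with one row per code and `p`.
#' @export
simulation3 <- function(codes, p_grid = c(0.1, 0.3, 0.5), trials = 1e4,
                        m = NULL) {
  if (inherits(codes, "barcode_set")) codes <- list(codes)
  labels <- names(codes) %||% rep(NA_character_, length(codes))
  rows <- list()
  for (ci in seq_along(codes)) {
    code <- codes[[ci]]
    meta <- code_meta(code)
    label <- labels[ci]
    if (is.na(label) || !nzchar(label)) {
      label <- sprintf("%s dmin=%d n=%d", meta$metric, meta$dmin, meta$n)
    }
    mm <- m %||% (meta$n + 6L)
    for (p in p_grid) {
      idx <- sample.int(nrow(code), trials, replace = TRUE)
      mut <- mutate_per_base(code$sequence[idx], p)
      reads <- embed_in_reads(mut$mutated, mm)
      dec <- decode_by_metric(reads, code, best_effort = TRUE)
      correct <- !is.na(dec$matched_index) & dec$matched_index == idx
      # ties are resolved randomly in best-effort mode; count the ones that
      # resolved wrongly as ambiguous
      amb <- if ("status" %in% names(dec)) {
        sum(dec$status == "ambiguous" & !correct)
      } else 0L
      rows[[length(rows) + 1]] <- arm_row(
        "simulation3", label, meta, p_or_e = p, trials = trials,
        n_correct = sum(correct),
        n_wrong = trials - sum(correct) - amb,
        n_ambiguous = amb,
        mean_mutations = mean(mut$n_sub + mut$n_ins + mut$n_del))
    }
  }
  new_simulation_report(dplyr::bind_rows(rows))
}

#' Plot a simulation report
#'
#' For per-base sweeps ([simulation3()]) draws the correct-decoding rate
#' against the mutation probability `p`, one curve per code; for the other
#' scenarios a bar chart of failure rates per arm.
#'
#' @param object A `simulation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulation_report <- function(object, ...) {
  df <- tidy(object)
  df$correct_rate <- df$n_correct / df$trials
  if (length(unique(df$p_or_e)) > 1 && all(df$scenario == "simulation3")) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$p_or_e, y = .data$correct_rate,
                                     colour = .data$code)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "per-base mutation probability p",
                    y = "correct decoding rate", colour = "code") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    df$arm <- paste0(df$code, " (e=", df$p_or_e, ")")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$failure_rate)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "failure rate") +
      ggplot2::coord_flip() +
      ggplot2::theme_minimal()
  }
}
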