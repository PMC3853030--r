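# Decoders: assign reads to barcodes and recover the word boundary.

STATUS_LEVELS <- c("unique", "ambiguous", "rejected")

#' Sequence-Levenshtein decoding of reads
#'
#' Computes the Sequence-Levenshtein distance between every codeword and the
#' read (by default restricted to the read prefix of length `n + k`, which
#' provably does not change any decision at distance <= k and bounds the
#' cost per read) and reports the nearest codeword. Because indels move the
#' barcode/sample boundary, the matched codeword's optimal edit script also
#' recovers where the sample sequence starts: `boundary = n + insertions -
#' deletions`.
#'
#' @param reads Character vector of reads (each at least `n - k` bases).
#' @param code A `barcode_set` with metric `"seqlev"`.
#' @param max_distance Acceptance threshold: reads whose best distance
#'   exceeds it are `rejected`. Defaults to the code's guaranteed `k`; use
#'   `Inf` for best-effort decoding (accept any unique minimum, as when more
#'   than `k` errors may have occurred).
#' @param window `"bounded"` (default) decodes against the read prefix of
#'   length `n + k`; `"full"` uses the whole read, reproducing textbook
#'   worked examples at distances beyond `k`.
#' @param ties `"ambiguous"` (default) reports minimum-distance ties as
#'   such; `"random"` resolves them uniformly at random (R's RNG), the
#'   behaviour used by the mutation simulations.
#' @return A tibble with one row per read: `read`, `matched_index`,
#'   `matched_id`, `barcode`, `distance`, `boundary`, `status`
#'   (`unique` / `ambiguous` / `rejected`). Ambiguous means two or more
#'   codewords tie at the minimum distance.
#' @examples
#' code <- barcode_set(c("TTCC", "ACAC", "CGAA", "TAGG"), "seqlev", dmin = 3)
#' sl_decode("TCCATGCATA", code)  # TTCC, distance 1, boundary 3
#' @export
sl_decode <- function(reads, code, max_distance = NULL,
                      window = c("bounded", "full"),
                      ties = c("ambiguous", "random")) {
  window <- match.arg(window)
  ties <- match.arg(ties)
  m <- code_meta(code)
  if (m$metric != "seqlev") {
    stop("sl_decode requires a code with metric 'seqlev'", call. = FALSE)
  }
  if (nrow(code) == 0) stop("empty code", call. = FALSE)
  assert_dna(reads)
  short <- nchar(reads) < m$n - m$k
  if (any(short)) {
    stop("read(s) shorter than n - k = ", m$n - m$k,
         " cannot contain a recoverable barcode (first offender: read ",
         which(short)[1], ")", call. = FALSE)
  }
  max_distance <- max_distance %||% m$k
  md <- if (is.finite(max_distance)) as.integer(max_distance) else -1L
  win <- if (window == "bounded") m$n + m$k else -1L
  res <- c_sl_decode_batch(reads, code$sequence, win, md, ties == "random")
  tibble::tibble(
    read = reads,
    matched_index = res$index,
    matched_id = code$id[res$index],
    barcode = code$sequence[res$index],
    distance = res$distance,
    boundary = res$boundary,
    status = factor(STATUS_LEVELS[res$status], levels = STATUS_LEVELS)
  )
}

#' Fixed-length classic Levenshtein decoding
#'
#' The decoding procedure available when a classic Levenshtein code is used
#' in DNA context and the received barcode length is unknown: compare all
#' codewords against the length-`n` read prefix; if not exactly one codeword
#' lies within distance `k`, retry with the presumed word lengths `n - s` and
#' `n + s` for `s = 1..k` (an imbalance of `s` indels shifts the boundary by
#' `s` positions); any remaining ambiguity is resolved uniformly at random
#' (driven by R's RNG — `set.seed()` makes runs reproducible). This is the
#' procedure whose
#' failure modes motivate the Sequence-Levenshtein metric: an indel slides a
#' sample base into the window and with probability ~1/4 the adverse base
#' makes a wrong codeword the nearest one.
#'
#' @param reads Character vector of reads, each at least `n + k` bases.
#' @param code A `barcode_set` with metric `"levenshtein"`.
#' @return A tibble with one row per read: `read`, `matched_index`,
#'   `matched_id`, `barcode`, `distance`, `window_used` (the presumed word
#'   length the match was found at, reported as the boundary) and `status`
#'   (`unique`, or `random` when the tie-break decided).
#' @export
classic_decode_fixed_length <- function(reads, code) {
  m <- code_meta(code)
  if (m$metric != "levenshtein") {
    stop("classic_decode_fixed_length requires a code with metric 'levenshtein'",
         call. = FALSE)
  }
  if (nrow(code) == 0) stop("empty code", call. = FALSE)
  assert_dna(reads)
  if (any(nchar(reads) < m$n + max(m$k, 1L))) {
    stop("read(s) shorter than n + k = ", m$n + max(m$k, 1L), call. = FALSE)
  }
  res <- c_classic_decode_batch(reads, code$sequence, m$n, m$k)
  tibble::tibble(
    read = reads,
    matched_index = res$index,
    matched_id = code$id[res$index],
    barcode = code$sequence[res$index],
    distance = res$distance,
    window_used = res$window_used,
    status = factor(c("unique", "random")[res$status],
                    levels = c("unique", "random"))
  )
}

#' Nearest-codeword Hamming decoding
#'
#' Matches the length-`n` read prefix to the nearest codeword by Hamming
#' distance. Substitution errors within `k = (dmin - 1) / 2` are corrected;
#' indels are outside this decoder's model and the boundary is always `n`.
#'
#' @param reads Character vector of reads, each at least `n` bases.
#' @param code A `barcode_set` with metric `"hamming"`.
#' @param max_distance Acceptance threshold as in [sl_decode()].
#' @param ties Tie policy as in [sl_decode()].
#' @return A tibble like [sl_decode()]'s, with `boundary` fixed at `n`.
#' @export
hamming_decode <- function(reads, code, max_distance = NULL,
                           ties = c("ambiguous", "random")) {
  ties <- match.arg(ties)
  m <- code_meta(code)
  if (m$metric != "hamming") {
    stop("hamming_decode requires a code with metric 'hamming'", call. = FALSE)
  }
  if (nrow(code) == 0) stop("empty code", call. = FALSE)
  assert_dna(reads)
  if (any(nchar(reads) < m$n)) {
    stop("read(s) shorter than n = ", m$n, call. = FALSE)
  }
  max_distance <- max_distance %||% m$k
  md <- if (is.finite(max_distance)) as.integer(max_distance) else -1L
  res <- c_hamming_decode_batch(reads, code$sequence, m$n, md, ties == "random")
  tibble::tibble(
    read = reads,
    matched_index = res$index,
    matched_id = code$id[res$index],
    barcode = code$sequence[res$index],
    distance = res$distance,
    boundary = ifelse(res$status == 1L, m$n, NA_integer_),
    status = factor(STATUS_LEVELS[res$status], levels = STATUS_LEVELS)
  )
}

# Dispatch to the decoder matching a code's metric; best_effort drops the
# acceptance threshold (and, for the seqlev decoder, widens the window to the
# full read: with more than k errors the optimal alignment can extend past
# n + k). Returns a tibble with at least matched_index/status.
decode_by_metric <- function(reads, code, best_effort = FALSE) {
  m <- code_meta(code)
  switch(m$metric,
    seqlev = sl_decode(reads, code,
                       max_distance = if (best_effort) Inf else m$k,
                       window = if (best_effort) "full" else "bounded",
                       ties = if (best_effort) "random" else "ambiguous"),
    levenshtein = classic_decode_fixed_length(reads, code),
    hamming = hamming_decode(reads, code,
                             max_distance = if (best_effort) Inf else m$k,
                             ties = if (best_effort) "random" else "ambiguous")
  )
}
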