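# Chemical/sequence constraints on candidate barcodes.

#' Chemical filter policy for barcode candidates
#'
#' Candidate barcodes are screened for properties that make them reliable to
#' synthesize and sequence: GC content between `gc_min` and `gc_max`
#' (inclusive bounds), no homopolymer run longer than `max_homopolymer_run`
#' bases, and no perfect self reverse-complementarity (a barcode equal to its
#' own reverse complement can fold back on itself or its primer). The
#' defaults retain GC in \[0.40, 0.60\], runs of at most 2 and reject
#' self-reverse-complementary words.
#'
#' @param gc_min,gc_max Inclusive GC-fraction bounds in `[0, 1]`.
#' @param max_homopolymer_run Longest allowed run of identical bases.
#' @param reject_self_reverse_complement Reject words equal to their own
#'   reverse complement? (Only even-length words can be; for odd lengths the
#'   check never fires.)
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(gc_min = 0.4, gc_max = 0.6,
                          max_homopolymer_run = 2L,
                          reject_self_reverse_complement = TRUE) {
  stopifnot(gc_min >= 0, gc_max <= 1, gc_min <= gc_max,
            max_homopolymer_run >= 1)
  structure(
    list(gc_min = gc_min, gc_max = gc_max,
         max_homopolymer_run = as.integer(max_homopolymer_run),
         reject_self_reverse_complement = isTRUE(reject_self_reverse_complement)),
    class = "filter_policy"
  )
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy> GC in [", x$gc_min, ", ", x$gc_max, "], max run ",
      x$max_homopolymer_run, ", self-revcomp ",
      if (x$reject_self_reverse_complement) "rejected" else "allowed",
      "\n", sep = "")
  invisible(x)
}

#' GC fraction of DNA words
#'
#' @param x Character vector of non-empty DNA words.
#' @return Numeric vector of (#G + #C) / length values in `[0, 1]`.
#' @examples
#' gc_fraction(c("AAAA", "GCGC", "ACGTACGT"))
#' @export
gc_fraction <- function(x) {
  assert_dna(x, allow_empty = FALSE)
  (nchar(x) - nchar(gsub("[GC]", "", x))) / nchar(x)
}

#' Longest homopolymer run
#'
#' Length of the longest block of identical consecutive bases.
#'
#' @param x Character vector of non-empty DNA words.
#' @return Integer vector of run lengths (>= 1).
#' @examples
#' max_homopolymer_run(c("ACAC", "AACC", "GAAAT"))
#' @export
max_homopolymer_run <- function(x) {
  assert_dna(x, allow_empty = FALSE)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) max(rle(ch)$lengths), integer(1))
}

#' Apply a filter policy to candidate barcodes
#'
#' @param x Character vector of non-empty DNA words.
#' @param policy A [filter_policy()].
#' @return Logical vector: does each word pass every rule?
#' @examples
#' passes_filters(c("ACGT", "AAAC", "TTCC"))
#' @export
passes_filters <- function(x, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  assert_dna(x, allow_empty = FALSE)
  gc <- gc_fraction(x)
  ok <- gc >= policy$gc_min - 1e-9 & gc <= policy$gc_max + 1e-9 &
    max_homopolymer_run(x) <= policy$max_homopolymer_run
  if (policy$reject_self_reverse_complement) {
    ok <- ok & x != reverse_complement(x)
  }
  ok
}

#' Enumerate all filtered barcode candidates of a given length
#'
#' Generates every length-`n` word over A/C/G/T, keeps those passing the
#' filter policy, and returns them in lexicographic order (A < C < G < T,
#' matching the quaternary 0-3 encoding). This fixed order is what the
#' greedy closure scans, so candidate pools are fully deterministic.
#'
#' @param n Barcode length (>= 1).
#' @param policy A [filter_policy()].
#' @return Character vector of candidates, sorted, duplicate-free.
#' @examples
#' length(enumerate_candidates(4))
#' @export
enumerate_candidates <- function(n, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"), n >= 1)
  c_enumerate_candidates(as.integer(n), policy$gc_min, policy$gc_max,
                         policy$max_homopolymer_run,
                         policy$reject_self_reverse_complement)
}
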