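# Mutation models for barcode corruption.

#' Apply a fixed number of random edits to each word
#'
#' Applies `e` sequential random edits per word. Each edit's type is drawn
#' from `mix` (defaults: substitution, insertion and deletion equally
#' likely), its position uniformly on the word as it currently stands
#' (insertions have `length + 1` slots), substituted bases uniformly from
#' the 3 alternatives (a substitution always changes the base), and inserted
#' bases uniformly over A/C/G/T. Randomness comes from R's RNG.
#'
#' @param words Character vector of DNA words.
#' @param e Number of edits per word (>= 0).
#' @param mix Named numeric weights for `sub`, `ins`, `del` (need not sum
#'   to 1). `c(sub = 0, ins = 1, del = 1)` gives the pure-indel channel.
#' @return A tibble with columns `word`, `mutated`, `n_sub`, `n_ins`,
#'   `n_del`.
#' @examples
#' set.seed(1)
#' mutate_exact(c("CAGG", "TTCC"), e = 1)
#' @export
mutate_exact <- function(words, e, mix = c(sub = 1, ins = 1, del = 1)) {
  assert_dna(words)
  stopifnot(e >= 0)
  mix <- mix_weights(mix)
  res <- c_mutate_exact_batch(words, as.integer(e),
                              mix[["sub"]], mix[["ins"]], mix[["del"]])
  tibble::tibble(word = words, mutated = res$word,
                 n_sub = res$n_sub, n_ins = res$n_ins, n_del = res$n_del)
}

#' Mutate each base independently with probability p
#'
#' Every original base mutates with probability `p`; a mutating base is
#' (with equal probability 1/3 each) substituted by one of the 3 other
#' bases, deleted, or kept with a uniformly random base inserted in front of
#' it. Inserted bases are not re-mutated within the pass, so the expected
#' number of edits is exactly `p * nchar(word)`.
#'
#' @param words Character vector of DNA words.
#' @param p Per-base mutation probability in `[0, 1]`.
#' @return A tibble like [mutate_exact()]'s.
#' @export
mutate_per_base <- function(words, p) {
  assert_dna(words)
  stopifnot(p >= 0, p <= 1)
  res <- c_mutate_per_base_batch(words, p)
  tibble::tibble(word = words, mutated = res$word,
                 n_sub = res$n_sub, n_ins = res$n_ins, n_del = res$n_del)
}

mix_weights <- function(mix) {
  if (is.null(names(mix))) names(mix) <- c("sub", "ins", "del")[seq_along(mix)]
  w <- c(sub = 0, ins = 0, del = 0)
  bad <- setdiff(names(mix), names(w))
  if (length(bad)) stop("unknown mutation type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  w[names(mix)] <- mix
  if (any(w < 0) || sum(w) <= 0) {
    stop("mutation weights must be non-negative with a positive sum", call. = FALSE)
  }
  w
}

#' Enumerate every word reachable by at most e edits
#'
#' The complete, duplicate-free set of words obtainable from `word` by at
#' most `e` substitutions, insertions or deletions (the unedited word itself
#' included, since 0 edits <= e). For one edit on a word of length n the raw
#' operation count is `3n` substitutions, `4(n + 1)` insertions and `n`
#' deletions before deduplication. Used by the exhaustive guarantee check
#' ([simulation2()]).
#'
#' @param word A single DNA word.
#' @param e Maximum number of edits (1 or 2).
#' @return Sorted character vector of distinct corrupted words; every member
#'   `w` satisfies `levenshtein_distance(word, w) <= e`.
#' @examples
#' enumerate_corruptions("A", 1)
#' @export
enumerate_corruptions <- function(word, e) {
  stopifnot(length(word) == 1, e %in% c(1, 2))
  assert_dna(word)
  out <- one_edit_neighbours(word)
  if (e == 2) {
    out <- unique(c(out, unlist(lapply(out, one_edit_neighbours))))
  }
  sort(out)
}

one_edit_neighbours <- function(word) {
  n <- nchar(word)
  bases <- c("A", "C", "G", "T")
  subs <- character(0); ins <- character(0); dels <- character(0)
  if (n > 0) {
    pos <- rep(seq_len(n), each = 4)
    b <- rep(bases, n)
    subs <- paste0(substring(word, 1, pos - 1), b, substring(word, pos + 1, n))
    dels <- vapply(seq_len(n), function(i) {
      paste0(substring(word, 1, i - 1), substring(word, i + 1, n))
    }, character(1))
  }
  posi <- rep(0:n, each = 4)
  bi <- rep(bases, n + 1)
  ins <- paste0(substring(word, 1, posi), bi, substring(word, posi + 1, n))
  unique(c(word, subs, ins, dels))
}
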