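#' Barcode distance metrics
#'
#' Pairwise distances between DNA words under the three metrics used for
#' barcode design:
#'
#' * `hamming_distance()`: number of differing positions (equal-length words
#'   only); corrects substitutions.
#' * `levenshtein_distance()`: minimum number of substitutions, insertions
#'   and deletions transforming one word into the other (unit costs).
#' * `seqlev_distance()`: the Sequence-Levenshtein distance — edits
#'   transforming `a` towards `b` followed by one free truncation or
#'   elongation to match `b` exactly. Equivalently, the minimum over the last
#'   row and last column of the Levenshtein dynamic-programming matrix. It is
#'   zero exactly when one word is a prefix of the other, which is the right
#'   notion of identity when a barcode is embedded at the start of a longer
#'   read.
#'
#' All three are vectorized over pairs: `a` and `b` must have equal length
#' (or either may be a scalar, which is recycled).
#'
#' @param a,b Character vectors of DNA words (A/C/G/T; empty words allowed
#'   except for `hamming_distance`, where lengths must match).
#' @return Integer vector of distances.
#' @examples
#' levenshtein_distance("CAGG", "CGTC")  # 3
#' seqlev_distance("CAGG", "CGTC")       # 2
#' seqlev_distance("AC", "ACGT")         # 0: prefix
#' @export
hamming_distance <- function(a, b) {
  p <- recycle_pair(a, b)
  c_pair_distance(p$a, p$b, 0L)
}

#' @rdname hamming_distance
#' @export
levenshtein_distance <- function(a, b) {
  p <- recycle_pair(a, b)
  c_pair_distance(p$a, p$b, 1L)
}

#' @rdname hamming_distance
#' @export
seqlev_distance <- function(a, b) {
  p <- recycle_pair(a, b)
  c_pair_distance(p$a, p$b, 2L)
}

recycle_pair <- function(a, b) {
  assert_dna(a, arg = "a")
  assert_dna(b, arg = "b")
  if (length(a) != length(b)) {
    if (length(a) == 1) a <- rep(a, length(b))
    else if (length(b) == 1) b <- rep(b, length(a))
    else stop("'a' and 'b' must have equal length (or one must be a scalar)",
              call. = FALSE)
  }
  list(a = a, b = b)
}

#' Levenshtein dynamic-programming matrix
#'
#' The full (|a|+1) x (|b|+1) Wagner-Fischer matrix with unit edit costs.
#' Cell `[i+1, j+1]` holds the Levenshtein distance between the length-i
#' prefix of `a` and the length-j prefix of `b`; the bottom-right cell is the
#' classic distance and the minimum over the last row and last column is the
#' Sequence-Levenshtein distance.
#'
#' @param a,b Single DNA words.
#' @return Integer matrix with prefix strings as dimnames.
#' @examples
#' m <- levenshtein_matrix("TTCC", "TCCATGCATA")
#' m[nrow(m), ]                 # last row
#' min(m[nrow(m), ], m[, ncol(m)])  # seqlev_distance("TTCC", "TCCATGCATA")
#' @export
levenshtein_matrix <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  assert_dna(a, arg = "a"); assert_dna(b, arg = "b")
  m <- c_lev_matrix(a, b)
  pref <- function(x) substring(x, 1, 0:nchar(x))
  dimnames(m) <- list(pref(a), pref(b))
  m
}
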