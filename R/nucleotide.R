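# Plain-character helpers for words over the quaternary DNA alphabet.

assert_dna <- function(x, allow_empty = TRUE, arg = deparse(substitute(x))) {
  if (!is.character(x)) stop("'", arg, "' must be a character vector", call. = FALSE)
  if (anyNA(x)) stop("'", arg, "' contains NA", call. = FALSE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("'", arg, "' contains non-ACGT characters (first offender: '",
         x[which(bad)[1]], "')", call. = FALSE)
  }
  if (!allow_empty && any(!nzchar(x))) {
    stop("'", arg, "' contains an empty word", call. = FALSE)
  }
  invisible(x)
}

#' Encode and decode DNA words in the quaternary alphabet
#'
#' DNA bases A, C, G, T are identified with the digits 0, 1, 2, 3. The two
#' functions are exact inverses of each other.
#'
#' @param word A single DNA word (character scalar over A/C/G/T).
#' @param digits An integer vector with values in 0:3.
#' @return `encode_dna()` returns an integer vector of quaternary digits;
#'   `decode_dna()` returns the corresponding DNA word.
#' @examples
#' encode_dna("ACGT")
#' decode_dna(c(3L, 0L))
#' @export
encode_dna <- function(word) {
  stopifnot(length(word) == 1)
  assert_dna(word)
  if (!nzchar(word)) return(integer(0))
  match(strsplit(word, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
}

#' @rdname encode_dna
#' @export
decode_dna <- function(digits) {
  if (length(digits) == 0) return("")
  digits <- as.integer(digits)
  if (anyNA(digits) || any(digits < 0L | digits > 3L)) {
    stop("quaternary digits must be integers in 0..3", call. = FALSE)
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

#' Reverse complement of DNA words
#'
#' Watson-Crick complement of the reversed word; an involution.
#'
#' @param x Character vector of DNA words.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAA"))
#' @export
reverse_complement <- function(x) {
  assert_dna(x)
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Random DNA words
#'
#' Uniform i.i.d. words over A/C/G/T, drawn from R's RNG (so `set.seed()`
#' makes them reproducible).
#'
#' @param n_words Number of words.
#' @param length Length of each word.
#' @return Character vector of `n_words` DNA words.
#' @export
random_dna <- function(n_words, length) {
  stopifnot(n_words >= 0, length >= 0)
  c_random_words(as.integer(n_words), as.integer(length))
}
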