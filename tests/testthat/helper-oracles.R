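# Independent oracles, written directly from the textbook definitions and
# kept free of the package's DP code paths.

# Memoized recursion over the classic Levenshtein recurrence.
oracle_lev <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  memo <- matrix(NA_integer_, la + 1, lb + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0) {
      j
    } else if (j == 0) {
      i
    } else {
      cost <- as.integer(substr(a, i, i) != substr(b, j, j))
      min(rec(i - 1, j - 1) + cost, rec(i - 1, j) + 1L, rec(i, j - 1) + 1L)
    }
    memo[i + 1, j + 1] <<- as.integer(v)
    memo[i + 1, j + 1]
  }
  rec(la, lb)
}

# Brute-force prefix-minimum realisation of the truncate/elongate definition:
# min( min_i d_L(a[1..i], b), min_j d_L(a, b[1..j]) ). `lev` defaults to the
# package's Levenshtein (itself checked against oracle_lev elsewhere); pass
# oracle_lev for a fully independent check.
oracle_seqlev <- function(a, b, lev = levenshtein_distance) {
  min(vapply(0:nchar(a), function(i) lev(substr(a, 1, i), b), integer(1)),
      vapply(0:nchar(b), function(j) lev(a, substr(b, 1, j)), integer(1)))
}

rand_word <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rand_words <- function(n, lens) {
  lens <- if (length(lens) == 1) rep.int(lens, n) else
    lens[sample.int(length(lens), n, replace = TRUE)]
  vapply(lens, rand_word, character(1))
}

# All ACGT words of a given length (lexicographic).
all_words <- function(len) {
  if (len == 0) return("")
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), len),
                                  stringsAsFactors = FALSE)))
}

# The four-barcode worked-example code.
example_code <- function() {
  barcode_set(c("TTCC", "ACAC", "CGAA", "TAGG"), metric = "seqlev", dmin = 3)
}
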