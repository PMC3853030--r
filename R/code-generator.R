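# Barcode sets (codes) and their construction by greedy closure.

#' Construct a barcode set
#'
#' A barcode set (a *code*) is a collection of equal-length barcodes
#' (*codewords*) whose pairwise distances under a chosen metric are all at
#' least `dmin`. A code with `dmin = 2k + 1` corrects `k` errors under its
#' own metric; the number of errors *guaranteed in DNA context* (barcode
#' followed by sample sequence) additionally depends on the metric:
#' Sequence-Levenshtein codes keep the full `k`, classic Levenshtein codes
#' under fixed-length decoding need `dmin = 4k + 1` for `k` context errors,
#' and Hamming codes guarantee none once indels are possible.
#'
#' The object is a tibble with columns `id` and `sequence`, carrying the code
#' metadata (`metric`, `dmin`, `n`, `k`, `context_k`, `policy`) as
#' attributes, so it pipes into the usual data-frame verbs.
#'
#' @param barcodes Character vector of equal-length DNA words, no duplicates.
#' @param metric One of `"hamming"`, `"levenshtein"`, `"seqlev"`.
#' @param dmin Guaranteed minimum pairwise distance (>= 1).
#' @param policy The [filter_policy()] the barcodes are expected to satisfy,
#'   or `NULL` for none.
#' @param ids Optional barcode ids; defaults to `BC001`, `BC002`, ...
#' @param verify Check the pairwise-distance and filter invariants on
#'   construction (via [verify_code()]) and fail if violated.
#' @return A `barcode_set`.
#' @examples
#' barcode_set(c("TTCC", "ACAC", "CGAA", "TAGG"), metric = "seqlev", dmin = 3)
#' @export
barcode_set <- function(barcodes, metric = c("seqlev", "levenshtein", "hamming"),
                        dmin, policy = filter_policy(), ids = NULL,
                        verify = TRUE) {
  metric <- match.arg(metric)
  assert_dna(barcodes, allow_empty = FALSE)
  stopifnot(length(barcodes) >= 1, dmin >= 1)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in set", call. = FALSE)
  n <- unique(nchar(barcodes))
  if (length(n) != 1) stop("barcodes must all have the same length", call. = FALSE)
  if (is.null(ids)) {
    ids <- sprintf("BC%0*d", max(3L, nchar(length(barcodes))), seq_along(barcodes))
  }
  if (anyDuplicated(ids)) stop("duplicate barcode ids", call. = FALSE)
  dmin <- as.integer(dmin)
  out <- tibble::tibble(id = as.character(ids), sequence = barcodes)
  class(out) <- c("barcode_set", class(out))
  attr(out, "metric") <- metric
  attr(out, "dmin") <- dmin
  attr(out, "n") <- as.integer(n)
  attr(out, "k") <- (dmin - 1L) %/% 2L
  attr(out, "context_k") <- switch(metric,
    seqlev = (dmin - 1L) %/% 2L,
    levenshtein = (dmin - 1L) %/% 4L,
    hamming = 0L
  )
  attr(out, "policy") <- policy
  if (verify) {
    v <- verify_code(out)
    if (!v$valid) {
      stop("barcode set violates its own invariants: ",
           nrow(v$violations), " pair(s) below dmin, ",
           nrow(v$filter_failures), " filter failure(s)", call. = FALSE)
    }
  }
  out
}

code_meta <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  list(metric = attr(set, "metric"), dmin = attr(set, "dmin"),
       n = attr(set, "n"), k = attr(set, "k"),
       context_k = attr(set, "context_k"), policy = attr(set, "policy"))
}

#' @export
print.barcode_set <- function(x, ...) {
  m <- code_meta(x)
  cat("<barcode_set> ", nrow(x), " barcodes of length ", m$n,
      ", metric ", m$metric, ", dmin ", m$dmin,
      " (corrects ", m$k, " error(s); ", m$context_k,
      " guaranteed in DNA context)\n", sep = "")
  NextMethod()
}

#' @export
tidy.barcode_set <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @export
glance.barcode_set <- function(x, ...) {
  m <- code_meta(x)
  tibble::tibble(
    metric = m$metric, n = m$n, dmin = m$dmin, k = m$k,
    context_k = m$context_k, size = nrow(x), code_rate = code_rate(x)
  )
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), "barcode_set")
  attr(x, "metric") <- NULL; attr(x, "dmin") <- NULL; attr(x, "n") <- NULL
  attr(x, "k") <- NULL; attr(x, "context_k") <- NULL; attr(x, "policy") <- NULL
  x
}

#' Greedy closure of a seed under a minimum-distance constraint
#'
#' Walks through the candidate pool in lexicographic order and accepts every
#' barcode whose distance to all previously accepted barcodes (seed
#' included) is at least `dmin`. Deterministic given its inputs. The seed —
#' a small set of barcodes already satisfying the constraint — steers which
#' maximal code the scan settles into; the evolutionary search
#' ([evolutionary_search()]) optimizes over seeds.
#'
#' @param seed Character vector of seed barcodes (may be empty for a plain
#'   lexicographic greedy scan). Must itself satisfy the pairwise constraint.
#' @param candidates Candidate pool in scan order, typically from
#'   [enumerate_candidates()].
#' @param dmin Minimum pairwise distance.
#' @param metric Distance metric name.
#' @param max_size Stop the scan once this many barcodes are accepted
#'   (`Inf` for no cap) — useful when only a fixed number of samples is
#'   needed.
#' @param policy Filter policy recorded on (and checked for) the result;
#'   `NULL` to skip.
#' @return A `barcode_set` containing the seed plus all accepted candidates.
#' @export
greedy_closure <- function(seed, candidates,
                           dmin, metric = c("seqlev", "levenshtein", "hamming"),
                           max_size = Inf, policy = filter_policy()) {
  metric <- match.arg(metric)
  seed <- as.character(seed %||% character(0))
  if (length(seed) > 0) assert_dna(seed, allow_empty = FALSE)
  assert_dna(candidates, allow_empty = FALSE)
  ms <- if (is.finite(max_size)) as.integer(max_size) else -1L
  out <- c_greedy_closure(seed, candidates, as.integer(dmin),
                          metric_int(metric), ms)
  barcode_set(out, metric = metric, dmin = dmin, policy = policy,
              verify = FALSE)
}

#' Greedy closure evolutionary search for large barcode sets
#'
#' Evolves small seeds (2-4 barcodes satisfying the distance constraint)
#' whose fitness is the size of their greedy closure over the filtered
#' candidate pool, and returns the largest code found. Selection is a size-2
#' tournament on a steady-state population; variation replaces one seed
#' member with a random candidate that keeps the seed internally valid
#' (mutation only — successful seeds are perturbed rather than recombined).
#' The budget is counted in greedy-closure evaluations, so a run's effort is
#' hardware independent. The best-so-far code size never decreases, and the
#' whole search is reproducible from R's RNG state (use `set.seed()`).
#'
#' @param n Barcode length.
#' @param k Number of errors the code must correct under its metric;
#'   `dmin = 2k + 1`.
#' @param metric Distance metric name.
#' @param policy Filter policy defining the candidate pool.
#' @param population Number of seeds kept in the population.
#' @param seed_size Barcodes per seed (2-4).
#' @param budget Total number of greedy-closure evaluations.
#' @param target_size Optional early stop once a code of at least this size
#'   is found (e.g. the number of samples to be multiplexed).
#' @param candidates Optional precomputed candidate pool (must be the
#'   lexicographic pool for `n` and `policy`).
#' @return The largest `barcode_set` found; attributes `evaluations` and
#'   `best_trace` (best size after each evaluation) record the search.
#' @examples
#' set.seed(1)
#' code <- evolutionary_search(5, k = 1, metric = "seqlev", budget = 20)
#' nrow(code)
#' @export
evolutionary_search <- function(n, k, metric = c("seqlev", "levenshtein", "hamming"),
                                policy = filter_policy(), population = 50L,
                                seed_size = 3L, budget = 300L,
                                target_size = NULL, candidates = NULL) {
  metric <- match.arg(metric)
  stopifnot(k >= 1, population >= 1, budget >= 1,
            seed_size >= 2, seed_size <= 4)
  dmin <- 2L * as.integer(k) + 1L
  cand <- candidates %||% enumerate_candidates(n, policy)
  if (length(cand) == 0) stop("no candidates pass the filter policy", call. = FALSE)
  mint <- metric_int(metric)

  draw_seed <- function() {
    s <- sample(cand, 1L)
    tries <- 0L
    while (length(s) < seed_size && tries < 200L) {
      cnd <- sample(cand, 1L)
      if (all(c_pair_distance(rep(cnd, length(s)), s, mint) >= dmin)) {
        s <- c(s, cnd)
      }
      tries <- tries + 1L
    }
    s
  }
  mutate_seed <- function(s) {
    slot <- sample.int(length(s), 1L)
    for (tries in 1:200) {
      cnd <- sample(cand, 1L)
      rest <- s[-slot]
      if (!cnd %in% rest &&
          all(c_pair_distance(rep(cnd, length(rest)), rest, mint) >= dmin)) {
        s[slot] <- cnd
        return(s)
      }
    }
    draw_seed()
  }

  best <- character(0)
  trace <- integer(0)
  evals <- 0L
  evaluate <- function(s) {
    cl <- c_greedy_closure(s, cand, dmin, mint, -1L)
    evals <<- evals + 1L
    if (length(cl) > length(best)) best <<- cl
    trace[evals] <<- length(best)
    length(cl)
  }

  pop <- replicate(population, draw_seed(), simplify = FALSE)
  fit <- integer(population)
  for (i in seq_len(population)) {
    if (evals >= budget) break
    fit[i] <- evaluate(pop[[i]])
    if (!is.null(target_size) && length(best) >= target_size) break
  }
  while (evals < budget &&
         (is.null(target_size) || length(best) < target_size)) {
    contenders <- sample.int(population, 2L)
    parent <- contenders[which.max(fit[contenders])]
    child <- mutate_seed(pop[[parent]])
    f <- evaluate(child)
    worst <- which.min(fit)
    if (f >= fit[worst]) {
      pop[[worst]] <- child
      fit[worst] <- f
    }
  }

  out <- barcode_set(best, metric = metric, dmin = dmin, policy = policy,
                     verify = FALSE)
  attr(out, "evaluations") <- evals
  attr(out, "best_trace") <- trace
  out
}

#' Verify a barcode set by brute force
#'
#' Recomputes every pairwise distance and every filter rule from scratch and
#' reports all violations. Generation uses memoized/incremental distance
#' checks, so this is the independent safety net: a set is valid iff
#' `verify_code(set)$valid`.
#'
#' @param set A `barcode_set`.
#' @return A list with `valid` (logical), `violations` (tibble of pairs with
#'   distance below `dmin`) and `filter_failures` (tibble of barcodes
#'   failing the policy).
#' @export
verify_code <- function(set) {
  m <- code_meta(set)
  pairs <- c_violating_pairs(set$sequence, m$dmin, metric_int(m$metric))
  violations <- tibble::tibble(
    i = pairs[, 1], j = pairs[, 2],
    sequence_i = set$sequence[pairs[, 1]],
    sequence_j = set$sequence[pairs[, 2]],
    distance = pairs[, 3]
  )
  if (!is.null(m$policy)) {
    ok <- passes_filters(set$sequence, m$policy)
    filter_failures <- tibble::tibble(
      id = set$id[!ok], sequence = set$sequence[!ok]
    )
  } else {
    filter_failures <- tibble::tibble(id = character(0), sequence = character(0))
  }
  list(valid = nrow(violations) == 0 && nrow(filter_failures) == 0,
       violations = violations,
       filter_failures = filter_failures)
}

#' Code rate of a barcode set
#'
#' Information efficiency of a code: `log2(size) / log2(4^n)`, i.e. the
#' fraction of the theoretical `2n` bits per barcode actually used to
#' address samples.
#'
#' @param set A `barcode_set`, or a code size (count) if `n` is given.
#' @param n Barcode length, only when `set` is a plain count.
#' @return The code rate in `[0, 1]`.
#' @examples
#' code_rate(188, n = 8)  # ~0.472
#' code_rate(552, n = 8)  # ~0.569
#' @export
code_rate <- function(set, n = NULL) {
  if (inherits(set, "barcode_set")) {
    size <- nrow(set)
    n <- attr(set, "n")
  } else {
    size <- set
    if (is.null(n)) stop("'n' is required when 'set' is a count", call. = FALSE)
  }
  stopifnot(size >= 1, n >= 1)
  log2(size) / (2 * n)
}
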