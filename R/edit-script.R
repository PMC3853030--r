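#' Optimal edit script under the Sequence-Levenshtein distance
#'
#' Traces back one optimal chain of substitutions, insertions and deletions
#' that transforms `a` towards `b`, finished by the free truncation or
#' elongation step of the Sequence-Levenshtein distance. The script's cost
#' (number of operations) equals `seqlev_distance(a, b)`.
#'
#' The boundary cell of the DP matrix is chosen by a deterministic tie-break:
#' last-row cells are preferred over last-column cells, and among last-row
#' cells the column `j` closest to `|a|` wins (larger `j` on ties). This
#' keeps the net indel balance of the script as close to zero as possible,
#' which is what makes the recovered word boundary `|a| + insertions -
#' deletions` the canonical one during decoding.
#'
#' Operation positions are 1-based on the *evolving* word: operations are
#' meant to be applied in order, each position interpreted on the word as it
#' stands at that point (see [apply_edit_script()]).
#'
#' @param a Source DNA word (for decoding: the candidate barcode).
#' @param b Target DNA word (for decoding: the read or read prefix).
#' @return An object of class `edit_script`: a list with elements
#'   `ops` (tibble with columns `op`, `pos`, `base`), `final_action`
#'   (`"truncate"`, `"elongate"` or `"none"`), `elongate_with`,
#'   `n_sub`, `n_ins`, `n_del`, `cost`, `boundary`, `source`, `target`.
#' @examples
#' s <- sl_traceback("TTCC", "TCCATGCATA")
#' s$cost       # 1
#' s$boundary   # 3: the read splits as TCC | ATGCATA
#' apply_edit_script(s)  # "TCCATGCATA"
#' @export
sl_traceback <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  assert_dna(a, arg = "a"); assert_dna(b, arg = "b")
  cell <- c_seqlev_boundary(a, b)
  dist <- cell[["distance"]]; row <- cell[["row"]]; col <- cell[["col"]]
  m <- c_lev_matrix(a, b)
  ac <- if (nzchar(a)) strsplit(a, "", fixed = TRUE)[[1]] else character(0)
  bc <- if (nzchar(b)) strsplit(b, "", fixed = TRUE)[[1]] else character(0)

  # Backtrace from the boundary cell to (0, 0); prefer diagonal (match or
  # substitution), then up (deletion), then left (insertion).
  i <- row; j <- col
  op <- character(0); src <- integer(0); base <- character(0)
  while (i > 0 || j > 0) {
    v <- m[i + 1, j + 1]
    if (i > 0 && j > 0 && m[i, j] + (ac[i] != bc[j]) == v) {
      if (ac[i] != bc[j]) {
        op <- c("sub", op); src <- c(i, src); base <- c(bc[j], base)
      }
      i <- i - 1; j <- j - 1
    } else if (i > 0 && m[i, j + 1] + 1 == v) {
      op <- c("del", op); src <- c(i, src); base <- c(NA_character_, base)
      i <- i - 1
    } else {
      op <- c("ins", op); src <- c(i, src); base <- c(bc[j], base)
      j <- j - 1
    }
  }

  # Convert source-anchored positions to positions on the evolving word.
  shift <- 0L
  pos <- integer(length(op))
  for (t in seq_along(op)) {
    if (op[t] == "sub") {
      pos[t] <- src[t] + shift
    } else if (op[t] == "del") {
      pos[t] <- src[t] + shift
      shift <- shift - 1L
    } else {
      pos[t] <- src[t] + shift + 1L
      shift <- shift + 1L
    }
  }

  if (row == nchar(a)) {
    final_action <- if (col < nchar(b)) "elongate" else "none"
    elongate_with <- if (col < nchar(b)) substring(b, col + 1) else ""
  } else {
    final_action <- "truncate"
    elongate_with <- ""
  }

  structure(
    list(
      ops = tibble::tibble(op = op, pos = pos, base = base),
      final_action = final_action,
      elongate_with = elongate_with,
      n_sub = sum(op == "sub"),
      n_ins = sum(op == "ins"),
      n_del = sum(op == "del"),
      cost = dist,
      boundary = col,
      source = a,
      target = b
    ),
    class = "edit_script"
  )
}

#' Replay an edit script
#'
#' Applies the operations of an [sl_traceback()] script in order, then the
#' final truncate/elongate action. Replaying a script on its source word
#' reproduces its target word exactly.
#'
#' @param script An `edit_script`.
#' @param word Word to apply the script to; defaults to the script's source.
#' @return The transformed word.
#' @export
apply_edit_script <- function(script, word = script$source) {
  stopifnot(inherits(script, "edit_script"))
  ch <- if (nzchar(word)) strsplit(word, "", fixed = TRUE)[[1]] else character(0)
  ops <- script$ops
  for (t in seq_len(nrow(ops))) {
    p <- ops$pos[t]
    switch(ops$op[t],
      sub = { ch[p] <- ops$base[t] },
      del = { ch <- ch[-p] },
      ins = { ch <- append(ch, ops$base[t], after = p - 1L) }
    )
  }
  out <- paste(ch, collapse = "")
  if (script$final_action == "truncate") {
    out <- substring(out, 1, nchar(script$target))
  } else if (script$final_action == "elongate") {
    out <- paste0(out, script$elongate_with)
  }
  out
}

#' @export
print.edit_script <- function(x, ...) {
  cat("<edit_script> ", x$source, " -> ", x$target,
      "  (cost ", x$cost, ")\n", sep = "")
  if (nrow(x$ops) == 0) {
    cat("  no edit operations\n")
  } else {
    lab <- ifelse(x$ops$op == "del",
                  sprintf("del(%d)", x$ops$pos),
                  sprintf("%s(%s,%d)", x$ops$op, x$ops$base, x$ops$pos))
    cat("  ", paste(lab, collapse = ", "), "\n", sep = "")
  }
  cat("  final action: ", x$final_action,
      if (x$final_action == "elongate") paste0(" (\"", x$elongate_with, "\")"),
      "; boundary ", x$boundary, "\n", sep = "")
  invisible(x)
}
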