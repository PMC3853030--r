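# Indel-aware FASTQ demultiplexing.

#' Demultiplex a FASTQ file by Sequence-Levenshtein barcodes
#'
#' Decodes each read's barcode with the decoder matching the code's metric
#' (for Sequence-Levenshtein codes this is [sl_decode()], which recovers the
#' post-mutation barcode length), trims the barcode at the recovered
#' boundary (qualities trimmed identically) and writes each sample's reads
#' to `sample_<id>.fastq` in `out_dir`. Ambiguous and rejected reads keep
#' their full sequence and go to `undetermined.fastq`; reads too short to
#' contain a recoverable barcode (< n - k bases) are rejected rather than
#' decoded. With `ambiguous = "random"`, ties are instead resolved uniformly
#' at random (seed R's RNG for reproducibility).
#'
#' @param path Input FASTQ, optionally gzipped.
#' @param code A verified `barcode_set` (verified again here before any
#'   read is processed).
#' @param out_dir Output directory, created if needed.
#' @param max_distance Acceptance threshold passed to the decoder; default
#'   the code's `k`.
#' @param ambiguous `"reject"` (default) sends ties to undetermined;
#'   `"random"` picks uniformly among the tied codewords.
#' @param compress Write gzipped outputs?
#' @return A `demux_summary` tibble: one row per sample plus
#'   `undetermined`, with columns `sample_id`, `n_unique`, `n_ambiguous`,
#'   `n_rejected`, `mean_distance`, `mean_boundary`.
#' @export
demultiplex <- function(path, code, out_dir, max_distance = NULL,
                        ambiguous = c("reject", "random"), compress = FALSE) {
  ambiguous <- match.arg(ambiguous)
  meta <- code_meta(code)
  v <- verify_code(code)
  if (!v$valid) {
    stop("refusing to demultiplex with an invalid code (",
         nrow(v$violations), " pair(s) below dmin)", call. = FALSE)
  }
  recs <- read_fastq(path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  decodable <- nchar(recs$sequence) >= meta$n - meta$k
  dec <- tibble::tibble(matched_index = rep(NA_integer_, nrow(recs)),
                        distance = NA_integer_,
                        boundary = NA_integer_,
                        status = factor(rep("rejected", nrow(recs)),
                                        levels = STATUS_LEVELS))
  tie_mode <- if (ambiguous == "random") "random" else "ambiguous"
  if (any(decodable)) {
    d <- switch(meta$metric,
      seqlev = sl_decode(recs$sequence[decodable], code,
                         max_distance = max_distance, ties = tie_mode),
      hamming = hamming_decode(recs$sequence[decodable], code,
                               max_distance = max_distance, ties = tie_mode),
      levenshtein = {
        cd <- classic_decode_fixed_length(recs$sequence[decodable], code)
        tibble::tibble(matched_index = cd$matched_index,
                       distance = cd$distance, boundary = cd$window_used,
                       status = factor(ifelse(cd$status == "unique",
                                              "unique", "ambiguous"),
                                       levels = STATUS_LEVELS))
      })
    dec[decodable, c("matched_index", "distance", "boundary", "status")] <-
      d[, c("matched_index", "distance", "boundary", "status")]
  }

  assigned <- !is.na(dec$matched_index) &
    (dec$status == "unique" |
       (ambiguous == "random" & dec$status == "ambiguous"))
  trim_at <- pmin(pmax(dec$boundary, 0L), nchar(recs$sequence))
  outputs <- character(0)
  for (ci in seq_len(nrow(code))) {
    sel <- which(assigned & dec$matched_index == ci)
    f <- file.path(out_dir, paste0("sample_", code$id[ci], ".fastq",
                                   if (compress) ".gz" else ""))
    write_fastq(tibble::tibble(
      id = recs$id[sel],
      sequence = substring(recs$sequence[sel], trim_at[sel] + 1L),
      quality = substring(recs$quality[sel], trim_at[sel] + 1L)
    ), f)
    outputs <- c(outputs, f)
  }
  und <- which(!assigned)
  undf <- file.path(out_dir, paste0("undetermined.fastq",
                                    if (compress) ".gz" else ""))
  write_fastq(recs[und, ], undf)

  per_sample <- lapply(seq_len(nrow(code)), function(ci) {
    sel <- assigned & dec$matched_index == ci
    tibble::tibble(
      sample_id = code$id[ci],
      n_unique = sum(sel),
      n_ambiguous = 0L, n_rejected = 0L,
      mean_distance = if (any(sel)) mean(dec$distance[sel]) else NA_real_,
      mean_boundary = if (any(sel)) mean(dec$boundary[sel]) else NA_real_
    )
  })
  summary <- dplyr::bind_rows(c(per_sample, list(tibble::tibble(
    sample_id = "undetermined",
    n_unique = 0L,
    n_ambiguous = sum(dec$status == "ambiguous" & !assigned),
    n_rejected = sum(dec$status == "rejected"),
    mean_distance = NA_real_, mean_boundary = NA_real_
  ))))
  class(summary) <- c("demux_summary", class(summary))
  attr(summary, "files") <- c(outputs, undf)
  attr(summary, "n_reads") <- nrow(recs)
  summary
}

#' @export
tidy.demux_summary <- function(x, ...) {
  class(x) <- setdiff(class(x), "demux_summary")
  attr(x, "files") <- NULL
  attr(x, "n_reads") <- NULL
  x
}
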