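# File formats: barcode manifests (TSV/FASTA + JSON sidecar) and FASTQ.

#' Write a barcode set to disk
#'
#' Writes the barcodes as a TSV (columns `id`, `sequence`) or FASTA file,
#' plus (by default) a JSON sidecar `<path>.json` recording the code's
#' guarantees (metric, dmin, n, k, filter policy, size) so that a later
#' decoding run never has to guess them. Both formats round-trip losslessly
#' through [read_barcode_manifest()].
#'
#' @param set A `barcode_set`.
#' @param path Output file; extension `.tsv`/`.txt` for TSV, `.fa`/`.fasta`
#'   for FASTA (or use `format`).
#' @param format `"tsv"` or `"fasta"`; default inferred from `path`.
#' @param sidecar Write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_barcode_set <- function(set, path, format = NULL, sidecar = TRUE) {
  stopifnot(inherits(set, "barcode_set"))
  format <- format %||% guess_manifest_format(path)
  if (format == "tsv") {
    readr::write_tsv(tibble::tibble(id = set$id, sequence = set$sequence), path)
  } else {
    seqs <- Biostrings::DNAStringSet(stats::setNames(set$sequence, set$id))
    Biostrings::writeXStringSet(seqs, path)
  }
  if (sidecar) {
    m <- code_meta(set)
    jsonlite::write_json(
      list(metric = m$metric, dmin = m$dmin, n = m$n, k = m$k,
           context_k = m$context_k, size = nrow(set),
           policy = if (!is.null(m$policy)) unclass(m$policy)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a barcode manifest
#'
#' Reads a barcode set from a TSV (columns `id`, `sequence`) or FASTA file.
#' Lowercase bases are uppercased; any other non-ACGT character, duplicate
#' id or sequence, or ragged barcode length is a format error naming the
#' offending record. The code's metric and `dmin` are taken from the JSON
#' sidecar written by [write_barcode_set()] when present, else from the
#' arguments. The parsed set is verified ([verify_code()]) before use.
#'
#' @param path Manifest file.
#' @param metric,dmin Code guarantees, required when no sidecar exists.
#' @param policy Filter policy for verification; `NULL` skips filter checks
#'   (sidecar policies are honored when present).
#' @param format `"tsv"` or `"fasta"`; default inferred from `path`.
#' @return A verified `barcode_set`.
#' @export
read_barcode_manifest <- function(path, metric = NULL, dmin = NULL,
                                  policy = NULL, format = NULL) {
  format <- format %||% guess_manifest_format(path)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    if (!all(c("id", "sequence") %in% names(df))) {
      stop("manifest must have columns 'id' and 'sequence'", call. = FALSE)
    }
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    df <- tibble::tibble(id = unname(names(seqs)),
                         sequence = unname(as.character(seqs)))
  }
  df$sequence <- toupper(df$sequence)
  bad <- grepl("[^ACGT]", df$sequence)
  if (any(bad)) {
    w <- which(bad)[1]
    stop("record ", w, " ('", df$id[w], "'): non-ACGT sequence '",
         df$sequence[w], "'", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate id '", df$id[anyDuplicated(df$id)], "'", call. = FALSE)
  }
  if (anyDuplicated(df$sequence)) {
    w <- anyDuplicated(df$sequence)
    stop("record ", w, " ('", df$id[w], "'): duplicate sequence", call. = FALSE)
  }
  if (length(unique(nchar(df$sequence))) != 1) {
    w <- which(nchar(df$sequence) != nchar(df$sequence)[1])[1]
    stop("record ", w, " ('", df$id[w], "'): barcode length differs from record 1",
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    metric <- metric %||% meta$metric
    dmin <- dmin %||% meta$dmin
    if (is.null(policy) && !is.null(meta$policy)) {
      policy <- filter_policy(meta$policy$gc_min, meta$policy$gc_max,
                              meta$policy$max_homopolymer_run,
                              meta$policy$reject_self_reverse_complement)
    }
  }
  if (is.null(metric) || is.null(dmin)) {
    stop("no sidecar found: 'metric' and 'dmin' must be given", call. = FALSE)
  }
  set <- barcode_set(df$sequence, metric = metric, dmin = dmin,
                     policy = policy, ids = df$id, verify = FALSE)
  v <- verify_code(set)
  if (!v$valid) {
    stop("manifest fails verification: ", nrow(v$violations),
         " pair(s) below dmin = ", dmin,
         if (nrow(v$filter_failures) > 0)
           paste0(", ", nrow(v$filter_failures), " filter failure(s)"),
         call. = FALSE)
  }
  set
}

guess_manifest_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("fa", "fasta", "fna")) "fasta" else "tsv"
}

#' Read and write FASTQ files
#'
#' Thin tidy wrappers around Biostrings' FASTQ support (gzipped input and
#' output work transparently). `read_fastq()` returns a tibble of records;
#' `write_fastq()` writes one. Sequence/quality length mismatches and
#' truncated records are format errors.
#'
#' @param path FASTQ file, optionally `.gz`.
#' @param records A data frame with columns `id`, `sequence`, `quality`.
#' @return `read_fastq()`: a tibble with columns `id`, `sequence`,
#'   `quality`; `write_fastq()`: `path`, invisibly.
#' @export
read_fastq <- function(path) {
  tryCatch({
    # Biostrings warns about dropped metadata columns on plain FASTQ input;
    # there are none worth keeping in 4-line records
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    tibble::tibble(
      id = unname(names(x)),
      sequence = unname(as.character(x)),
      quality = unname(as.character(Biostrings::quality(x)))
    )
  }, error = function(e) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    n_lines <- length(readLines(con, warn = FALSE))
    close(con)
    hint <- if (n_lines %% 4 != 0) {
      paste0(" (truncated at record ", n_lines %/% 4 + 1, ")")
    } else ""
    stop("malformed FASTQ '", path, "'", hint, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality))) {
    w <- which(nchar(records$sequence) != nchar(records$quality))[1]
    stop("record ", w, " ('", records$id[w],
         "'): sequence and quality lengths differ", call. = FALSE)
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(records$sequence, records$id)),
    Biostrings::PhredQuality(records$quality)
  )
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}
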