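#' Quality-filter amplicon reads
#'
#' Applies the read-level filter used before taxonomic profiling: the
#' maximal run of low-quality bases (Phred score below `qual_floor`) at the
#' 3' end of each read is trimmed off, and only reads that are at least
#' `min_len` bases long after trimming are retained. Defaults implement the
#' common Q20 / 200 bp rule for 2x300 bp amplicon data. The operation is
#' idempotent: filtering an already-filtered file changes nothing, because
#' after trimming the terminal base is at or above the floor.
#'
#' Properties of the read set that are often reported alongside (total
#' high-quality reads, fraction of bases at or above Q30) are returned in
#' the report but never enforced.
#'
#' @param input Path to a FASTQ file (Sanger/Phred+33 qualities).
#' @param output Path for the filtered FASTQ; `NULL` skips writing.
#' @param qual_floor Phred score below which trailing bases are trimmed.
#' @param min_len Minimum retained read length after trimming.
#' @return A one-row tibble: `n_in`, `n_kept`, `n_dropped`, `mean_len_kept`,
#'   `frac_q30_kept` (fraction of retained bases with quality >= 30), and
#'   the `output` path (NA when not written).
#' @export
qc_filter_reads <- function(input, output = NULL, qual_floor = 20L, min_len = 200L) {
  stopifnot(qual_floor > 0, min_len > 0)
  check_fastq_structure(input)
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(input, quality.scoring = "phred"),
    # Biostrings notes that it drops its own internal metadata columns
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  quals <- as(Biostrings::quality(reads), "IntegerList")
  n_in <- length(reads)

  keep_len <- purrr::map_int(quals, function(q) {
    n <- length(q)
    i <- n
    while (i >= 1L && q[i] < qual_floor) i <- i - 1L
    i
  })
  if (n_in == 0L) keep_len <- integer(0)

  trimmed <- Biostrings::subseq(reads, start = 1L, end = pmax(keep_len, 1L))
  # reads trimmed to nothing carry keep_len 0; they can never pass min_len
  kept <- keep_len >= min_len
  out_set <- trimmed[kept]

  qk <- as(Biostrings::quality(out_set), "IntegerList")
  total_bases <- sum(keep_len[kept])
  frac_q30 <- if (total_bases > 0) sum(purrr::map_int(qk, ~ sum(.x >= 30L))) / total_bases else NA_real_

  if (!is.null(output)) {
    Biostrings::writeQualityScaledXStringSet(out_set, output)
  }
  tibble(
    n_in = n_in,
    n_kept = sum(kept),
    n_dropped = n_in - sum(kept),
    mean_len_kept = if (any(kept)) mean(keep_len[kept]) else NA_real_,
    frac_q30_kept = frac_q30,
    output = output %||% NA_character_
  )
}

# light structural scan so a malformed record is reported with its index
check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4", length(lines)))
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    h <- lines[4L * (i - 1L) + 1L]
    s <- lines[4L * (i - 1L) + 2L]
    p <- lines[4L * (i - 1L) + 3L]
    q <- lines[4L * (i - 1L) + 4L]
    if (!startsWith(h, "@") || !startsWith(p, "+") || nchar(s) != nchar(q)) {
      abort(sprintf("malformed FASTQ record at index %d", i))
    }
  }
  invisible(n)
}
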