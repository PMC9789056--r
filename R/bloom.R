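#' Detect short-term blooms
#'
#' A sample is a short-term bloom for a taxon when that taxon's relative
#' abundance in the sample is strictly greater than `fold_threshold` times
#' the taxon's average relative abundance across all of the same
#' individual's samples. The average includes the candidate sample itself
#' and counts zeros, which is the literal reading of the rule and makes
#' detection a deterministic single pass; set `include_self = FALSE` to
#' average over the other samples only (with few samples the two readings
#' can disagree near the threshold). Taxa never observed in an individual
#' (mean zero) cannot bloom. Ties at exactly the threshold are not blooms.
#'
#' Because the rule compares a sample against the same individual's own
#' mean, it is invariant to any per-taxon rescaling that is removed again by
#' closure, and raising the threshold can only remove calls.
#'
#' @param table An `abund_tbl` in relative mode.
#' @param metadata [sample_metadata()] covering every table sample.
#' @param fold_threshold Positive fold-change threshold (default 5).
#' @param include_self Include the candidate sample in the individual mean.
#' @return A tibble of bloom calls: `individual_id`, `sample_id`, `taxon`,
#'   `abundance`, `individual_mean`, `fold`.
#' @export
detect_blooms <- function(table, metadata, fold_threshold = 5, include_self = TRUE) {
  stopifnot(inherits(table, "abund_tbl"), fold_threshold > 0)
  if (abund_mode(table) != "relative") abort("detect_blooms needs a relative-abundance table (see as_relative())")
  check_samples_covered(table, metadata)
  m <- abund_matrix(table)
  ind <- metadata$individual_id[match(colnames(m), metadata$sample_id)]

  calls <- purrr::map(unique(ind), function(p) {
    sub <- m[, ind == p, drop = FALSE]
    n_i <- ncol(sub)
    mu <- rowMeans(sub)
    if (include_self) {
      hits <- which(sub > fold_threshold * mu & mu > 0, arr.ind = TRUE)
      mu_used <- mu[hits[, 1L]]
    } else {
      if (n_i < 2L) return(NULL)
      # leave-one-out mean for each candidate column
      loo <- (rowSums(sub) - sub) / (n_i - 1L)
      hits <- which(sub > fold_threshold * loo & loo > 0, arr.ind = TRUE)
      mu_used <- loo[hits]
    }
    if (nrow(hits) == 0L) return(NULL)
    tibble(
      individual_id = p,
      sample_id = colnames(sub)[hits[, 2L]],
      taxon = rownames(sub)[hits[, 1L]],
      abundance = unname(sub[hits]),
      individual_mean = unname(mu_used),
      fold = unname(sub[hits] / mu_used)
    )
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0L) {
    out <- tibble(individual_id = character(), sample_id = character(),
                  taxon = character(), abundance = double(),
                  individual_mean = double(), fold = double())
  }
  arrange(out, .data$individual_id, .data$sample_id, .data$taxon)
}

#' Summarise bloom calls
#'
#' Counts how many samples contain at least one bloom (a sample counts once
#' however many taxa bloom in it), how many taxa bloom anywhere, and the
#' per-taxon, per-individual call counts suitable for annotating a taxonomy
#' tree.
#'
#' @param calls Output of [detect_blooms()].
#' @param metadata Metadata for the full sample set (defines the
#'   denominator of `fraction_samples_with_bloom`).
#' @param level Taxonomic level the calls were made at.
#' @return A list of class `bloom_summary`: `level`,
#'   `n_samples_with_bloom`, `n_samples_total`,
#'   `fraction_samples_with_bloom`, `n_taxa_blooming`, `per_taxon` (tibble
#'   of counts split by individual).
#' @export
summarize_blooms <- function(calls, metadata, level = "genus") {
  n_total <- nrow(metadata)
  n_bloom <- dplyr::n_distinct(calls$sample_id)
  per_taxon <- calls |>
    count(.data$taxon, .data$individual_id, name = "n_blooms") |>
    arrange(.data$taxon, .data$individual_id)
  structure(list(
    level = level,
    n_samples_with_bloom = n_bloom,
    n_samples_total = n_total,
    fraction_samples_with_bloom = n_bloom / n_total,
    n_taxa_blooming = dplyr::n_distinct(calls$taxon),
    per_taxon = per_taxon
  ), class = "bloom_summary")
}

#' @export
print.bloom_summary <- function(x, ...) {
  cat(sprintf("Short-term blooms at the %s level: %d/%d samples (%.1f%%), %d taxa\n",
              x$level, x$n_samples_with_bloom, x$n_samples_total,
              100 * x$fraction_samples_with_bloom, x$n_taxa_blooming))
  invisible(x)
}

#' @export
glance.bloom_summary <- function(x, ...) {
  tibble(level = x$level,
         n_samples_with_bloom = x$n_samples_with_bloom,
         n_samples_total = x$n_samples_total,
         fraction_samples_with_bloom = x$fraction_samples_with_bloom,
         n_taxa_blooming = x$n_taxa_blooming)
}

#' @export
tidy.bloom_summary <- function(x, ...) x$per_taxon

#' Write bloom calls and per-taxon counts as an annotation table
#'
#' Long-format TSV of per-taxon, per-individual bloom counts, usable as an
#' external annotation file for taxonomy-tree viewers.
#'
#' @param summary A `bloom_summary`.
#' @param path Output TSV path.
#' @export
write_bloom_annotation <- function(summary, path) {
  wide <- tidyr::pivot_wider(summary$per_taxon, names_from = "individual_id",
                             values_from = "n_blooms", values_fill = 0L)
  readr::write_tsv(wide, path)
  invisible(path)
}
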