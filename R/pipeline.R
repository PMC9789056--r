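#' Run the full time-scale analysis
#'
#' Orchestrates every stage on one table + metadata pair: optional read QC,
#' table loading, bloom detection, Bray-Curtis dissimilarities and interval
#' groups, permuted-time-point tests (per individual and pooled),
#' source-attribution retention by interval group, PCoA, and the Mantel
#' factor screen. Every stage's tabular output is written to `out_dir` as
#' TSV and inventoried with an MD5 digest in the run manifest, so two runs
#' with the same inputs and seed are verifiably identical. A stage failure
#' halts the run with a stage-tagged error.
#'
#' Stages that need inputs the run does not have are skipped with a log
#' note: QC without FASTQ files, source attribution when the table holds
#' relative abundances (counts cannot be recovered), the Mantel screen when
#' no covariate columns are present.
#'
#' @param table An `abund_tbl` or a path readable by
#'   [read_abundance_table()].
#' @param metadata A [sample_metadata()] tibble or TSV path.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param fastq Optional character vector of FASTQ paths to QC first.
#' @param level Taxonomic level when `table` is a path.
#' @param quiet Suppress stage log lines.
#' @return An object of class `gd_run` with each stage's result
#'   (`qc`, `blooms`, `bloom_summary`, `dm`, `pairs`, `pair_summary`,
#'   `perm_tests`, `retention`, `pcoa`, `mantel`), the inputs, `config`,
#'   and `manifest` (tibble: stage, file, md5, seconds).
#' @export
run_pipeline <- function(table, metadata, config = analysis_config(),
                         out_dir = tempfile("gutdrift_run_"), fastq = NULL,
                         level = "genus", quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list()
  run <- list(config = config, out_dir = out_dir)

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log_msg("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    attr(res, "gd_elapsed") <- proc.time()[["elapsed"]] - t0
    res
  }
  emit <- function(stage_name, file, writer) {
    path <- file.path(out_dir, file)
    writer(path)
    manifest[[length(manifest) + 1L]] <<-
      tibble(stage = stage_name, file = file,
             md5 = unname(tools::md5sum(path)))
    path
  }

  if (!is.null(fastq)) {
    run$qc <- stage("qc", function() {
      bind_rows(purrr::map(fastq, function(f) {
        out <- file.path(out_dir, paste0("filtered_", basename(f)))
        mutate(qc_filter_reads(f, out, qual_floor = config$qc_qual_floor,
                               min_len = config$qc_min_len),
               input = f, .before = 1L)
      }))
    })
    emit("qc", "qc_report.tsv", function(p) readr::write_tsv(run$qc, p))
  } else {
    log_msg("[qc] skipped (no FASTQ inputs)")
  }

  run$table <- stage("load", function() {
    if (is.character(table)) read_abundance_table(table, level = level) else table
  })
  run$metadata <- if (is.character(metadata)) read_sample_metadata(metadata) else sample_metadata(metadata)
  check_samples_covered(run$table, run$metadata)
  rel <- as_relative(run$table)

  run$blooms <- stage("bloom", function() {
    detect_blooms(rel, run$metadata, fold_threshold = config$bloom_fold_threshold)
  })
  run$bloom_summary <- summarize_blooms(run$blooms, run$metadata, level = abund_level(rel))
  emit("bloom", "blooms.tsv", function(p) readr::write_tsv(run$blooms, p))
  emit("bloom", "bloom_summary.tsv", function(p) readr::write_tsv(glance(run$bloom_summary), p))

  run$dm <- stage("dissimilarity", function() bray_curtis(rel))
  emit("dissimilarity", "distance_matrix.tsv", function(p) write_distance_matrix(run$dm, p))
  run$pairs <- stage("pairs", function() {
    enumerate_pairs(run$dm, run$metadata, group_bounds = config$group_bounds)
  })
  run$pair_summary <- summarize_pairs(run$pairs)
  emit("pairs", "pairs.tsv", function(p) readr::write_tsv(as_tibble(run$pairs), p))
  emit("pairs", "pair_group_summary.tsv", function(p) readr::write_tsv(run$pair_summary, p))

  run$perm_tests <- stage("permtest", function() {
    permute_timepoint_tests(run$dm, run$metadata,
                            group_pair = config$perm_group_pair,
                            reps = config$perm_reps, rng_seed = config$rng_seed,
                            group_bounds = config$group_bounds)
  })
  emit("permtest", "perm_tests.tsv", function(p) readr::write_tsv(run$perm_tests, p))

  if (abund_mode(run$table) == "counts") {
    run$retention <- stage("source", function() {
      st <- config$gibbs
      st$rng_seed <- config$rng_seed
      retained_fraction_by_interval(run$table, run$metadata, settings = st,
                                    group_bounds = config$group_bounds)
    })
    emit("source", "retention_pairs.tsv", function(p) readr::write_tsv(run$retention$pairs, p))
    emit("source", "retention_groups.tsv", function(p) readr::write_tsv(run$retention$groups, p))
  } else {
    log_msg("[source] skipped (table is relative abundance; counts needed)")
  }

  run$pcoa <- stage("pcoa", function() pcoa(run$dm, n_axes = 2L))
  emit("pcoa", "pcoa_coordinates.tsv", function(p) readr::write_tsv(tidy(run$pcoa), p))
  emit("pcoa", "pcoa_eigenvalues.tsv", function(p) {
    readr::write_tsv(tibble(axis = seq_along(run$pcoa$eigenvalues),
                            eigenvalue = run$pcoa$eigenvalues), p)
  })

  covs <- covariate_names(run$metadata)
  if (length(covs)) {
    run$mantel <- stage("mantel", function() {
      mantel_screen(run$dm, run$metadata, reps = config$perm_reps,
                    rng_seed = config$rng_seed)
    })
    emit("mantel", "mantel.tsv", function(p) readr::write_tsv(as_tibble(run$mantel), p))
  } else {
    log_msg("[mantel] skipped (no covariate columns in metadata)")
  }

  emit("config", "config.yaml", function(p) write_analysis_config(config, p))
  run$manifest <- bind_rows(manifest)
  structure(run, class = "gd_run")
}

#' @export
print.gd_run <- function(x, ...) {
  cat("gutdrift pipeline run\n")
  cat(sprintf("  %d samples, %d taxa (%s, %s)\n", length(sample_ids(x$table)),
              nrow(x$table), abund_level(x$table), abund_mode(x$table)))
  print(x$bloom_summary)
  cat(sprintf("  outputs: %s (%d files)\n", x$out_dir, nrow(x$manifest)))
  invisible(x)
}

#' Restrict a cohort to samples at or before a cutoff time point
#'
#' Sensitivity analysis helper: drops every sample collected after the
#' cutoff, given either a time-point label present in the metadata (e.g.
#' `"T28"`) or a month index, then the downstream stages can be rerun on
#' the subset.
#'
#' @param table An `abund_tbl`.
#' @param metadata Matching [sample_metadata()].
#' @param cutoff A `timepoint_label` value or a month index (integer).
#' @return List with the filtered `table` and `metadata`.
#' @export
subset_before_timepoint <- function(table, metadata, cutoff) {
  stopifnot(inherits(table, "abund_tbl"))
  if (is.character(cutoff)) {
    if (!"timepoint_label" %in% names(metadata) ||
        !cutoff %in% metadata$timepoint_label) {
      abort(paste0("cutoff time point not found in metadata: ", cutoff))
    }
    cutoff_month <- max(metadata$month_index[metadata$timepoint_label == cutoff])
  } else {
    cutoff_month <- as.integer(cutoff)
  }
  keep <- metadata$sample_id[metadata$month_index <= cutoff_month]
  keep <- intersect(sample_ids(table), keep)
  if (length(keep) == 0L) abort("cutoff removes every sample")
  m <- abund_matrix(table)[, keep, drop = FALSE]
  list(
    table = matrix_to_abund(m, abund_level(table), abund_mode(table)),
    metadata = metadata[metadata$sample_id %in% keep, ]
  )
}
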