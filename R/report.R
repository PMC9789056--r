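#' Stacked-bar composition plot over time
#'
#' One stacked bar per sample, faceted by individual and ordered by
#' collection month. Taxa whose relative abundance never reaches `floor`
#' in any sample are pooled into an `"Other"` band, mirroring the usual
#' "only taxa with abundance >= 0.1% are shown" display rule.
#'
#' @param table An `abund_tbl` (converted to relative if needed).
#' @param metadata [sample_metadata()].
#' @param floor Display floor on relative abundance (default 0.001).
#' @return A ggplot.
#' @export
plot_composition <- function(table, metadata, floor = 0.001) {
  rel <- as_relative(table)
  m <- abund_matrix(rel)
  shown <- rownames(m)[apply(m, 1L, max) >= floor]
  pooled <- setdiff(rownames(m), shown)
  df <- as_tibble(t(m[shown, , drop = FALSE]))
  df$sample_id <- colnames(m)
  if (length(pooled)) {
    df$Other <- colSums(m[pooled, , drop = FALSE])
  }
  long <- tidyr::pivot_longer(df, -"sample_id", names_to = "taxon",
                              values_to = "abundance")
  long <- left_join(long,
                    select(as_tibble(metadata), "sample_id", "individual_id", "month_index"),
                    by = "sample_id")
  long <- mutate(long,
                 taxon = factor(.data$taxon, levels = c(shown, if (length(pooled)) "Other")),
                 sample_id = stats::reorder(.data$sample_id, .data$month_index))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~individual_id, scales = "free_x") +
    ggplot2::labs(x = "sample (chronological)", y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = if (length(shown) > 25) "none" else "right")
}

#' Render a markdown report of a pipeline run
#'
#' Writes `report.md` plus PNG panels into a directory: community
#' composition over time, dissimilarity by interval group, retained
#' proportion by group, the PCoA scatter, the Mantel factor screen, and the
#' permutation-test table with seeds and permutation counts for audit.
#' Panels whose stage was skipped are replaced by a note rather than
#' failing the report.
#'
#' @param run A `gd_run` from [run_pipeline()].
#' @param dir Output directory (defaults to the run's `out_dir`).
#' @return Path to `report.md`, invisibly.
#' @export
render_report <- function(run, dir = run$out_dir) {
  stopifnot(inherits(run, "gd_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Longitudinal gut microbiota time-scale report", "")
  save_panel <- function(plot, file, width = 8, height = 5) {
    path <- file.path(dir, file)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    file
  }
  panel <- function(title, body) c(sprintf("## %s", title), "", body, "")
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 4)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }

  lines <- c(lines, panel("Run summary", c(
    sprintf("- samples: %d, taxa: %d (%s level, %s mode)",
            length(sample_ids(run$table)), nrow(run$table),
            abund_level(run$table), abund_mode(run$table)),
    sprintf("- individuals: %d", dplyr::n_distinct(run$metadata$individual_id)),
    sprintf("- rng seed: %d; permutations: %d", run$config$rng_seed, run$config$perm_reps)
  )))

  if (!is.null(run$qc)) {
    lines <- c(lines, panel("Read QC", md_table(run$qc)))
  } else {
    lines <- c(lines, panel("Read QC", "Skipped: no FASTQ inputs."))
  }

  f <- save_panel(plot_composition(run$table, run$metadata,
                                   floor = run$config$display_abundance_floor),
                  "panel_composition.png", width = 10)
  lines <- c(lines, panel("Community composition over time", c(
    sprintf("Taxa below %.2g%% everywhere are pooled into \"Other\".",
            100 * run$config$display_abundance_floor),
    "", sprintf("![composition](%s)", f))))

  bs <- run$bloom_summary
  lines <- c(lines, panel("Short-term blooms", c(
    sprintf("%d of %d samples (%.1f%%) contain a bloom (> %g-fold the individual mean), covering %d taxa.",
            bs$n_samples_with_bloom, bs$n_samples_total,
            100 * bs$fraction_samples_with_bloom,
            run$config$bloom_fold_threshold, bs$n_taxa_blooming))))

  f <- save_panel(autoplot(run$pairs), "panel_dissimilarity.png")
  lines <- c(lines, panel("Dissimilarity by sampling interval", c(
    md_table(run$pair_summary), "", sprintf("![dissimilarity](%s)", f))))

  lines <- c(lines, panel("Permuted-time-point tests", md_table(run$perm_tests)))

  if (!is.null(run$retention)) {
    f <- save_panel(autoplot(run$retention), "panel_retention.png")
    lines <- c(lines, panel("Retained community proportion", c(
      md_table(run$retention$groups), "", sprintf("![retention](%s)", f))))
  } else {
    lines <- c(lines, panel("Retained community proportion",
                            "Skipped: counts-mode table required."))
  }

  f <- save_panel(autoplot(run$pcoa, metadata = run$metadata), "panel_pcoa.png")
  lines <- c(lines, panel("Ordination (PCoA)", c(
    sprintf("Axes explain %s of the positive-eigenvalue variation.",
            paste(sprintf("%.1f%%", 100 * run$pcoa$proportion_explained), collapse = " / ")),
    "", sprintf("![pcoa](%s)", f))))

  if (!is.null(run$mantel)) {
    f <- save_panel(autoplot(run$mantel, alpha = run$config$alpha), "panel_mantel.png")
    lines <- c(lines, panel("Factor screen (Mantel)", c(
      md_table(as_tibble(run$mantel)), "", sprintf("![mantel](%s)", f))))
  } else {
    lines <- c(lines, panel("Factor screen (Mantel)", "Skipped: no covariates."))
  }

  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
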