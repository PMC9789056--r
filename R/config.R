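#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one validated
#' object: the bloom fold-change threshold (5), permutation count (1000),
#' significance level (0.05), display floor for composition plots (0.001,
#' i.e. 0.1% relative abundance), read-QC thresholds (Q20, 200 bp),
#' interval-group bounds, Gibbs sampler settings, and the run seed.
#'
#' @param bloom_fold_threshold Fold-change above the individual mean that
#'   defines a short-term bloom.
#' @param perm_reps Permutations for the time-point and Mantel tests.
#' @param alpha Significance level used in reports.
#' @param display_abundance_floor Taxa never reaching this relative
#'   abundance are pooled into "Other" in composition plots.
#' @param qc_min_len,qc_qual_floor Read-QC thresholds, see
#'   [qc_filter_reads()].
#' @param group_bounds See [default_group_bounds()].
#' @param gibbs A [gibbs_settings()] object.
#' @param perm_group_pair Interval groups contrasted by the permutation
#'   test (shorter, longer).
#' @param rng_seed Master seed for the run.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(bloom_fold_threshold = 5,
                            perm_reps = 1000L,
                            alpha = 0.05,
                            display_abundance_floor = 0.001,
                            qc_min_len = 200L,
                            qc_qual_floor = 20L,
                            group_bounds = default_group_bounds(),
                            gibbs = gibbs_settings(),
                            perm_group_pair = c("M1", "Y3"),
                            rng_seed = 1L) {
  cfg <- list(bloom_fold_threshold = bloom_fold_threshold,
              perm_reps = as.integer(perm_reps), alpha = alpha,
              display_abundance_floor = display_abundance_floor,
              qc_min_len = as.integer(qc_min_len),
              qc_qual_floor = as.integer(qc_qual_floor),
              group_bounds = group_bounds, gibbs = gibbs,
              perm_group_pair = perm_group_pair,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$bloom_fold_threshold > 0, cfg$perm_reps > 0,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$display_abundance_floor > 0,
            cfg$qc_min_len > 0, cfg$qc_qual_floor > 0,
            inherits(cfg$gibbs, "gibbs_settings"),
            length(cfg$perm_group_pair) == 2L)
  check_group_bounds(cfg$group_bounds)
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Flat key-value YAML mirroring the arguments of [analysis_config()]
#' (`group_bounds` as a mapping of group name to `[lower, upper]`, `gibbs`
#' as a nested mapping of [gibbs_settings()] arguments). Unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) abort(paste0("unknown config key(s): ", toString(unknown)))
  if (!is.null(raw$gibbs)) {
    g_unknown <- setdiff(names(raw$gibbs), names(formals(gibbs_settings)))
    if (length(g_unknown)) abort(paste0("unknown gibbs key(s): ", toString(g_unknown)))
    raw$gibbs <- do.call(gibbs_settings, raw$gibbs)
  }
  if (!is.null(raw$group_bounds)) {
    raw$group_bounds <- purrr::map(raw$group_bounds, function(b) {
      b <- as.numeric(purrr::map_dbl(b, ~ if (identical(.x, "Inf") || is.infinite(.x)) Inf else as.numeric(.x)))
      b
    })
  }
  do.call(analysis_config, raw)
}

#' @rdname read_analysis_config
#' @param config An `analysis_config` to write.
#' @export
write_analysis_config <- function(config, path) {
  x <- unclass(config)
  x$gibbs <- unclass(x$gibbs)
  x$group_bounds <- purrr::map(x$group_bounds, function(b) {
    purrr::map(as.list(b), ~ if (is.infinite(.x)) "Inf" else .x)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}
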