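#' Gibbs sampler settings for source attribution
#'
#' Hyperparameters and chain controls for the Bayesian source-tracking
#' sampler, following the published defaults of the method: `alpha1`
#' (Dirichlet smoothing of known-source taxon distributions, 0.001),
#' `alpha2` (smoothing of the learned Unknown-source distribution, scaled
#' by sink depth, 0.1), `beta` (Dirichlet prior on the mixing proportions,
#' 10), 100 burn-in sweeps, 10 independent restarts with 1 recorded draw
#' each, thinning `delay` 1. `rarefaction_depth = NULL` rarefies sink and
#' sources to the minimum observed depth capped at 1000 reads, which keeps
#' per-pair runtime bounded; an explicit depth larger than any sample's
#' total is rejected.
#'
#' @param alpha1,alpha2,beta Positive prior masses (see above).
#' @param burn_in Sweeps discarded before recording.
#' @param restarts Independent chains averaged into the estimate.
#' @param draws_per_restart Draws recorded per chain after burn-in.
#' @param delay Sweeps between recorded draws (thinning).
#' @param rarefaction_depth Common depth to subsample to, or `NULL`.
#' @param rng_seed Seed; identical seeds give identical estimates.
#' @return A `gibbs_settings` list.
#' @export
gibbs_settings <- function(alpha1 = 0.001, alpha2 = 0.1, beta = 10,
                           burn_in = 100L, restarts = 10L,
                           draws_per_restart = 1L, delay = 1L,
                           rarefaction_depth = NULL, rng_seed = 1L) {
  s <- list(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
            burn_in = as.integer(burn_in), restarts = as.integer(restarts),
            draws_per_restart = as.integer(draws_per_restart),
            delay = as.integer(delay),
            rarefaction_depth = if (is.null(rarefaction_depth)) NULL else as.integer(rarefaction_depth),
            rng_seed = as.integer(rng_seed))
  stopifnot(s$alpha1 > 0, s$alpha2 > 0, s$beta > 0, s$burn_in >= 1,
            s$restarts >= 1, s$draws_per_restart >= 1, s$delay >= 1)
  structure(s, class = "gibbs_settings")
}

rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  if (total < depth) abort(sprintf("rarefaction depth %d exceeds available %d reads", depth, total))
  if (total == depth) return(as.integer(counts))
  picked <- sample.int(total, depth)
  tabulate(findInterval(picked - 1L, cumsum(counts), left.open = FALSE) + 1L,
           nbins = length(counts))
}

#' Estimate source proportions of a sink community
#'
#' Decomposes a sink sample's community into contributions from known
#' source samples plus an Unknown source, via a collapsed Gibbs sampler
#' over per-read source assignments (the Bayesian source-tracking model;
#' see [gibbs_settings()] for the conditional and priors). Reported
#' proportions are posterior means over all recorded draws across
#' restarts.
#'
#' @param sink Integer vector of sink taxon counts (named by taxon, or in
#'   the same order as the rows of `sources`).
#' @param sources Taxa-by-sources matrix of counts (one column per known
#'   source), or a single counts vector for one source.
#' @param settings A [gibbs_settings()].
#' @param sink_id,source_ids Labels for the output.
#' @return A tibble of class `source_estimate`: one row per source plus
#'   `"Unknown"`, columns `sink_id`, `source_id`, `proportion` (posterior
#'   mean, rows sum to 1), `sd` (posterior SD across draws), `depth` (after
#'   rarefaction), `rng_seed`.
#' @export
gibbs_source_proportions <- function(sink, sources, settings = gibbs_settings(),
                                     sink_id = "sink", source_ids = NULL) {
  stopifnot(inherits(settings, "gibbs_settings"))
  if (is.null(dim(sources))) sources <- matrix(sources, ncol = 1L)
  if (nrow(sources) != length(sink)) abort("sink and sources disagree on taxon count")
  if (sum(sink) == 0) abort("zero-depth sink")
  if (any(colSums(sources) == 0)) abort("zero-depth source")
  if (is.null(source_ids)) {
    source_ids <- colnames(sources) %||% sprintf("source_%d", seq_len(ncol(sources)))
  }

  set.seed(settings$rng_seed)
  depths <- c(sum(sink), colSums(sources))
  depth <- settings$rarefaction_depth %||% min(min(depths), 1000L)
  if (depth > min(depths)) {
    abort(sprintf("rarefaction depth %d exceeds the shallowest sample (%d reads)",
                  depth, min(depths)))
  }
  sink_r <- rarefy_counts(as.integer(sink), depth)
  src_r <- apply(sources, 2L, function(cc) rarefy_counts(as.integer(cc), depth))
  src_r <- matrix(as.integer(src_r), nrow = length(sink_r))

  draws <- purrr::map(seq_len(settings$restarts), function(r) {
    .gibbs_chain(sink_r, t(src_r),
                 settings$alpha1, settings$alpha2, settings$beta,
                 settings$burn_in, settings$draws_per_restart, settings$delay)
  })
  draws <- do.call(rbind, draws)

  out <- tibble(
    sink_id = sink_id,
    source_id = c(source_ids, "Unknown"),
    proportion = colMeans(draws),
    sd = apply(draws, 2L, sd),
    depth = depth,
    rng_seed = settings$rng_seed
  )
  attr(out, "settings") <- settings
  class(out) <- c("source_estimate", class(out))
  out
}

#' Shared community proportion by sampling-interval group
#'
#' For every ordered same-individual sample pair (earlier -> later), the
#' earlier sample is taken as the sole known source and the later sample as
#' the sink; the estimated known-source proportion is the fraction of the
#' later community shared with (retained from) the earlier one. Pairs are
#' binned into the interval groups and per-group means reported. One known
#' source per pair (rather than pooling all earlier samples) keeps each
#' estimate interpretable as "retained across these two time points".
#'
#' Each pair gets its own deterministic seed derived from
#' `settings$rng_seed`, so subsets of pairs reproduce identically.
#'
#' @param table An `abund_tbl` in counts mode.
#' @param metadata [sample_metadata()] covering the table samples.
#' @param settings A [gibbs_settings()].
#' @param group_bounds See [default_group_bounds()].
#' @return A list of class `gd_retention`: `pairs` (tibble: sink, source,
#'   individual, interval_months, group, shared, unknown) and `groups`
#'   (tibble of per-group n / mean / sd of the shared proportion).
#' @export
retained_fraction_by_interval <- function(table, metadata,
                                          settings = gibbs_settings(),
                                          group_bounds = default_group_bounds()) {
  stopifnot(inherits(table, "abund_tbl"))
  if (abund_mode(table) != "counts") abort("source attribution needs a counts-mode table")
  check_samples_covered(table, metadata)
  check_group_bounds(group_bounds)
  m <- abund_matrix(table)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]

  pair_rows <- list()
  for (p in unique(meta$individual_id)) {
    sel <- which(meta$individual_id == p)
    sel <- sel[order(meta$month_index[sel])]
    if (length(sel) < 2L) next
    cmb <- utils::combn(sel, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]   # a earlier, b later
      iv <- meta$month_index[b] - meta$month_index[a]
      g <- assign_interval_group(iv, group_bounds)
      if (iv == 0L || is.na(g)) next
      pair_rows[[length(pair_rows) + 1L]] <-
        tibble(source = meta$sample_id[a], sink = meta$sample_id[b],
               individual_id = p, interval_months = iv, group = g)
    }
  }
  pairs <- bind_rows(pair_rows)
  if (nrow(pairs) == 0L) abort("no same-individual ordered pairs to attribute")

  est <- purrr::map_dbl(seq_len(nrow(pairs)), function(i) {
    src <- pairs$source[i]; snk <- pairs$sink[i]
    st <- settings
    st$rng_seed <- (settings$rng_seed + i) %% .Machine$integer.max
    e <- gibbs_source_proportions(m[, snk], m[, src, drop = FALSE], st,
                                  sink_id = snk, source_ids = src)
    e$proportion[e$source_id == src]
  })
  pairs$shared <- est
  pairs$unknown <- 1 - est

  groups <- pairs |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean_shared = mean(.data$shared),
              sd_shared = sd(.data$shared), .groups = "drop") |>
    arrange(factor(.data$group, levels = names(group_bounds)))
  structure(list(pairs = pairs, groups = groups, settings = settings),
            class = "gd_retention")
}

#' @export
print.gd_retention <- function(x, ...) {
  cat(sprintf("Retained (shared) community proportion, %d ordered pairs:\n",
              nrow(x$pairs)))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' @export
glance.gd_retention <- function(x, ...) {
  tidyr::pivot_wider(select(x$groups, "group", "mean_shared"),
                     names_from = "group", values_from = "mean_shared",
                     names_prefix = "mean_shared_")
}

#' @export
tidy.gd_retention <- function(x, ...) x$pairs

#' @export
autoplot.gd_retention <- function(object, ...) {
  df <- mutate(object$pairs,
               group = factor(.data$group, levels = c("M1", "Y1", "Y2", "Y3")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$shared,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "sampling-interval group",
                  y = "proportion retained from earlier sample") +
    ggplot2::theme_minimal()
}
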