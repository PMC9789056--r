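#' Wilcoxon rank-sum statistic
#'
#' The rank-sum `W` of group `x` over the pooled sample `c(x, y)`, with
#' midranks for ties. This is the raw statistic the permutation procedure
#' permutes; its usual sampling distribution is *not* used anywhere,
#' because pairwise dissimilarities sharing a sample are dependent and the
#' ordinary critical values would be invalid.
#'
#' @param x,y Non-empty numeric vectors (group A and group B).
#' @return The rank-sum of `x`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # ranks 1,2 -> W = 3
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  sum(rank(c(x, y))[seq_along(x)])
}

#' Permuted-time-point test for rising dissimilarity with interval
#'
#' Tests whether pairwise dissimilarities in a longer-interval group are
#' larger than in a shorter-interval group, for one individual or pooled
#' over all. Pairs of samples share samples and are therefore dependent, so
#' instead of the Wilcoxon null distribution the test builds its own: the
#' collection-month labels are permuted uniformly at random among each
#' individual's samples (the dissimilarity matrix itself is held fixed),
#' pairs are re-binned by the permuted intervals, and the rank-sum of the
#' longer-interval group is recomputed. Permutations that leave either
#' group empty are discarded and redrawn, up to `10 * reps` attempts.
#'
#' The reported `p_value` uses the add-one estimator
#' `(1 + #\{W_null >= W_obs\}) / (1 + valid reps)` for the one-sided
#' "longer interval is more dissimilar" alternative (the direction of the
#' scientific claim); `alternative = "two.sided"` doubles the smaller tail.
#' Critical values are the 90th/95th/99th percentiles of the null.
#'
#' @param dm A `dist_mat` (typically from [bray_curtis()]).
#' @param metadata [sample_metadata()] covering the matrix samples.
#' @param individual_id One individual's ID, or `"pooled"` to combine the
#'   pairs of all individuals (months are still permuted within individual).
#' @param group_pair Length-2 character: shorter- then longer-interval
#'   group, e.g. `c("M1", "Y3")`.
#' @param reps Number of permutations (default 1000).
#' @param rng_seed Seed; identical seeds give identical results.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @param group_bounds See [default_group_bounds()].
#' @return An object of class `perm_test` with fields `individual_id`,
#'   `group_pair`, `n_short`, `n_long`, `observed_W`, `null_W`,
#'   `critical_values`, `p_value`, `reps` (valid permutations),
#'   `alternative`, `rng_seed`.
#' @export
permute_timepoint_test <- function(dm, metadata, individual_id = "pooled",
                                   group_pair = c("M1", "Y3"), reps = 1000L,
                                   rng_seed = 1L,
                                   alternative = c("greater", "two.sided"),
                                   group_bounds = default_group_bounds()) {
  stopifnot(inherits(dm, "dist_mat"), length(group_pair) == 2L)
  alternative <- match.arg(alternative)
  check_group_bounds(group_bounds)
  ids <- rownames(dm)
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) abort(paste0("sample(s) missing metadata: ", toString(ids[is.na(idx)])))
  ind <- metadata$individual_id[idx]
  mon <- metadata$month_index[idx]

  keep_ind <- if (identical(individual_id, "pooled")) unique(ind) else individual_id
  if (!all(keep_ind %in% ind)) abort(paste0("unknown individual: ", toString(setdiff(keep_ind, ind))))

  # per-individual pair scaffolding: upper-triangle indices and dissimilarities
  per_ind <- purrr::map(keep_ind, function(p) {
    sel <- which(ind == p)
    if (length(sel) < 2L) return(NULL)
    sub <- dm[sel, sel, drop = FALSE]
    ut <- which(upper.tri(sub), arr.ind = TRUE)
    list(months = mon[sel], i = ut[, 1L], j = ut[, 2L], d = sub[ut])
  })
  per_ind <- per_ind[!purrr::map_lgl(per_ind, is.null)]
  if (!length(per_ind)) abort("no individual with at least 2 samples")

  group_values <- function(month_list) {
    d_short <- list(); d_long <- list()
    for (k in seq_along(per_ind)) {
      s <- per_ind[[k]]
      iv <- abs(month_list[[k]][s$i] - month_list[[k]][s$j])
      g <- assign_interval_group(iv, group_bounds)
      g[iv == 0L] <- NA_character_
      d_short[[k]] <- s$d[!is.na(g) & g == group_pair[1L]]
      d_long[[k]] <- s$d[!is.na(g) & g == group_pair[2L]]
    }
    list(short = unlist(d_short), long = unlist(d_long))
  }

  obs <- group_values(purrr::map(per_ind, "months"))
  if (length(obs$short) == 0L || length(obs$long) == 0L) {
    abort(sprintf("individual '%s' has no pairs in group %s",
                  paste(individual_id, collapse = ","),
                  group_pair[if (length(obs$short) == 0L) 1L else 2L]))
  }
  observed_W <- wilcoxon_rank_sum(obs$long, obs$short)

  set.seed(as.integer(rng_seed))
  null_W <- numeric(0)
  attempts <- 0L
  max_attempts <- 10L * reps
  while (length(null_W) < reps && attempts < max_attempts) {
    attempts <- attempts + 1L
    perm <- group_values(purrr::map(per_ind, ~ sample(.x$months)))
    if (length(perm$short) == 0L || length(perm$long) == 0L) next
    null_W[length(null_W) + 1L] <- wilcoxon_rank_sum(perm$long, perm$short)
  }
  if (length(null_W) < 2L) {
    abort(sprintf(paste0("only %d of %d permutations produced both groups ",
                         "('%s' and '%s'); schedule too sparse for this test"),
                  length(null_W), attempts, group_pair[1L], group_pair[2L]))
  }

  p_greater <- (1 + sum(null_W >= observed_W)) / (1 + length(null_W))
  p_less <- (1 + sum(null_W <= observed_W)) / (1 + length(null_W))
  p_value <- switch(alternative,
                    greater = p_greater,
                    two.sided = min(1, 2 * min(p_greater, p_less)))

  structure(list(
    individual_id = if (identical(individual_id, "pooled")) "pooled" else individual_id,
    group_pair = group_pair,
    n_short = length(obs$short), n_long = length(obs$long),
    observed_W = observed_W,
    null_W = null_W,
    critical_values = quantile(null_W, c(0.90, 0.95, 0.99)),
    p_value = p_value,
    reps = length(null_W),
    alternative = alternative,
    rng_seed = as.integer(rng_seed)
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permuted-time-point Wilcoxon test (%s): %s vs %s\n",
              x$individual_id, x$group_pair[1L], x$group_pair[2L]))
  cat(sprintf("  W = %.1f (n = %d vs %d), p = %.4g (%s, %d permutations)\n",
              x$observed_W, x$n_short, x$n_long, x$p_value, x$alternative, x$reps))
  cat(sprintf("  null critical values: 90%% %.1f, 95%% %.1f, 99%% %.1f\n",
              x$critical_values[[1L]], x$critical_values[[2L]], x$critical_values[[3L]]))
  invisible(x)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble(individual_id = x$individual_id,
         group_short = x$group_pair[1L], group_long = x$group_pair[2L],
         n_short = x$n_short, n_long = x$n_long,
         observed_W = x$observed_W,
         crit_90 = x$critical_values[[1L]], crit_95 = x$critical_values[[2L]],
         crit_99 = x$critical_values[[3L]],
         p_value = x$p_value, reps = x$reps,
         alternative = x$alternative, rng_seed = x$rng_seed)
}

#' @export
tidy.perm_test <- function(x, ...) tibble(null_W = x$null_W)

#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(W = object$null_W), ggplot2::aes(x = .data$W)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_W, colour = "red") +
    ggplot2::labs(title = sprintf("%s: %s vs %s, p = %.3g", object$individual_id,
                                  object$group_pair[1L], object$group_pair[2L],
                                  object$p_value),
                  x = "rank-sum W under permuted time points", y = "count") +
    ggplot2::theme_minimal()
}

#' Run the permutation test per individual and pooled
#'
#' @inheritParams permute_timepoint_test
#' @return A tibble with one [glance.perm_test()] row per individual that
#'   has pairs in both groups, plus a pooled row. Individuals whose
#'   schedule cannot form both groups are skipped with a warning.
#' @export
permute_timepoint_tests <- function(dm, metadata, group_pair = c("M1", "Y3"),
                                    reps = 1000L, rng_seed = 1L,
                                    group_bounds = default_group_bounds()) {
  inds <- unique(metadata$individual_id[metadata$sample_id %in% rownames(dm)])
  runs <- purrr::map(c(as.list(inds), list("pooled")), function(p) {
    tryCatch(
      glance(permute_timepoint_test(dm, metadata, individual_id = p,
                                    group_pair = group_pair, reps = reps,
                                    rng_seed = rng_seed, group_bounds = group_bounds)),
      error = function(e) {
        warn(sprintf("skipping '%s': %s", paste(p, collapse = ","), conditionMessage(e)))
        NULL
      })
  })
  bind_rows(runs)
}
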