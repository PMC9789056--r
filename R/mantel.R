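#' Mantel test of a per-sample factor against community dissimilarity
#'
#' Correlates the community distance matrix with a factor distance matrix
#' built from per-sample values: absolute difference for numeric factors,
#' 0/1 mismatch for categorical ones. `r` is the Pearson correlation of the
#' two vectorised upper triangles (Spearman available via `method`), and
#' significance comes from permuting the rows/columns of the factor matrix
#' jointly, the standard Mantel permutation scheme for distance matrices
#' (entries of a distance matrix cannot be permuted independently).
#'
#' A constant factor gives zero-variance distances; the result is then
#' flagged `undefined` with `r = NA` rather than dividing by zero.
#'
#' @param dm A `dist_mat` of community dissimilarities.
#' @param factor_values Per-sample factor values, in `rownames(dm)` order
#'   or named by sample ID.
#' @param factor_kind `"auto"` (numeric vectors -> numeric), `"numeric"` or
#'   `"categorical"`.
#' @param reps Number of permutations (default 1000).
#' @param rng_seed Seed.
#' @param method Correlation flavour for `r`.
#' @param factor_name Label carried into the result.
#' @return An object of class `mantel_result`: `factor_name`, `r`,
#'   `p_value` (one-sided, positive association), `reps`, `undefined`,
#'   `null_r`, `rng_seed`.
#' @export
mantel_test <- function(dm, factor_values,
                        factor_kind = c("auto", "numeric", "categorical"),
                        reps = 1000L, rng_seed = 1L,
                        method = c("pearson", "spearman"),
                        factor_name = "factor") {
  stopifnot(inherits(dm, "dist_mat"))
  factor_kind <- match.arg(factor_kind)
  method <- match.arg(method)
  n <- nrow(dm)
  if (!is.null(names(factor_values))) {
    miss <- setdiff(rownames(dm), names(factor_values))
    if (length(miss)) abort(paste0("factor missing for sample(s): ", toString(miss)))
    factor_values <- factor_values[rownames(dm)]
  }
  if (length(factor_values) != n) abort("factor_values must cover every sample")
  if (anyNA(factor_values)) abort(paste0(factor_name, ": missing factor values; drop those samples first"))
  if (factor_kind == "auto") {
    factor_kind <- if (is.numeric(factor_values)) "numeric" else "categorical"
  }
  fd <- if (factor_kind == "numeric") {
    abs(outer(as.numeric(factor_values), as.numeric(factor_values), "-"))
  } else {
    outer(factor_values, factor_values, "!=") * 1
  }

  ut <- upper.tri(dm)
  a <- dm[ut]
  result <- function(r, p, null_r, undefined = FALSE) {
    structure(list(factor_name = factor_name, r = r, p_value = p, reps = length(null_r),
                   undefined = undefined, null_r = null_r,
                   method = method, factor_kind = factor_kind,
                   rng_seed = as.integer(rng_seed)),
              class = "mantel_result")
  }
  if (sd(fd[ut]) == 0 || sd(a) == 0) {
    return(result(NA_real_, NA_real_, numeric(0), undefined = TRUE))
  }
  corr <- function(b) cor(a, b, method = method)
  r_obs <- corr(fd[ut])
  set.seed(as.integer(rng_seed))
  null_r <- purrr::map_dbl(seq_len(reps), function(k) {
    p <- sample.int(n)
    corr(fd[p, p][ut])
  })
  p_value <- (1 + sum(null_r >= r_obs)) / (1 + reps)
  result(r_obs, p_value, null_r)
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Mantel test (%s): undefined (constant factor)\n", x$factor_name))
  } else {
    cat(sprintf("Mantel test (%s, %s): r = %.3f, p = %.4g (%d permutations)\n",
                x$factor_name, x$method, x$r, x$p_value, x$reps))
  }
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(factor_name = x$factor_name, factor_kind = x$factor_kind,
         r = x$r, p_value = x$p_value, reps = x$reps,
         undefined = x$undefined, method = x$method, rng_seed = x$rng_seed)
}

#' @export
tidy.mantel_result <- function(x, ...) tibble(null_r = x$null_r)

#' Screen the survey factors with Mantel tests
#'
#' Runs [mantel_test()] for each requested metadata column against the
#' community distance matrix; the Mantel `r` is reported as the factor's
#' influence score. Participant identity is treated as categorical and the
#' collection date as numeric (month index); other columns follow their
#' storage type.
#'
#' @param dm A `dist_mat`.
#' @param metadata [sample_metadata()] with covariate columns filled.
#' @param factors Character vector of metadata columns to screen; defaults
#'   to participant identity, date, and every covariate column present.
#' @param reps,rng_seed,method Passed to [mantel_test()].
#' @return A tibble of class `mantel_screen`, one [glance.mantel_result()]
#'   row per factor, sorted by `r` descending.
#' @export
mantel_screen <- function(dm, metadata, factors = NULL, reps = 1000L,
                          rng_seed = 1L, method = "pearson") {
  meta <- metadata[match(rownames(dm), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort(paste0("sample(s) missing metadata: ",
                 toString(setdiff(rownames(dm), metadata$sample_id))))
  }
  if (is.null(factors)) {
    covs <- covariate_names(meta)
    id_col <- if ("participant_id" %in% covs) NULL else "individual_id"
    factors <- unique(c(id_col, "month_index", covs))
  }
  miss <- setdiff(factors, names(meta))
  if (length(miss)) abort(paste0("unknown factor column(s): ", toString(miss)))
  rows <- purrr::imap(setNames(factors, factors), function(f, nm) {
    vals <- meta[[f]]
    kind <- if (f %in% c("individual_id", "participant_id")) "categorical"
            else if (f %in% c("month_index", "date")) "numeric" else "auto"
    if (f == "date") vals <- meta$month_index
    glance(mantel_test(dm, vals, factor_kind = kind, reps = reps,
                       rng_seed = rng_seed, method = method, factor_name = nm))
  })
  out <- arrange(bind_rows(rows), dplyr::desc(.data$r))
  class(out) <- c("mantel_screen", class(out))
  out
}

#' @export
autoplot.mantel_screen <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(object),
               factor_name = stats::reorder(.data$factor_name, .data$r),
               significant = !is.na(.data$p_value) & .data$p_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$factor_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               name = sprintf("p < %.2g", alpha)) +
    ggplot2::labs(x = "Mantel r (influence score)", y = NULL) +
    ggplot2::theme_minimal()
}
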