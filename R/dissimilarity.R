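#' Pairwise distance matrices
#'
#' A `dist_mat` is a square symmetric numeric matrix of pairwise
#' dissimilarities with sample IDs as dimnames, a zero diagonal, and (for
#' Bray-Curtis) entries in `[0, 1]`.
#'
#' @param m A square numeric matrix with matching row/column names.
#' @return A validated `dist_mat`.
#' @export
distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) || !identical(rownames(m), colnames(m))) {
    abort("distance matrix needs identical row and column sample IDs")
  }
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix is not symmetric (tolerance 1e-12)")
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) abort("distance matrix diagonal must be exactly zero")
  structure(m, class = c("dist_mat", "matrix", "array"))
}

#' @export
print.dist_mat <- function(x, ...) {
  cat(sprintf("<dist_mat> %d samples\n", nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` over taxa. 0 means
#' identical composition, 1 disjoint taxon support. Requires a
#' relative-abundance table; convert counts first with [as_relative()] so
#' the choice of normalisation is explicit.
#'
#' @param table An `abund_tbl` in relative mode.
#' @return A `dist_mat` over the table's samples.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abund_tbl"))
  if (abund_mode(table) != "relative") {
    abort("bray_curtis needs a relative-abundance table; call as_relative() first")
  }
  if (length(sample_ids(table)) < 2L) abort("need at least 2 samples")
  m <- abund_matrix(table)
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  distance_matrix(d)
}

#' Read/write a distance matrix as square TSV
#'
#' @param x A `dist_mat`.
#' @param path File path.
#' @export
write_distance_matrix <- function(x, path) {
  df <- cbind(data.frame(sample_id = rownames(x)), as.data.frame(unclass(x)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  distance_matrix(m)
}

#' Interval group bounds
#'
#' Same-individual sample pairs are binned by the calendar-month interval
#' between collections: `M1` for pairs one month apart (two consecutive
#' months), `Y1` for 2-12 months, `Y2` for 13-24 months, `Y3` for more than
#' 24 months. Pairs from different individuals are labelled `D`.
#'
#' @return Named list of `c(lower, upper)` inclusive interval bounds.
#' @export
default_group_bounds <- function() {
  list(M1 = c(1, 1), Y1 = c(2, 12), Y2 = c(13, 24), Y3 = c(25, Inf))
}

check_group_bounds <- function(bounds) {
  b <- do.call(rbind, bounds)
  if (any(b[, 1L] > b[, 2L])) abort("group bounds must have lower <= upper")
  if (any(b[, 1L] <= 0)) abort("group bounds must be positive")
  o <- order(b[, 1L])
  if (any(b[o, 1L][-1L] <= b[o, 2L][-nrow(b)])) abort("group bounds overlap")
  invisible(bounds)
}

assign_interval_group <- function(interval, bounds = default_group_bounds()) {
  out <- rep(NA_character_, length(interval))
  for (g in names(bounds)) {
    out[interval >= bounds[[g]][1L] & interval <= bounds[[g]][2L]] <- g
  }
  out
}

#' Enumerate pairwise comparisons with interval groups
#'
#' Every unordered sample pair becomes one row. Same-individual pairs get
#' their calendar-month interval and group (`M1`/`Y1`/`Y2`/`Y3`);
#' different-individual pairs are labelled `D`. Same-individual pairs with
#' interval 0 (duplicate months) are excluded -- the short-interval group is
#' defined as two *consecutive* months, not repeats.
#'
#' @param dm A `dist_mat`.
#' @param metadata [sample_metadata()] covering every sample in `dm`.
#' @param group_bounds See [default_group_bounds()].
#' @return A tibble of class `gd_pairs`: `sample_a`, `sample_b`,
#'   `individual_a`, `individual_b`, `interval_months`, `group`,
#'   `dissimilarity`.
#' @export
enumerate_pairs <- function(dm, metadata, group_bounds = default_group_bounds()) {
  stopifnot(inherits(dm, "dist_mat"))
  check_group_bounds(group_bounds)
  ids <- rownames(dm)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing)) abort(paste0("sample(s) missing metadata: ", toString(missing)))
  idx <- match(ids, metadata$sample_id)
  ind <- metadata$individual_id[idx]
  mon <- metadata$month_index[idx]

  ut <- which(upper.tri(dm), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  out <- tibble(
    sample_a = ids[i], sample_b = ids[j],
    individual_a = ind[i], individual_b = ind[j],
    interval_months = abs(mon[i] - mon[j]),
    dissimilarity = dm[ut]
  )
  same <- out$individual_a == out$individual_b
  out$group <- ifelse(same, assign_interval_group(out$interval_months, group_bounds), "D")
  # drop same-individual duplicate-month pairs and (under custom bounds)
  # intervals falling in a gap between groups
  out <- out[!(same & (out$interval_months == 0L | is.na(out$group))), ]
  out <- select(out, "sample_a", "sample_b", "individual_a", "individual_b",
                "interval_months", "group", "dissimilarity")
  class(out) <- c("gd_pairs", class(out))
  out
}

#' Mean dissimilarity per interval group
#'
#' @param pairs A `gd_pairs` tibble from [enumerate_pairs()].
#' @return A tibble with one row per group: n pairs, mean/sd/median
#'   dissimilarity.
#' @export
summarize_pairs <- function(pairs) {
  pairs |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              mean_dissimilarity = mean(.data$dissimilarity),
              sd_dissimilarity = sd(.data$dissimilarity),
              median_dissimilarity = stats::median(.data$dissimilarity),
              .groups = "drop") |>
    arrange(factor(.data$group, levels = c("M1", "Y1", "Y2", "Y3", "D")))
}

#' Boxplot of dissimilarity by interval group
#'
#' @param object A `gd_pairs` tibble.
#' @param ... Unused.
#' @return A ggplot: Bray-Curtis dissimilarity by group, same-individual
#'   groups ordered by interval, different-individual pairs last.
#' @export
autoplot.gd_pairs <- function(object, ...) {
  df <- mutate(as_tibble(object),
               group = factor(.data$group, levels = c("M1", "Y1", "Y2", "Y3", "D")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$dissimilarity,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "sampling-interval group", y = "Bray-Curtis dissimilarity") +
    ggplot2::theme_minimal()
}
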