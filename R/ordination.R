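#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Embeds samples from a distance matrix: the squared distances are double
#' centered (`G = -1/2 * J D^2 J`), `G` is eigendecomposed, and coordinates
#' are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, so Euclidean distances between coordinates reproduce the
#' input distances when the input is Euclidean-embeddable. Bray-Curtis
#' matrices are generally not, so negative eigenvalues can appear; they are
#' dropped (no Cailliez/Lingoes correction) and their total magnitude
#' reported. The proportion of variation explained by an axis is its
#' eigenvalue over the sum of positive eigenvalues.
#'
#' Each axis's sign is fixed by forcing its largest-magnitude loading
#' positive, so output is reproducible (eigenvectors are otherwise defined
#' only up to sign).
#'
#' @param dm A `dist_mat`.
#' @param n_axes Number of axes to retain; truncated (with a flag) if it
#'   exceeds the number of positive eigenvalues.
#' @return An object of class `gd_pcoa`: `sample_ids`, `coordinates`
#'   (samples x axes matrix), `eigenvalues` (all, descending),
#'   `proportion_explained` (retained axes), `negative_magnitude` (sum of
#'   |negative eigenvalues|), `truncated` flag.
#' @export
pcoa <- function(dm, n_axes = 2L) {
  stopifnot(inherits(dm, "dist_mat"), n_axes >= 1L)
  n <- nrow(dm)
  d2 <- unclass(dm)^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * ctr %*% d2 %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)

  truncated <- FALSE
  k <- n_axes
  if (length(pos) == 0L) {
    coords <- matrix(0, n, n_axes)
    prop <- rep(0, n_axes)
  } else {
    if (k > length(pos)) {
      warn(sprintf("only %d positive eigenvalues; truncating from %d axes", length(pos), k))
      truncated <- TRUE
      k <- length(pos)
    }
    vec <- e$vectors[, pos[seq_len(k)], drop = FALSE]
    val <- e$values[pos[seq_len(k)]]
    # reproducible sign: largest-|loading| entry of each axis made positive
    for (a in seq_len(k)) {
      i <- which.max(abs(vec[, a]))
      if (vec[i, a] < 0) vec[, a] <- -vec[, a]
    }
    coords <- vec %*% diag(sqrt(val), nrow = k)
    prop <- val / sum(e$values[pos])
  }
  rownames(coords) <- rownames(dm)
  colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))

  structure(list(
    sample_ids = rownames(dm),
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = prop,
    negative_magnitude = sum(abs(e$values[e$values < -tol])),
    truncated = truncated
  ), class = "gd_pcoa")
}

#' @export
print.gd_pcoa <- function(x, ...) {
  cat(sprintf("PCoA of %d samples: %d axes retained", length(x$sample_ids),
              ncol(x$coordinates)))
  if (length(x$proportion_explained)) {
    cat(sprintf(" (%s explained)",
                paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", ")))
  }
  cat("\n")
  if (x$negative_magnitude > 0) {
    cat(sprintf("  dropped negative eigenvalues, total magnitude %.3g\n",
                x$negative_magnitude))
  }
  invisible(x)
}

#' @export
tidy.gd_pcoa <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out$sample_id <- x$sample_ids
  select(out, "sample_id", dplyr::everything())
}

#' @export
glance.gd_pcoa <- function(x, ...) {
  tibble(n_samples = length(x$sample_ids),
         n_axes = ncol(x$coordinates),
         prop_axis1 = x$proportion_explained[1] %||% NA_real_,
         prop_axis2 = if (length(x$proportion_explained) >= 2) x$proportion_explained[2] else NA_real_,
         negative_magnitude = x$negative_magnitude,
         truncated = x$truncated)
}

#' Ordination scatter plot coloured by individual
#'
#' @param object A `gd_pcoa`.
#' @param metadata Optional [sample_metadata()]; when given, points are
#'   coloured by `individual_id`.
#' @param ... Unused.
#' @export
autoplot.gd_pcoa <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata)) {
    df <- left_join(df, select(as_tibble(metadata), "sample_id", "individual_id"),
                    by = "sample_id")
  }
  lab <- function(i) {
    p <- object$proportion_explained
    if (length(p) >= i) sprintf("PCo%d (%.1f%%)", i, 100 * p[i]) else sprintf("PCo%d", i)
  }
  aes <- if (!is.null(metadata)) {
    ggplot2::aes(x = .data$PCo1, y = .data$PCo2, colour = .data$individual_id)
  } else {
    ggplot2::aes(x = .data$PCo1, y = .data$PCo2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = "individual") +
    ggplot2::theme_minimal()
}
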