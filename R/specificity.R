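# Cross-cell-type specificity of accessibility regions: variance-stabilize
# the region-by-cell-type counts, z-score each region across cell types, and
# compare z distributions between region subsets. A lineage-specific region
# shows a high z in its lineage and low elsewhere; a shared open region has
# no strongly deviating cell type.

count_columns <- function(m) {
  setdiff(names(m), c("chrom", "start", "end"))
}

#' Variance-stabilizing transform of DHS counts
#'
#' The default is the inverse hyperbolic sine,
#' `asinh(x) = log(x + sqrt(x^2 + 1))`: monotone, maps 0 to 0, and behaves
#' like `log(2x)` for large counts. A strict arcsine-of-square-root-
#' proportion variant (`asin(sqrt(x / column total))`) is available for
#' comparison. An optional per-column counts-per-million scaling can be
#' applied first (off by default).
#'
#' @param m count matrix: numeric matrix, or data frame with chrom/start/end
#'   plus one count column per cell type.
#' @param method `"asinh"` (default) or `"arcsin_prop"`.
#' @param cpm scale each cell-type column to counts per million first.
#' @return object of the same shape with transformed values.
#' @export
transform_counts <- function(m, method = c("asinh", "arcsin_prop"),
                             cpm = FALSE) {
  method <- match.arg(method)
  is_df <- is.data.frame(m)
  x <- if (is_df) as.matrix(m[, count_columns(m), drop = FALSE]) else m
  if (any(x < 0)) stop("counts must be nonnegative")
  if (cpm) x <- sweep(x, 2L, colSums(x) / 1e6, "/")
  t_x <- switch(method,
    asinh = asinh(x),
    arcsin_prop = {
      tot <- colSums(x)
      tot[tot == 0] <- 1
      asin(sqrt(sweep(x, 2L, tot, "/")))
    }
  )
  if (is_df) {
    out <- m
    out[, count_columns(m)] <- t_x
    out
  } else {
    t_x
  }
}

#' Per-region cell-type z-scores
#'
#' For each region, z-scores the transformed signal across cell types
#' (sample SD, n-1 denominator). Regions whose values are identical across
#' all cell types get z = 0 everywhere and a `degenerate` flag, so no
#' regions are dropped.
#'
#' @param tm transformed matrix (output of [transform_counts()]).
#' @param focal_cell cell-type label whose z is reported as `focal_z`.
#' @return data frame with one `z_` column per cell type, `focal_z`, and
#'   `degenerate`.
#' @export
region_zscores <- function(tm, focal_cell) {
  x <- if (is.data.frame(tm)) {
    as.matrix(tm[, count_columns(tm), drop = FALSE])
  } else {
    tm
  }
  if (ncol(x) < 2L) stop("at least 2 cell types required for z-scores")
  if (!focal_cell %in% colnames(x)) {
    stop("focal cell type '", focal_cell, "' not in the matrix")
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  degenerate <- sdv == 0
  sdv[degenerate] <- 1
  z <- (x - mu) / sdv
  z[degenerate, ] <- 0
  out <- as.data.frame(z)
  names(out) <- paste0("z_", colnames(x))
  out$focal_z <- z[, focal_cell]
  out$degenerate <- degenerate
  out
}

#' Compare two z-score distributions
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test (asymptotic p-value) on the
#' supremum distance between the empirical CDFs of two region subsets, e.g.
#' focal z-scores of condition-dependent versus all peaks.
#'
#' @param z_subset_a,z_subset_b numeric vectors of z-scores; non-empty.
#' @return list with `statistic` (D) and `p.value`.
#' @export
compare_zscore_distributions <- function(z_subset_a, z_subset_b) {
  if (length(z_subset_a) == 0L || length(z_subset_b) == 0L) {
    stop("both z-score samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(z_subset_a, z_subset_b,
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Write a z-score table
#'
#' @param z output of [region_zscores()].
#' @param path TSV output path.
#' @export
write_zscore_table <- function(z, path) {
  utils::write.table(z, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
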