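#' Mean-impute isolated missing values within condition
#'
#' Ordination cannot tolerate missing cells; the surviving single missing
#' value per condition (guaranteed by [filter_missingness()]) is replaced by
#' the mean of the observed values of the same protein in the same
#' condition. This imputation is for ordination and heat-map ordering only,
#' never for hypothesis testing.
#'
#' @param qm A [quant_matrix()].
#' @return The `quant_matrix` with no missing cells.
#' @export
impute_condition_mean <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  for (idx in condition_split(qm)) {
    block <- v[, idx, drop = FALSE]
    miss <- which(is.na(block), arr.ind = TRUE)
    if (nrow(miss) > 0L) {
      means <- rowMeans(block, na.rm = TRUE)
      if (any(!is.finite(means[miss[, 1]])))
        stop("a protein has no observed value in a condition; filter first")
      block[miss] <- means[miss[, 1]]
      v[, idx] <- block
    }
  }
  quant_matrix(v, qm$condition, log10 = qm$log10)
}

#' Principal component analysis of the sample profiles
#'
#' Samples are the observations and proteins the variables; proteins are
#' centered and (by default) unit-scaled, i.e. correlation-matrix PCA.
#' Variance-explained percentages are always reported from the unrotated
#' eigenvalues -- an oblique (promax, Kaiser-normalized) rotation can be
#' applied to the loadings for presentation, but rotated components do not
#' partition variance and never change the reported fractions.
#'
#' @param qm A [quant_matrix()] (log10 scale recommended); isolated missing
#'   values are mean-imputed within condition.
#' @param proteins Optional protein subset (e.g. the differential set).
#' @param rotation `"none"` (default) or `"promax"`.
#' @param n_rotate Number of components entering the rotation.
#' @param scale_proteins Unit-scale protein variables (default `TRUE`).
#' @return A `pca_result` list: `scores` (samples x components), `loadings`,
#'   `variance_pct` (non-increasing, sums to 100 over all components),
#'   `condition`, `rotation`, and `rotated_loadings` when rotation was
#'   requested. Also records `dropped` (constant proteins removed before
#'   scaling).
#' @export
run_pca <- function(qm, proteins = NULL, rotation = c("none", "promax"),
                    n_rotate = 2L, scale_proteins = TRUE) {
  rotation <- match.arg(rotation)
  stopifnot(inherits(qm, "quant_matrix"))
  if (ncol(qm$values) < 3L) stop("PCA needs at least 3 samples")
  if (!is.null(proteins)) qm <- subset_quant_matrix(qm, proteins = proteins)
  qm <- impute_condition_mean(qm)
  x <- t(qm$values)                      # samples x proteins
  dropped <- character(0)
  if (scale_proteins) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      dropped <- colnames(x)[sds == 0]
      warning("dropping ", length(dropped),
              " constant protein(s) before scaled PCA")
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale_proteins)
  var_pct <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  out <- list(scores = pr$x, loadings = pr$rotation,
              variance_pct = var_pct, condition = qm$condition,
              rotation = rotation, dropped = dropped)
  if (rotation == "promax") {
    k <- min(n_rotate, ncol(pr$rotation))
    # component loadings scaled by the singular values, Kaiser-normalized
    # varimax inside promax (stats default)
    L <- pr$rotation[, seq_len(k), drop = FALSE] %*%
      diag(pr$sdev[seq_len(k)], k, k)
    pm <- stats::promax(L)
    out$rotated_loadings <- unclass(pm$loadings)
  }
  class(out) <- "pca_result"
  out
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_pct))
  cat("PCA:", nrow(x$scores), "samples;",
      nrow(x$loadings), "proteins\n")
  cat("variance explained (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$variance_pct[seq_len(k)]),
            collapse = ", "), "\n")
  if (!is.null(x$rotated_loadings))
    cat("promax-rotated loadings available (presentation only)\n")
  invisible(x)
}

#' Pearson-correlation hierarchical clustering for heat-map ordering
#'
#' Average-linkage agglomerative clustering with distance
#' `1 - Pearson correlation`, applied to protein rows and to sample columns,
#' yielding the deterministic leaf orders used to draw a clustered heat map.
#'
#' @param qm A [quant_matrix()]; isolated missing values are mean-imputed
#'   within condition.
#' @param proteins Optional protein subset.
#' @return A `cluster_order` list: `row_order` and `col_order` (label
#'   permutations), `row_tree` and `col_tree` (hclust objects), and
#'   `ordered_values` (the matrix rearranged for rendering).
#' @export
pearson_cluster <- function(qm, proteins = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (!is.null(proteins)) qm <- subset_quant_matrix(qm, proteins = proteins)
  qm <- impute_condition_mean(qm)
  v <- qm$values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("clustering needs at least 2 rows and 2 columns")
  row_sd <- apply(v, 1, stats::sd)
  col_sd <- apply(v, 2, stats::sd)
  if (any(row_sd == 0) || any(col_sd == 0))
    stop("constant rows/columns have undefined Pearson correlation")
  row_d <- stats::as.dist(1 - stats::cor(t(v)))
  col_d <- stats::as.dist(1 - stats::cor(v))
  row_tree <- stats::hclust(row_d, method = "average")
  col_tree <- stats::hclust(col_d, method = "average")
  structure(list(
    row_order = rownames(v)[row_tree$order],
    col_order = colnames(v)[col_tree$order],
    row_tree = row_tree, col_tree = col_tree,
    ordered_values = v[row_tree$order, col_tree$order, drop = FALSE]
  ), class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat("Pearson/average-linkage clustering:",
      length(x$row_order), "rows x", length(x$col_order), "columns\n")
  cat("column order:", paste(x$col_order, collapse = " "), "\n")
  invisible(x)
}
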