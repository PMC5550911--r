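#' Protein-by-sample quantitation matrix
#'
#' The central container of the pipeline: a numeric matrix of (normalized)
#' peak areas with proteins as rows and replicate samples as columns, a
#' condition label per sample, a missingness mask (`NA` cells), and a flag
#' recording whether the values are on the log10 scale.
#'
#' @param values Numeric matrix, proteins x samples, with row and column
#'   names. `NA` encodes a missing measurement (e.g. below the noise floor).
#' @param condition Character vector, one label per column of `values`
#'   (conventionally `"control_18C"` / `"elevated_22C"`). Each condition must
#'   contain at least two samples.
#' @param log10 Logical; `TRUE` once [log10_transform()] has been applied.
#'
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `condition` and `log10`.
#' @seealso [generate_intensity_matrix()], [filter_missingness()],
#'   [log10_transform()], [call_de()]
#' @export
quant_matrix <- function(values, condition, log10 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (protein) and column (sample) names")
  if (length(condition) != ncol(values))
    stop("'condition' must have one label per sample column")
  condition <- as.character(condition)
  tab <- table(condition)
  if (length(tab) < 1L || any(tab < 2L))
    stop("each condition needs at least two samples")
  if (isTRUE(log10) && any(!is.finite(values[!is.na(values)])))
    stop("log10 values must be finite for all non-missing cells")
  structure(
    list(values = values, condition = condition, log10 = isTRUE(log10)),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf(
    "quant_matrix: %d proteins x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), if (x$log10) "log10" else "raw"
  ))
  for (cond in unique(x$condition)) {
    cat(sprintf("  %s: %s\n", cond,
                paste(colnames(x$values)[x$condition == cond], collapse = " ")))
  }
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              n_na, 100 * n_na / length(x$values)))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Subset a quant_matrix by protein and/or sample
#'
#' @param qm A [quant_matrix()].
#' @param proteins Row names (or indices) to keep; `NULL` keeps all.
#' @param samples Column names (or indices) to keep; `NULL` keeps all.
#' @return A `quant_matrix` restricted to the requested rows/columns.
#' @export
subset_quant_matrix <- function(qm, proteins = NULL, samples = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  cond <- qm$condition
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, colnames(v)) else samples
    v <- v[, idx, drop = FALSE]
    cond <- cond[idx]
  }
  quant_matrix(v, cond, log10 = qm$log10)
}

#' Write / read a quant_matrix as TSV
#'
#' The matrix is written proteins-as-rows with a `protein` first column and
#' sample IDs as the header; the condition map goes to a two-column sidecar
#' TSV (`sample`, `condition`) at `paste0(path, ".conditions")` unless
#' another path is given.
#'
#' @param qm A [quant_matrix()].
#' @param path Output TSV path.
#' @param conditions_path Sidecar path for the sample-to-condition map.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(qm, path,
                               conditions_path = paste0(path, ".conditions")) {
  stopifnot(inherits(qm, "quant_matrix"))
  df <- data.frame(protein = rownames(qm$values), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(qm$values), condition = qm$condition),
    conditions_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param log10 Scale flag to set on the matrix read back in.
#' @export
read_quant_matrix <- function(path,
                              conditions_path = paste0(path, ".conditions"),
                              log10 = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cm <- utils::read.delim(conditions_path, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  cond <- cm$condition[match(colnames(v), cm$sample)]
  if (anyNA(cond)) stop("condition sidecar does not cover all samples")
  quant_matrix(v, cond, log10 = log10)
}

# Per-condition column indices, in stable condition order.
condition_split <- function(qm) {
  split(seq_along(qm$condition), qm$condition)[unique(qm$condition)]
}
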