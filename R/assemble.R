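#' Roll peptide areas up to proteins
#'
#' Protein area per replicate is the sum of the protein's peptide normalized
#' areas observed in that replicate (the default; `fun = "mean"` averages
#' instead). A protein is missing in a replicate when none of its peptides
#' was quantified there. Peptides mapping to more than one protein
#' (degenerate/shared peptides) are dropped before roll-up; peptides with no
#' protein mapping are an error.
#'
#' @param peptide_table Data frame with columns `peptide`, `protein`,
#'   `replicate`, `normalized_area` (`NA` = not quantified).
#' @param conditions Named character vector mapping replicate ID to
#'   condition label; its order fixes the sample column order.
#' @param fun `"sum"` (default) or `"mean"` roll-up of observed peptides.
#' @return A raw-scale [quant_matrix()]; attribute `partial` is a logical
#'   matrix marking cells quantified from only a subset of the protein's
#'   peptides.
#' @export
rollup_proteins <- function(peptide_table, conditions, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  stopifnot(all(c("peptide", "protein", "replicate", "normalized_area") %in%
                  names(peptide_table)))
  unmapped <- unique(peptide_table$peptide[
    is.na(peptide_table$protein) | peptide_table$protein == ""])
  if (length(unmapped) > 0L)
    stop("peptides with no protein mapping: ",
         paste(unmapped, collapse = ", "))
  shared <- tapply(peptide_table$protein, peptide_table$peptide,
                   function(p) length(unique(p)))
  drop <- names(shared)[shared > 1L]
  if (length(drop) > 0L) {
    message("dropping ", length(drop), " shared peptide(s) from roll-up: ",
            paste(drop, collapse = ", "))
    peptide_table <- peptide_table[!peptide_table$peptide %in% drop, ,
                                   drop = FALSE]
  }

  reps <- names(conditions)
  prots <- sort(unique(peptide_table$protein))
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_
    else if (fun == "sum") sum(v) else mean(v)
  }
  vals <- matrix(NA_real_, length(prots), length(reps),
                 dimnames = list(prots, reps))
  partial <- matrix(FALSE, length(prots), length(reps),
                    dimnames = list(prots, reps))
  for (p in prots) {
    sub <- peptide_table[peptide_table$protein == p, , drop = FALSE]
    for (r in reps) {
      v <- sub$normalized_area[sub$replicate == r]
      vals[p, r] <- agg(v)
      partial[p, r] <- !all(is.na(v)) && anyNA(v)
    }
  }
  qm <- quant_matrix(vals, unname(conditions), log10 = FALSE)
  attr(qm, "partial") <- partial
  qm
}

#' Filter proteins by per-condition missingness
#'
#' Retains exactly the proteins with at most `max_missing_per_condition`
#' missing measurements in each condition; everything else is eliminated
#' from the analysis. The removal log (character vector of dropped protein
#' IDs) is attached as attribute `removed`.
#'
#' @param qm A [quant_matrix()].
#' @param max_missing_per_condition Maximum missing values allowed per
#'   condition (default 1).
#' @return The filtered `quant_matrix` (idempotent under re-application).
#' @export
filter_missingness <- function(qm, max_missing_per_condition = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  cols <- condition_split(qm)
  keep <- rep(TRUE, nrow(qm$values))
  for (idx in cols) {
    nmiss <- rowSums(is.na(qm$values[, idx, drop = FALSE]))
    keep <- keep & nmiss <= max_missing_per_condition
  }
  out <- quant_matrix(qm$values[keep, , drop = FALSE], qm$condition,
                      log10 = qm$log10)
  attr(out, "removed") <- rownames(qm$values)[!keep]
  out
}

#' Log10-transform all intensity measurements
#'
#' Cell-wise log10 to reduce variance between the sample groups; missing
#' stays missing. Non-missing values must be positive (guaranteed upstream
#' by the noise floor).
#'
#' @param qm A raw-scale [quant_matrix()].
#' @return The `quant_matrix` on the log10 scale.
#' @export
log10_transform <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$log10) stop("matrix is already log10 transformed")
  obs <- qm$values[!is.na(qm$values)]
  if (any(obs <= 0))
    stop("log10 transform requires all non-missing values > 0")
  quant_matrix(log10(qm$values), qm$condition, log10 = TRUE)
}
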