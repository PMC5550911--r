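#' Read a flat annotation map from a two-column TSV
#'
#' Expects columns `protein_id` and `term` (header optional when exactly two
#' columns), one row per protein-term pair -- the layout of GAF-derived flat
#' exports. Terms are flat labels: no ontology-graph propagation is applied,
#' so pre-propagate the file if true-path closure is wanted.
#'
#' @param path TSV path.
#' @return Named list mapping protein ID to a character vector of terms.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation TSV needs two columns (protein, term)")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Over/under-representation of annotation categories in the DE set
#'
#' For every category annotated on the reference list, builds the 2x2 table
#' (in/out of the DE set x in/out of the category, over the reference) and
#' scores it with the exact two-sided hypergeometric (Fisher) test -- or a
#' binomial approximation for comparison. Expected count, fold enrichment
#' and direction are reported for every category; Q-values are
#' Benjamini-Hochberg across categories. Proteins absent from the
#' annotation map count as unannotated members of the reference (they are
#' real quantified proteins) unless `drop_unannotated = TRUE`.
#'
#' @param de_list Character vector of differential proteins; must be a
#'   subset of `reference_list`.
#' @param reference_list Character vector of all quantified proteins.
#' @param ann Annotation map: named list protein -> terms (see
#'   [read_annotation_tsv()]).
#' @param alpha Significance level used only to flag `significant` rows
#'   after BH correction.
#' @param method `"fisher"` (exact, default) or `"binomial"`.
#' @param drop_unannotated Remove unannotated proteins from both lists
#'   before testing.
#' @return Data frame, one row per category, with columns `category`,
#'   `n_de_in_cat`, `n_ref_in_cat`, `expected`, `fold_enrichment`,
#'   `direction` (`over` iff observed > expected, else `under`), `p`, `q`,
#'   `significant`; ordered by `p`.
#' @export
overrepresentation <- function(de_list, reference_list, ann,
                               alpha = 0.05,
                               method = c("fisher", "binomial"),
                               drop_unannotated = FALSE) {
  method <- match.arg(method)
  de_list <- unique(as.character(de_list))
  reference_list <- unique(as.character(reference_list))
  if (length(reference_list) == 0L) stop("reference list is empty")
  offenders <- setdiff(de_list, reference_list)
  if (length(offenders) > 0L)
    stop("DE proteins not in the reference list: ",
         paste(offenders, collapse = ", "))
  if (drop_unannotated) {
    annotated <- names(ann)[vapply(ann, length, 1L) > 0L]
    reference_list <- intersect(reference_list, annotated)
    de_list <- intersect(de_list, annotated)
  }
  terms_of <- function(p) if (!is.null(ann[[p]])) ann[[p]] else character(0)
  ref_terms <- lapply(reference_list, terms_of)
  cats <- sort(unique(unlist(ref_terms)))
  if (length(cats) == 0L) stop("no annotated category on the reference list")

  N <- length(reference_list)
  n_de <- length(de_list)
  in_de <- reference_list %in% de_list

  rows <- lapply(cats, function(cat) {
    in_cat <- vapply(ref_terms, function(tt) cat %in% tt, logical(1))
    K <- sum(in_cat)
    k <- sum(in_cat & in_de)
    expected <- n_de * K / N
    p <- if (method == "fisher") {
      stats::fisher.test(matrix(c(k, K - k, n_de - k, N - K - (n_de - k)),
                                nrow = 2))$p.value
    } else {
      stats::binom.test(k, n_de, K / N)$p.value
    }
    data.frame(category = cat, n_de_in_cat = k, n_ref_in_cat = K,
               expected = expected,
               fold_enrichment = if (expected > 0) k / expected else NA_real_,
               direction = if (k > expected) "over" else "under",
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q < alpha
  out[order(out$p, out$category), , drop = FALSE]
}
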