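#' Differential-expression decision configuration
#'
#' @param alpha Per-test significance level for the dual-test rule.
#' @param anchor_q_max Q-value ceiling defining the anchor candidate set for
#'   the derived fold-change cutoff.
#' @param cutoff_db Fixed fold-change cutoff in decibel units
#'   (`10*log10(FC)`); `NULL` (default) derives it from the anchor protein.
#' @param cutoff_fallback_db Cutoff used by [run_pipeline()] when derivation
#'   fails because no protein reaches `anchor_q_max` (default 2.0 dB, i.e.
#'   linear thresholds 1.58 up / 0.63 down).
#' @param fold_change_basis `"arithmetic_means"` (ratio of raw-scale group
#'   means, default) or `"geometric_means"` (back-transformed difference of
#'   log10 group means).
#' @param truncate_cutoff Truncate the derived cutoff to one decimal
#'   (default) or keep it exact.
#' @param welch Use Welch's t instead of the classic equal-variance
#'   Student's t.
#' @param bh_on Which p-value family feeds the Benjamini-Hochberg
#'   adjustment: `"p_t"` (default) or `"p_u"`.
#' @return A `de_config` list.
#' @export
de_config <- function(alpha = 0.05,
                      anchor_q_max = 0.05,
                      cutoff_db = NULL,
                      cutoff_fallback_db = 2.0,
                      fold_change_basis = c("arithmetic_means",
                                            "geometric_means"),
                      truncate_cutoff = TRUE,
                      welch = FALSE,
                      bh_on = c("p_t", "p_u")) {
  stopifnot(alpha > 0, alpha < 1, anchor_q_max > 0, anchor_q_max < 1)
  if (!is.null(cutoff_db) && cutoff_db <= 0) stop("cutoff_db must be > 0")
  structure(list(alpha = alpha, anchor_q_max = anchor_q_max,
                 cutoff_db = cutoff_db,
                 cutoff_fallback_db = cutoff_fallback_db,
                 fold_change_basis = match.arg(fold_change_basis),
                 truncate_cutoff = isTRUE(truncate_cutoff),
                 welch = isTRUE(welch), bh_on = match.arg(bh_on)),
            class = "de_config")
}

#' Dual hypothesis test for one protein
#'
#' Two-sided two-sample Student's t-test (equal variance unless
#' `welch = TRUE`) and two-sided Mann-Whitney U-test on the same
#' observations -- intended to be the log10 intensities. The U-test is exact
#' (full enumeration of labelings) for tie-free groups of size <= 8 each,
#' and uses the normal approximation with continuity and tie correction
#' otherwise. Degenerate inputs: two constant groups with equal values give
#' `p_t = 1`; two constant but unequal groups give `p_t = 0` (perfect
#' separation at zero variance), with a message.
#'
#' @param control,elevated Numeric observations (NAs dropped; >= 2 each).
#' @param welch Use Welch's t-test.
#' @return Named numeric vector `c(p_t = , p_u = )`.
#' @export
test_protein <- function(control, elevated, welch = FALSE) {
  control <- control[!is.na(control)]
  elevated <- elevated[!is.na(elevated)]
  if (length(control) < 2L || length(elevated) < 2L)
    stop("need at least 2 observations per group")
  if (stats::sd(control) == 0 && stats::sd(elevated) == 0) {
    if (control[1] == elevated[1]) {
      p_t <- 1
    } else {
      message("constant unequal groups: t-test p set to 0")
      p_t <- 0
    }
  } else {
    p_t <- stats::t.test(elevated, control, var.equal = !welch)$p.value
  }
  exact <- length(control) <= 8L && length(elevated) <= 8L &&
    !anyDuplicated(c(control, elevated))
  p_u <- suppressWarnings(
    stats::wilcox.test(elevated, control, exact = exact,
                       correct = TRUE)$p.value
  )
  c(p_t = p_t, p_u = p_u)
}

#' Benjamini-Hochberg Q-values
#'
#' Step-up FDR adjustment (sorted ascending, `q_(i) = min_{j>=i} p_(j)*m/j`,
#' capped at 1, returned in input order).
#'
#' @param p Numeric vector of p-values.
#' @return Q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Fold change between conditions, linear and decibel scale
#'
#' @param control,elevated Positive raw-scale observations (NAs dropped).
#' @param basis `"arithmetic_means"`: ratio of raw-scale group means;
#'   `"geometric_means"`: `10^(mean(log10 elevated) - mean(log10 control))`.
#' @return Named numeric vector `c(fold_change = , score_db = )` where
#'   `score_db = 10*log10(fold_change)`.
#' @export
fold_change <- function(control, elevated,
                        basis = c("arithmetic_means", "geometric_means")) {
  basis <- match.arg(basis)
  control <- control[!is.na(control)]
  elevated <- elevated[!is.na(elevated)]
  stopifnot(length(control) >= 1L, length(elevated) >= 1L,
            all(control > 0), all(elevated > 0))
  fc <- if (basis == "arithmetic_means") {
    mean(elevated) / mean(control)
  } else {
    10^(mean(log10(elevated)) - mean(log10(control)))
  }
  c(fold_change = fc, score_db = 10 * log10(fc))
}

#' Linear fold-change thresholds implied by a decibel cutoff
#' @param cutoff_db Cutoff in decibel units.
#' @return `c(up = 10^(cutoff_db/10), down = 10^(-cutoff_db/10))`.
#' @export
linear_cutoffs <- function(cutoff_db) {
  c(up = 10^(cutoff_db / 10), down = 10^(-cutoff_db / 10))
}

#' Derive the fold-change cutoff from the anchor protein
#'
#' The anchor is the protein with the smallest fold-change magnitude
#' (`max(FC, 1/FC)`) among those passing the Q-value criterion
#' (`q < anchor_q_max`); the cutoff is `|10*log10(FC_anchor)|`, truncated to
#' one decimal by default (so an anchor at 1.6-fold gives 2.04 -> 2.0 dB,
#' i.e. linear thresholds 1.58 and 0.63).
#'
#' @param results Data frame with columns `protein`, `fold_change`, `q`.
#' @param anchor_q_max Q-value ceiling for anchor candidates.
#' @param truncate Truncate the cutoff to one decimal.
#' @return List with `cutoff_db`, `anchor` (protein ID), `anchor_fc`.
#' @export
derive_cutoff <- function(results, anchor_q_max = 0.05, truncate = TRUE) {
  stopifnot(all(c("protein", "fold_change", "q") %in% names(results)))
  ok <- !is.na(results$q) & results$q < anchor_q_max &
    is.finite(results$fold_change) & results$fold_change > 0
  if (!any(ok))
    stop("no protein passes q < ", anchor_q_max,
         ": cannot derive a cutoff; supply a fixed cutoff_db instead")
  cand <- results[ok, , drop = FALSE]
  mag <- pmax(cand$fold_change, 1 / cand$fold_change)
  i <- which.min(mag)
  db <- abs(10 * log10(cand$fold_change[i]))
  if (truncate) db <- floor(db * 10) / 10
  list(cutoff_db = db, anchor = cand$protein[i],
       anchor_fc = cand$fold_change[i])
}

#' Call differential expression with the dual-test + fold-change rule
#'
#' For every protein: Student's t and Mann-Whitney U on the available log10
#' observations, Benjamini-Hochberg Q-values over the chosen p-value family,
#' fold change on the raw scale, then the conjunction rule -- a protein is
#' called `up` when both p-values are below `alpha` and its decibel score
#' exceeds the cutoff, `down` symmetrically below the negative cutoff, and
#' `ns` otherwise. The cutoff is either fixed (`cfg$cutoff_db`) or derived
#' from the anchor protein via [derive_cutoff()].
#'
#' @param qm A log10-scale [quant_matrix()] (apply [filter_missingness()]
#'   and [log10_transform()] first).
#' @param cfg A [de_config()].
#' @return A data frame (one row per protein) with columns `protein`,
#'   `n_control`, `n_elevated`, `mean_control`, `mean_elevated` (raw-scale
#'   means), `fold_change`, `score_db`, `p_t`, `p_u`, `q`, `call`;
#'   attributes `cutoff_db`, `thresholds` (linear), `anchor`,
#'   `fold_change_basis`.
#' @export
call_de <- function(qm, cfg = de_config()) {
  stopifnot(inherits(qm, "quant_matrix"), inherits(cfg, "de_config"))
  if (!qm$log10)
    stop("call_de expects a log10-transformed matrix; use log10_transform()")
  cols <- condition_split(qm)
  if (length(cols) != 2L) stop("exactly two conditions are required")
  ctrl_idx <- cols[[grep("control", names(cols))[1]]]
  elev_idx <- setdiff(seq_along(qm$condition), ctrl_idx)

  n <- nrow(qm$values)
  res <- data.frame(
    protein = rownames(qm$values),
    n_control = integer(n), n_elevated = integer(n),
    mean_control = numeric(n), mean_elevated = numeric(n),
    fold_change = numeric(n), score_db = numeric(n),
    p_t = numeric(n), p_u = numeric(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    lc <- qm$values[i, ctrl_idx]
    le <- qm$values[i, elev_idx]
    lc <- lc[!is.na(lc)]
    le <- le[!is.na(le)]
    res$n_control[i] <- length(lc)
    res$n_elevated[i] <- length(le)
    rc <- 10^lc
    re <- 10^le
    res$mean_control[i] <- mean(rc)
    res$mean_elevated[i] <- mean(re)
    fc <- fold_change(rc, re, basis = cfg$fold_change_basis)
    res$fold_change[i] <- fc[["fold_change"]]
    res$score_db[i] <- fc[["score_db"]]
    pv <- test_protein(lc, le, welch = cfg$welch)
    res$p_t[i] <- pv[["p_t"]]
    res$p_u[i] <- pv[["p_u"]]
  }
  res$q <- bh_qvalues(if (cfg$bh_on == "p_t") res$p_t else res$p_u)

  if (is.null(cfg$cutoff_db)) {
    dc <- derive_cutoff(res, cfg$anchor_q_max, truncate = cfg$truncate_cutoff)
    cutoff_db <- dc$cutoff_db
    anchor <- dc$anchor
  } else {
    cutoff_db <- cfg$cutoff_db
    anchor <- NA_character_
  }

  sig <- res$p_t < cfg$alpha & res$p_u < cfg$alpha
  res$call <- ifelse(sig & res$score_db > cutoff_db, "up",
                     ifelse(sig & res$score_db < -cutoff_db, "down", "ns"))
  attr(res, "cutoff_db") <- cutoff_db
  attr(res, "thresholds") <- linear_cutoffs(cutoff_db)
  attr(res, "anchor") <- anchor
  attr(res, "fold_change_basis") <- cfg$fold_change_basis
  res
}
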