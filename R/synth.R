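#' Configuration of the synthetic acclimation-study generator
#'
#' Describes the simulated study: two temperature conditions with
#' `n_replicates` ovary samples each, `n_proteins` quantified proteins of
#' which a small fraction are truly up- or down-regulated, multiplicative
#' log-normal measurement noise, completely-at-random (or optionally
#' low-abundance-biased) missingness, a minimum reportable area, and one
#' exogenously spiked reference peptide that is constant across conditions.
#'
#' Defaults emulate the study design the pipeline targets: 5 replicates per
#' condition, 1532 proteins with 31 up- and 31 down-regulated, true log10
#' fold changes drawn uniformly from 0.2--2.2 (1.6-fold up to 160-fold),
#' within-condition CV of 25%, and a noise floor of 1000 counts.
#'
#' @param n_proteins Number of (non-spike) proteins.
#' @param peptides_per_protein Peptides per protein (used by the
#'   chromatogram-level generator and roll-up demonstrations).
#' @param n_replicates Replicates per condition (>= 2).
#' @param frac_up,frac_down Fractions of proteins truly up-/down-regulated;
#'   `frac_up + frac_down <= 1`.
#' @param log10_fc_up,log10_fc_down Effect size on the log10 scale: a single
#'   value for a fixed effect, or a length-2 range sampled uniformly.
#'   `log10_fc_up` must be positive, `log10_fc_down` negative.
#' @param cv Within-condition coefficient of variation of raw intensities
#'   (>= 0; 0 gives a noise-free generator).
#' @param missing_rate Marginal probability that a measurement is absent.
#' @param missing_mode `"mcar"` (default) or `"intensity"`
#'   (low-abundance-biased: missingness probability decreases with signal).
#' @param noise_floor Minimum reportable area; simulated areas below it are
#'   recorded as missing.
#' @param spike_label Identifier of the constant spiked peptide row.
#' @param base_log10_range Range of log10 baseline protein intensities.
#' @param seed RNG seed recorded in the output and used for all draws.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 1532L,
                         peptides_per_protein = 3L,
                         n_replicates = 5L,
                         frac_up = 31 / 1532,
                         frac_down = 31 / 1532,
                         log10_fc_up = c(0.2, 2.2),
                         log10_fc_down = c(-2.2, -0.2),
                         cv = 0.25,
                         missing_rate = 0.05,
                         missing_mode = c("mcar", "intensity"),
                         noise_floor = 1000,
                         spike_label = "DRVYHPF",
                         base_log10_range = c(4, 6.5),
                         seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (n_replicates < 2L) stop("configuration error: n_replicates must be >= 2")
  if (frac_up < 0 || frac_up > 1 || frac_down < 0 || frac_down > 1 ||
      frac_up + frac_down > 1)
    stop("configuration error: frac_up/frac_down must lie in [0,1] and sum to <= 1")
  if (cv < 0) stop("configuration error: cv must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    stop("configuration error: missing_rate must lie in [0,1]")
  if (any(log10_fc_up <= 0) || any(log10_fc_down >= 0))
    stop("configuration error: log10_fc_up must be > 0 and log10_fc_down < 0")
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_replicates = as.integer(n_replicates),
    frac_up = frac_up, frac_down = frac_down,
    log10_fc_up = log10_fc_up, log10_fc_down = log10_fc_down,
    cv = cv, missing_rate = missing_rate, missing_mode = missing_mode,
    noise_floor = noise_floor, spike_label = spike_label,
    base_log10_range = base_log10_range, seed = as.integer(seed)
  ), class = "synth_config")
}

sample_effect <- function(n, range) {
  if (n == 0L) return(numeric(0))
  if (length(range) == 1L) rep(range, n)
  else stats::runif(n, min(range), max(range))
}

#' Simulate a protein-by-sample intensity matrix with ground truth
#'
#' Draws, for each protein, a baseline intensity (log-uniform over
#' `base_log10_range`), multiplies the elevated-condition columns by
#' `10^log10_fc` for the truly regulated proteins, and applies multiplicative
#' log-normal noise with the configured coefficient of variation (the noise
#' factor has mean 1, so raw-scale group means are unbiased). Missingness is
#' then applied cell-wise -- never to the spike row -- and any simulated area
#' below the noise floor is also recorded as missing, mirroring the
#' minimum-reportable-area rule of the quantitation stage.
#'
#' Sample IDs follow the `R18_A..` / `R22_A..` replicate naming convention;
#' conditions are labelled `control_18C` and `elevated_22C`.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{a [quant_matrix()] of raw intensities, `n_proteins + 1`
#'       rows (the extra row is the spiked peptide, complete and with zero
#'       condition effect);}
#'     \item{truth}{a data frame with per-protein `class`
#'       (`up`/`down`/`null`), `log10_fc` (0 for null proteins) and
#'       `base_intensity`.}
#'   }
#' @export
generate_intensity_matrix <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  r <- cfg$n_replicates

  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  cls <- rep("null", n)
  ord <- sample.int(n)
  if (n_up > 0L) cls[ord[seq_len(n_up)]] <- "up"
  if (n_down > 0L) cls[ord[n_up + seq_len(n_down)]] <- "down"
  lfc <- numeric(n)
  lfc[cls == "up"] <- sample_effect(n_up, cfg$log10_fc_up)
  lfc[cls == "down"] <- sample_effect(n_down, cfg$log10_fc_down)

  proteins <- sprintf("P%04d", seq_len(n))
  rep_letters <- make.unique(rep(LETTERS, length.out = r), sep = "")
  samples <- c(paste0("R18_", rep_letters), paste0("R22_", rep_letters))
  condition <- rep(c("control_18C", "elevated_22C"), each = r)

  base <- 10^stats::runif(n, cfg$base_log10_range[1], cfg$base_log10_range[2])
  spike_base <- 10^mean(cfg$base_log10_range)
  mu <- cbind(matrix(base, n, r), matrix(base * 10^lfc, n, r))
  mu <- rbind(mu, rep(spike_base, 2 * r))

  if (cfg$cv > 0) {
    sdlog <- sqrt(log(1 + cfg$cv^2))
    noise <- matrix(stats::rlnorm((n + 1L) * 2L * r, -sdlog^2 / 2, sdlog),
                    n + 1L, 2L * r)
  } else {
    noise <- 1
  }
  vals <- mu * noise
  dimnames(vals) <- list(c(proteins, cfg$spike_label), samples)

  if (cfg$missing_rate > 0) {
    p <- matrix(cfg$missing_rate, n, 2L * r)
    if (cfg$missing_mode == "intensity") {
      # low-abundance-biased: linear in (1 - rank), mean kept at missing_rate
      u <- (rank(vals[seq_len(n), ]) - 0.5) / (n * 2L * r)
      p <- pmin(1, matrix(2 * cfg$missing_rate * (1 - u), n, 2L * r))
    }
    drop <- matrix(stats::runif(n * 2L * r) < p, n, 2L * r)
    vals[seq_len(n), ][drop] <- NA_real_
  }
  vals[seq_len(n), ][vals[seq_len(n), ] < cfg$noise_floor] <- NA_real_

  truth <- data.frame(protein = proteins, class = cls, log10_fc = lfc,
                      base_intensity = base, stringsAsFactors = FALSE)
  qm <- quant_matrix(vals, condition, log10 = FALSE)
  attr(qm, "seed") <- cfg$seed
  attr(qm, "spike_label") <- cfg$spike_label
  list(matrix = qm, truth = truth)
}

#' Simulate replicate chromatogram traces with known peak areas
#'
#' Builds, for each replicate, an RT/intensity trace that is a sum of
#' Gaussian peaks plus (optionally) white noise, with a per-replicate
#' monotone RT shift so that alignment can be exercised. The closed-form
#' true area of each peak, `height * sigma * sqrt(2*pi)`, is returned
#' alongside. Negative intensities that truncated noise would produce are
#' clipped at zero (traces are nonnegative by construction).
#'
#' @param cfg A [synth_config()] (supplies `n_replicates` and `seed`).
#' @param peak_spec Data frame with columns `rt_apex`, `width_sigma`,
#'   `height` (one row per peak; may have zero rows for a flat trace).
#' @param rt_range Length-2 retention-time range in seconds.
#' @param dt Sampling interval in seconds.
#' @param noise_sd Standard deviation of additive white noise.
#' @param rt_shift Per-replicate additive RT shift in seconds; default a
#'   small monotone drift across replicates. Recycled/validated to
#'   `n_replicates`.
#' @param peptide Peptide identifier stamped on the traces.
#' @return A list with `chromatograms` (list of [chromatogram()], one per
#'   replicate), `true_areas` (numeric, one per peak), and `rt_shift`.
#' @export
generate_chromatogram_set <- function(cfg = synth_config(),
                                      peak_spec,
                                      rt_range = c(0, 600),
                                      dt = 0.5,
                                      noise_sd = 0,
                                      rt_shift = NULL,
                                      peptide = "PEPTIDE") {
  stopifnot(inherits(cfg, "synth_config"))
  peak_spec <- as.data.frame(peak_spec)
  if (nrow(peak_spec) > 0) {
    stopifnot(all(c("rt_apex", "width_sigma", "height") %in% names(peak_spec)))
    if (any(peak_spec$height < 0)) stop("peak heights must be nonnegative")
    if (any(peak_spec$width_sigma <= 0)) stop("peak widths must be positive")
    if (any(peak_spec$rt_apex < rt_range[1] | peak_spec$rt_apex > rt_range[2]))
      stop("peak apexes must lie within rt_range")
  }
  r <- cfg$n_replicates
  if (is.null(rt_shift)) {
    rt_shift <- if (r == 1L) 0 else seq(-2, 2, length.out = r)
  }
  if (length(rt_shift) != r) stop("rt_shift must have one entry per replicate")

  set.seed(cfg$seed)
  rt <- seq(rt_range[1], rt_range[2], by = dt)
  chroms <- lapply(seq_len(r), function(k) {
    y <- numeric(length(rt))
    for (i in seq_len(nrow(peak_spec))) {
      y <- y + peak_spec$height[i] *
        exp(-(rt - (peak_spec$rt_apex[i] + rt_shift[k]))^2 /
              (2 * peak_spec$width_sigma[i]^2))
    }
    if (noise_sd > 0) y <- pmax(0, y + stats::rnorm(length(rt), 0, noise_sd))
    chromatogram(rt, y, peptide = peptide, replicate = k)
  })
  true_areas <- if (nrow(peak_spec) > 0)
    peak_spec$height * peak_spec$width_sigma * sqrt(2 * pi) else numeric(0)
  list(chromatograms = chroms, true_areas = true_areas, rt_shift = rt_shift)
}

#' Simulate a flat annotation map for overrepresentation testing
#'
#' Assigns each protein zero or more flat category terms. A fraction of
#' proteins stays unannotated (as in real GO mappings of non-model
#' organisms). If ground truth is supplied, two designated categories
#' (`stress_response_like`, `biosynthetic_like`) are preferentially loaded
#' with truly regulated / truly null proteins so that enrichment has signal
#' to find.
#'
#' @param proteins Character vector of protein IDs.
#' @param truth Optional ground-truth data frame from
#'   [generate_intensity_matrix()].
#' @param n_categories Number of generic background categories.
#' @param unannotated_rate Fraction of proteins left without terms.
#' @param seed RNG seed.
#' @return Named list mapping protein ID to a character vector of terms.
#' @export
generate_annotation_map <- function(proteins, truth = NULL,
                                    n_categories = 15L,
                                    unannotated_rate = 0.13,
                                    seed = 1L) {
  set.seed(seed)
  cats <- sprintf("category_%02d", seq_len(n_categories))
  ann <- stats::setNames(vector("list", length(proteins)), proteins)
  annotated <- stats::runif(length(proteins)) >= unannotated_rate
  for (i in which(annotated)) {
    k <- sample(1:3, 1L)
    ann[[i]] <- sample(cats, k)
  }
  if (!is.null(truth)) {
    de <- truth$protein[truth$class != "null"]
    null_p <- truth$protein[truth$class == "null"]
    # stress-like: mostly regulated proteins; biosynthetic-like: mostly null
    pick_de <- de[stats::runif(length(de)) < 0.6]
    for (p in pick_de) ann[[p]] <- union(ann[[p]], "stress_response_like")
    pick_null <- sample(null_p, min(length(null_p), max(10L, length(de))))
    for (p in pick_null) ann[[p]] <- union(ann[[p]], "biosynthetic_like")
  }
  ann[vapply(ann, length, 1L) > 0L]
}
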