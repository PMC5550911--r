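#' Chromatogram trace for one peptide ion in one replicate run
#'
#' @param rt Retention times in seconds, strictly increasing, length >= 2.
#' @param intensity Nonnegative intensities, same length as `rt`.
#' @param peptide,replicate Identifiers stamped on the trace.
#' @return A `chromatogram` object (list with the four fields).
#' @export
chromatogram <- function(rt, intensity, peptide = NA_character_,
                         replicate = NA) {
  if (length(rt) != length(intensity) || length(rt) < 2L)
    stop("rt and intensity must have equal length >= 2")
  if (any(diff(rt) <= 0)) stop("rt must be strictly increasing")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  structure(list(rt = as.numeric(rt), intensity = as.numeric(intensity),
                 peptide = peptide, replicate = replicate),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram %s / replicate %s: %d points, RT %.1f-%.1f s, max %.3g\n",
              x$peptide, as.character(x$replicate), length(x$rt),
              x$rt[1], x$rt[length(x$rt)], max(x$intensity)))
  invisible(x)
}

#' Write / read a chromatogram as two-column whitespace text
#' @param chrom A [chromatogram()].
#' @param path File path.
#' @return `path` (write) or a `chromatogram` (read), invisibly / visibly.
#' @export
write_chromatogram <- function(chrom, path) {
  utils::write.table(cbind(rt = chrom$rt, intensity = chrom$intensity),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @param peptide,replicate Identifiers to stamp on the trace read in.
#' @export
read_chromatogram <- function(path, peptide = NA_character_, replicate = NA) {
  m <- utils::read.table(path, header = FALSE)
  chromatogram(m[[1]], m[[2]], peptide = peptide, replicate = replicate)
}

#' Quantitation parameters
#'
#' Defaults follow the acquisition-matched settings the pipeline was designed
#' for: multi-pass minimum peak widths from 20 s down to 2 s, maximum peak
#' width 80 s, signal-to-noise threshold 10, a fallback integration window of
#' 40 s half-width, minimum reportable peak area (spectral noise level) 1000,
#' and the spiked reference peptide DRVYHPF.
#'
#' @param min_width_schedule Strictly decreasing minimum peak widths in
#'   seconds, one detection pass each (widest first).
#' @param max_width Maximum peak width in seconds.
#' @param snr_threshold Minimum apex signal-to-noise ratio.
#' @param fallback_halfwidth Half-width in seconds of the fallback
#'   integration window.
#' @param noise_floor Minimum reportable peak area.
#' @param spike_label Identifier of the spiked normalization peptide.
#' @return A `quant_params` list.
#' @export
quant_params <- function(min_width_schedule = c(20, 10, 5, 2),
                         max_width = 80,
                         snr_threshold = 10,
                         fallback_halfwidth = 40,
                         noise_floor = 1000,
                         spike_label = "DRVYHPF") {
  if (any(diff(min_width_schedule) >= 0))
    stop("min_width_schedule must be strictly decreasing")
  if (any(min_width_schedule <= 0)) stop("widths must be positive")
  if (max_width < max(min_width_schedule))
    stop("max_width must be >= max(min_width_schedule)")
  structure(list(min_width_schedule = min_width_schedule,
                 max_width = max_width, snr_threshold = snr_threshold,
                 fallback_halfwidth = fallback_halfwidth,
                 noise_floor = noise_floor, spike_label = spike_label),
            class = "quant_params")
}

empty_peak_table <- function() {
  data.frame(rt_start = numeric(0), rt_apex = numeric(0), rt_end = numeric(0),
             area = numeric(0), snr = numeric(0), width = numeric(0),
             method = character(0), pass_index = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract a selected ion chromatogram from a peak-list series
#'
#' For every scan, sums all signals whose m/z lies within a relative ppm
#' window of the target; scans with no matching signal contribute zero.
#'
#' @param spectra Data frame with columns `rt`, `mz`, `intensity` (every
#'   signal of every scan), sorted by `rt`.
#' @param target_mz Target m/z (> 0).
#' @param tol_ppm Half-width of the mass window in parts per million.
#' @param peptide,replicate Identifiers stamped on the trace.
#' @return A [chromatogram()] over the scan retention times.
#' @export
extract_sic <- function(spectra, target_mz, tol_ppm = 10,
                        peptide = NA_character_, replicate = NA) {
  if (is.null(spectra) || nrow(spectra) == 0L)
    stop("empty spectra series")
  stopifnot(all(c("rt", "mz", "intensity") %in% names(spectra)),
            target_mz > 0, tol_ppm > 0)
  scans <- sort(unique(spectra$rt))
  match_ok <- abs(spectra$mz - target_mz) / target_mz <= tol_ppm * 1e-6
  y <- numeric(length(scans))
  if (any(match_ok)) {
    sums <- tapply(spectra$intensity[match_ok], spectra$rt[match_ok], sum)
    idx <- match(as.numeric(names(sums)), scans)
    y[idx] <- as.numeric(sums)
  }
  chromatogram(scans, y, peptide = peptide, replicate = replicate)
}

# Ricker (Mexican hat) response of the trace at one wavelet scale sigma,
# L2-normalized kernel, zero-padded convolution.
ricker_response <- function(y, dt, sigma) {
  half <- max(3L, ceiling(4 * sigma / dt))
  tt <- seq(-half, half) * dt
  kern <- (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
  kern <- kern / sqrt(sum(kern^2))
  yy <- c(rep(0, half), y, rep(0, half))
  f <- stats::filter(yy, kern, sides = 2)
  as.numeric(f[(half + 1L):(half + length(y))])
}

# Half-height (FWHM) width of the peak at `apex`, linearly interpolated.
half_height_width <- function(rt, y, apex) {
  h <- y[apex] / 2
  l <- apex
  while (l > 1L && y[l] > h) l <- l - 1L
  left <- if (y[l] > h) rt[l] else
    rt[l] + (rt[l + 1L] - rt[l]) * (h - y[l]) / (y[l + 1L] - y[l])
  r <- apex
  n <- length(y)
  while (r < n && y[r] > h) r <- r + 1L
  right <- if (y[r] > h) rt[r] else
    rt[r] - (rt[r] - rt[r - 1L]) * (h - y[r]) / (y[r - 1L] - y[r])
  right - left
}

# Peak limits by descent on the raw trace: walk outward from the apex while
# the signal keeps strictly decreasing, stopping when it stops decreasing or
# reaches baseline (a small fraction of the apex height; the area beyond is
# negligible and stopping there keeps well-separated peaks disjoint).
descent_bounds <- function(y, apex, baseline_frac = 1e-3) {
  base <- baseline_frac * y[apex]
  l <- apex
  while (l > 1L && y[l - 1L] < y[l] && y[l - 1L] > base) l <- l - 1L
  r <- apex
  n <- length(y)
  while (r < n && y[r + 1L] < y[r] && y[r + 1L] > base) r <- r + 1L
  c(l, r)
}

#' Detect chromatographic peaks via continuous wavelet transform
#'
#' Computes the Ricker-wavelet response of the trace over a log-spaced grid
#' of scales spanning the requested width range, takes candidate apexes at
#' local maxima of the best-scale response, snaps each to the raw-trace
#' local maximum, and accepts a candidate when (i) its half-height width
#' lies within `[min_width, max_width]` and (ii) its apex signal-to-noise
#' ratio -- apex intensity over the MAD-based noise level of the trace
#' outside candidate peak regions -- reaches `snr_threshold`. Peak limits
#' are then found by descent on the non-transformed data and the area is the
#' trapezoidal integral between them. Returned peaks are pairwise disjoint
#' (strongest apex wins).
#'
#' @param chrom A [chromatogram()].
#' @param min_width,max_width Accepted half-height peak-width range, seconds.
#' @param snr_threshold Minimum apex signal-to-noise ratio.
#' @param n_scales Number of wavelet scales in the grid.
#' @return A data frame of peak calls with columns `rt_start`, `rt_apex`,
#'   `rt_end`, `area`, `snr`, `width`, `method` (`"cwt"`), `pass_index`.
#' @export
detect_peaks_cwt <- function(chrom, min_width, max_width,
                             snr_threshold = 10, n_scales = 10L) {
  stopifnot(inherits(chrom, "chromatogram"),
            min_width > 0, min_width < max_width)
  rt <- chrom$rt
  y <- chrom$intensity
  n <- length(y)
  if (all(y == 0)) return(empty_peak_table())
  if (rt[n] - rt[1] < min_width) return(empty_peak_table())
  dt <- stats::median(diff(rt))

  fwhm_k <- 2 * sqrt(2 * log(2))
  scales <- exp(seq(log(min_width / fwhm_k), log(max_width / fwhm_k),
                    length.out = n_scales))
  resp <- vapply(scales, function(s) ricker_response(y, dt, s), numeric(n))
  best <- max.col(resp, ties.method = "first")
  cmax <- resp[cbind(seq_len(n), best)]

  # local maxima of the best-scale response with positive coefficient
  d <- diff(sign(diff(cmax)))
  cand <- which(d < 0) + 1L
  cand <- cand[cmax[cand] > 0]
  if (length(cand) == 0L) return(empty_peak_table())

  # snap to raw-trace local maximum within the candidate's scale window
  apexes <- unique(vapply(cand, function(i) {
    w <- max(1L, ceiling(scales[best[i]] / dt))
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    as.integer(lo + which.max(y[lo:hi]) - 1L)
  }, integer(1)))
  apexes <- apexes[y[apexes] > 0]
  if (length(apexes) == 0L) return(empty_peak_table())

  widths <- vapply(apexes, function(a) half_height_width(rt, y, a), numeric(1))
  keep <- widths >= min_width & widths <= max_width
  apexes <- apexes[keep]
  widths <- widths[keep]
  if (length(apexes) == 0L) return(empty_peak_table())

  bounds <- t(vapply(apexes, function(a) descent_bounds(y, a), integer(2)))

  # noise: MAD (sigma-scaled) of the trace outside candidate peak regions
  inpeak <- logical(n)
  for (i in seq_along(apexes)) inpeak[bounds[i, 1]:bounds[i, 2]] <- TRUE
  out <- y[!inpeak]
  noise <- if (length(out) >= 10L) stats::mad(out) else 0
  snr <- if (noise > 0) y[apexes] / noise else rep(Inf, length(apexes))

  keep <- snr >= snr_threshold
  apexes <- apexes[keep]; widths <- widths[keep]
  bounds <- bounds[keep, , drop = FALSE]; snr <- snr[keep]
  if (length(apexes) == 0L) return(empty_peak_table())

  # enforce pairwise-disjoint intervals, strongest apex first
  ord <- order(y[apexes], decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    overlap <- any(vapply(sel, function(j) {
      bounds[i, 1] <= bounds[j, 2] && bounds[j, 1] <= bounds[i, 2]
    }, logical(1)))
    if (!overlap) sel <- c(sel, i)
  }
  sel <- sel[order(apexes[sel])]

  data.frame(
    rt_start = rt[bounds[sel, 1]],
    rt_apex = rt[apexes[sel]],
    rt_end = rt[bounds[sel, 2]],
    area = vapply(sel, function(i) {
      idx <- bounds[i, 1]:bounds[i, 2]
      pracma::trapz(rt[idx], y[idx])
    }, numeric(1)),
    snr = snr[sel],
    width = widths[sel],
    method = "cwt",
    pass_index = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Multi-pass wavelet peak detection over narrowing width ranges
#'
#' Runs [detect_peaks_cwt()] once per entry of the minimum-width schedule,
#' widest minimum first. A peak found in a later (narrower) pass is kept
#' only if its apex falls outside the retention-time bounds of every peak
#' already accepted by an earlier pass, so earlier passes win on overlap.
#'
#' @param chrom A [chromatogram()].
#' @param params A [quant_params()].
#' @return Peak-call data frame (see [detect_peaks_cwt()]) with
#'   `pass_index` recording the producing pass, ordered by apex RT.
#' @export
multipass_detect <- function(chrom, params = quant_params()) {
  stopifnot(inherits(params, "quant_params"))
  acc <- empty_peak_table()
  for (i in seq_along(params$min_width_schedule)) {
    p <- detect_peaks_cwt(chrom, params$min_width_schedule[i],
                          params$max_width, params$snr_threshold)
    if (nrow(p) == 0L) next
    p$pass_index <- i
    if (nrow(acc) > 0L) {
      new <- vapply(p$rt_apex, function(a) {
        !any(a >= acc$rt_start & a <= acc$rt_end)
      }, logical(1))
      p <- p[new, , drop = FALSE]
    }
    acc <- rbind(acc, p)
  }
  acc[order(acc$rt_apex), , drop = FALSE]
}

#' Integrate a fixed window around the most intense signal
#'
#' Fallback quantitation for traces where wavelet detection finds no peak:
#' trapezoidal integration over `center +/- halfwidth`, clipped to the
#' trace. The default center is the maximum-intensity signal (middle sample
#' of a plateau of equal maxima).
#'
#' @param chrom A [chromatogram()].
#' @param halfwidth Window half-width in seconds.
#' @param center Window center in seconds; default the trace maximum.
#' @return A one-row peak-call data frame, `method = "fallback"`; an
#'   all-zero trace yields area 0.
#' @export
fallback_integrate <- function(chrom, halfwidth, center = NULL) {
  stopifnot(inherits(chrom, "chromatogram"), halfwidth > 0)
  rt <- chrom$rt
  y <- chrom$intensity
  if (is.null(center)) {
    at_max <- which(y == max(y))
    center <- rt[at_max[ceiling(length(at_max) / 2)]]
  }
  sel <- which(rt >= center - halfwidth & rt <= center + halfwidth)
  if (length(sel) < 2L) {
    return(data.frame(rt_start = center, rt_apex = center, rt_end = center,
                      area = 0, snr = 0, width = 0, method = "fallback",
                      pass_index = NA_integer_, stringsAsFactors = FALSE))
  }
  apex <- sel[which.max(y[sel])]
  area <- pracma::trapz(rt[sel], y[sel])
  out <- y[-sel]
  noise <- if (length(out) >= 10L) stats::mad(out) else 0
  snr <- if (noise > 0) y[apex] / noise else if (y[apex] > 0) Inf else 0
  data.frame(rt_start = rt[sel[1]], rt_apex = rt[apex],
             rt_end = rt[sel[length(sel)]], area = area, snr = snr,
             width = rt[sel[length(sel)]] - rt[sel[1]],
             method = "fallback", pass_index = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Retention-time warp from anchor landmarks
#'
#' Aligns replicate runs on shared anchor peptides: the reference RT of each
#' anchor is the median apex RT across runs, and each run's warp is the
#' monotone piecewise-linear map through its (native, reference) anchor
#' pairs, extrapolating linearly with the end-segment slopes.
#'
#' @param anchor_rts Numeric matrix of native apex RTs, runs x anchors
#'   (>= 2 runs, >= 2 anchors).
#' @return A list of `rt_warp` objects, one per run (named by rownames).
#' @export
align_runs <- function(anchor_rts) {
  anchor_rts <- as.matrix(anchor_rts)
  if (nrow(anchor_rts) < 2L) stop("need at least 2 runs to align")
  if (ncol(anchor_rts) < 2L)
    stop("need at least 2 shared anchors per run to fit a warp")
  reference <- apply(anchor_rts, 2, stats::median)
  warps <- lapply(seq_len(nrow(anchor_rts)), function(k) {
    rt_warp(anchor_rts[k, ], reference)
  })
  names(warps) <- rownames(anchor_rts)
  warps
}

#' @rdname align_runs
#' @param native,reference Paired anchor RTs (native run scale and shared
#'   reference scale); both must be strictly monotone after sorting by
#'   `native`, otherwise the warp is rejected.
#' @export
rt_warp <- function(native, reference) {
  stopifnot(length(native) == length(reference), length(native) >= 2L)
  o <- order(native)
  native <- native[o]
  reference <- reference[o]
  if (any(diff(native) <= 0) || any(diff(reference) <= 0))
    stop("non-monotone anchor pairs: cannot fit a strictly increasing warp")
  structure(list(native = native, reference = reference), class = "rt_warp")
}

piecewise_linear <- function(x, xs, ys) {
  n <- length(xs)
  out <- stats::approx(xs, ys, xout = x, rule = 2)$y
  lo <- x < xs[1]
  hi <- x > xs[n]
  if (any(lo)) {
    s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[lo] <- ys[1] + s * (x[lo] - xs[1])
  }
  if (any(hi)) {
    s <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out[hi] <- ys[n] + s * (x[hi] - xs[n])
  }
  out
}

#' Apply (or invert) a retention-time warp
#' @param warp An `rt_warp`.
#' @param t Retention times, native scale for `warp_apply` (returns
#'   reference scale) and reference scale for `warp_invert` (returns native).
#' @return Warped retention times.
#' @export
warp_apply <- function(warp, t) {
  stopifnot(inherits(warp, "rt_warp"))
  piecewise_linear(t, warp$native, warp$reference)
}

#' @rdname warp_apply
#' @export
warp_invert <- function(warp, t) {
  stopifnot(inherits(warp, "rt_warp"))
  piecewise_linear(t, warp$reference, warp$native)
}

#' Quantify a peptide with no MS/MS identification in a run
#'
#' When a peptide was identified in other replicates but not fragmented in
#' this run, its SIC is integrated at the retention time predicted by the
#' alignment: the expected reference RT is mapped back through the run's
#' warp and a fallback window is integrated there.
#'
#' @param chrom The run's SIC for the peptide.
#' @param warp The run's [rt_warp()].
#' @param expected_rt Expected apex RT on the reference scale.
#' @param params A [quant_params()] (supplies the window half-width).
#' @return A one-row peak-call data frame, `method = "rt_fill"`; an expected
#'   RT falling outside the trace yields area 0 with a warning.
#' @export
fill_missing <- function(chrom, warp, expected_rt, params = quant_params()) {
  stopifnot(inherits(chrom, "chromatogram"))
  native_rt <- warp_invert(warp, expected_rt)
  n <- length(chrom$rt)
  if (native_rt < chrom$rt[1] || native_rt > chrom$rt[n]) {
    warning(sprintf(
      "expected RT %.1f s (native %.1f s) outside trace for %s replicate %s; area set to 0",
      expected_rt, native_rt, chrom$peptide, as.character(chrom$replicate)))
    pc <- data.frame(rt_start = native_rt, rt_apex = native_rt,
                     rt_end = native_rt, area = 0, snr = 0, width = 0,
                     method = "rt_fill", pass_index = NA_integer_,
                     stringsAsFactors = FALSE)
    return(pc)
  }
  pc <- fallback_integrate(chrom, params$fallback_halfwidth, center = native_rt)
  pc$method <- "rt_fill"
  pc
}

#' Apply the minimum reportable peak area
#'
#' Areas below the spectral noise floor are marked missing (`NA`) -- not
#' zero and not clamped -- so that they feed the downstream missingness
#' filter rather than corrupting the log10 transform.
#'
#' @param calls Data frame with an `area` column.
#' @param floor Minimum reportable area.
#' @return `calls` with sub-floor areas replaced by `NA`.
#' @export
apply_noise_floor <- function(calls, floor = 1000) {
  stopifnot("area" %in% names(calls))
  calls$area[!is.na(calls$area) & calls$area < floor] <- NA_real_
  calls
}

#' Normalize peak areas to the spiked reference peptide
#'
#' Divides every area in a replicate by that replicate's spike area, so the
#' spike's normalized value is 1 everywhere and between-run intensity drift
#' cancels.
#'
#' @param calls Data frame with columns `peptide`, `replicate`, `area`
#'   (`NA` allowed for non-spike peptides).
#' @param spike_label Spike peptide identifier; must be present with a
#'   usable area in every replicate.
#' @return `calls` with an added `normalized_area` column.
#' @export
normalize_spike <- function(calls, spike_label = "DRVYHPF") {
  stopifnot(all(c("peptide", "replicate", "area") %in% names(calls)))
  reps <- unique(calls$replicate)
  spike_area <- stats::setNames(rep(NA_real_, length(reps)),
                                as.character(reps))
  for (r in reps) {
    a <- calls$area[calls$peptide == spike_label & calls$replicate == r]
    a <- a[!is.na(a)]
    if (length(a) == 0L)
      stop(sprintf("spike peptide %s missing or below floor in replicate %s",
                   spike_label, as.character(r)))
    spike_area[as.character(r)] <- a[1]
  }
  calls$normalized_area <- calls$area / spike_area[as.character(calls$replicate)]
  calls
}
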