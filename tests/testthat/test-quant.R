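test_that("SIC extraction honours the ppm window and sums co-eluting signals", {
  spectra <- data.frame(
    rt = c(10, 20, 20, 30, 40),
    mz = c(500.000, 500.001, 500.002, 500.006, 499.990),
    intensity = c(100, 60, 40, 70, 80)
  )
  sic <- extract_sic(spectra, target_mz = 500.000, tol_ppm = 10)
  expect_equal(sic$rt, c(10, 20, 30, 40))
  # 500.006 is 12 ppm away -> excluded; 499.990 is 20 ppm away -> excluded
  expect_equal(sic$intensity, c(100, 60 + 40, 0, 0))
  expect_error(extract_sic(spectra[0, ], 500), "empty")
})

test_that("wavelet detection integrates noiseless Gaussians to the closed-form area", {
  for (s in c(2, 5, 20)) {
    ch <- gaussian_trace(s, 1e4)
    p <- detect_peaks_cwt(ch, min_width = 2, max_width = 80)
    expect_identical(nrow(p), 1L)
    true_area <- 1e4 * s * sqrt(2 * pi)
    expect_lt(abs(p$area - true_area) / true_area, 0.02)
    expect_gt(p$rt_apex, 299)
    expect_lt(p$rt_apex, 301)
    expect_true(p$rt_start < p$rt_apex && p$rt_apex < p$rt_end)
  }
})

test_that("wavelet detection returns nothing for flat traces and sub-threshold peaks", {
  rt <- seq(0, 600, 0.5)
  expect_identical(nrow(detect_peaks_cwt(chromatogram(rt, rep(0, length(rt))),
                                         2, 80)), 0L)
  # peak whose apex S/N (MAD-based) is ~5, under the threshold of 10
  set.seed(1)
  noise <- abs(stats::rnorm(length(rt), 0, 50))
  nlev <- stats::mad(noise)
  y <- pmax(0, 5 * nlev * exp(-(rt - 300)^2 / (2 * 5^2)) + noise)
  expect_identical(nrow(detect_peaks_cwt(chromatogram(rt, y), 2, 80, 10)), 0L)
  # the same peak ten times taller passes
  y2 <- pmax(0, 50 * nlev * exp(-(rt - 300)^2 / (2 * 5^2)) + noise)
  expect_identical(nrow(detect_peaks_cwt(chromatogram(rt, y2), 2, 80, 10)), 1L)
})

test_that("multi-pass detection separates width classes and deduplicates across passes", {
  rt <- seq(0, 600, 0.5)
  # one broad + one narrow, well separated: found in different passes
  y <- 1e4 * exp(-(rt - 150)^2 / (2 * 15^2)) +
    8e3 * exp(-(rt - 450)^2 / (2 * 2^2))
  p <- multipass_detect(chromatogram(rt, y))
  expect_identical(nrow(p), 2L)
  expect_lt(p$pass_index[1], p$pass_index[2])
  expect_lt(abs(p$area[1] - 1e4 * 15 * sqrt(2 * pi)) / (1e4 * 15 * sqrt(2 * pi)),
            0.02)
  expect_lt(abs(p$area[2] - 8e3 * 2 * sqrt(2 * pi)) / (8e3 * 2 * sqrt(2 * pi)),
            0.02)
  # a single mid-width peak is not re-reported by narrower passes
  y6 <- 1e4 * exp(-(rt - 300)^2 / (2 * 6^2))
  p6 <- multipass_detect(chromatogram(rt, y6))
  expect_identical(nrow(p6), 1L)
  # a narrow bump riding inside an accepted broad peak's bounds is suppressed
  yr <- 1e4 * exp(-(rt - 300)^2 / (2 * 15^2)) +
    3e3 * exp(-(rt - 303)^2 / (2 * 1.5^2))
  pr <- multipass_detect(chromatogram(rt, yr))
  expect_identical(nrow(pr), 1L)
  expect_identical(pr$pass_index, 1L)
  # empty trace
  expect_identical(nrow(multipass_detect(chromatogram(rt, rep(0, length(rt))))),
                   0L)
  # intervals pairwise disjoint, areas nonnegative (property on a busy trace)
  yb <- 1e4 * exp(-(rt - 100)^2 / (2 * 4^2)) +
    6e3 * exp(-(rt - 200)^2 / (2 * 10^2)) +
    4e3 * exp(-(rt - 400)^2 / (2 * 18^2))
  pb <- multipass_detect(chromatogram(rt, yb))
  expect_true(all(pb$area >= 0))
  if (nrow(pb) > 1) {
    o <- order(pb$rt_start)
    expect_true(all(pb$rt_start[o][-1] > pb$rt_end[o][-nrow(pb)]))
  }
})

test_that("fallback window integration matches hand integrals and clips at trace edges", {
  rt <- seq(0, 30, 0.5)
  y <- ifelse(rt >= 10 & rt <= 20, 100, 0)
  pc <- fallback_integrate(chromatogram(rt, y), halfwidth = 5)
  expect_equal(pc$area, 1000)            # exact rectangle integral
  expect_identical(pc$method, "fallback")
  # all-zero trace
  z <- fallback_integrate(chromatogram(rt, rep(0, length(rt))), 5)
  expect_equal(z$area, 0)
  # window past trace end: clipped to the available points
  ch <- gaussian_trace(3, 1e3, apex = 595, rt = seq(0, 600, 0.5))
  pc2 <- fallback_integrate(ch, halfwidth = 40)
  sel <- ch$rt >= 595 - 40
  expect_equal(pc2$area, trapz_hand(ch$rt[sel], ch$intensity[sel]))
})

test_that("run alignment recovers shifts and rejects unusable anchors", {
  anchors_ref <- c(100, 250, 400, 550)
  # identical runs -> identity warps
  m <- rbind(run1 = anchors_ref, run2 = anchors_ref, run3 = anchors_ref)
  w <- align_runs(m)
  t <- seq(50, 580, 7)
  expect_lt(max(abs(warp_apply(w[[1]], t) - t)), 1e-9)
  # a uniformly +5 s late run maps back by -5 s
  m2 <- rbind(run1 = anchors_ref, run2 = anchors_ref,
              late = anchors_ref + 5)
  w2 <- align_runs(m2)
  expect_lt(max(abs(warp_apply(w2$late, t) - (t - 5))), 1e-6)
  # inverse really inverts
  expect_lt(max(abs(warp_invert(w2$late, warp_apply(w2$late, t)) - t)), 1e-9)
  # < 2 anchors, or non-monotone pairs, are errors
  expect_error(align_runs(m[, 1, drop = FALSE]), "anchors")
  expect_error(rt_warp(c(1, 2, 3), c(1, 3, 2)), "non-monotone")
  expect_error(align_runs(m[1, , drop = FALSE]), "2 runs")
})

test_that("linear RT drift is absorbed by the piecewise-linear warp", {
  anchors_ref <- seq(60, 540, length.out = 6)
  set.seed(9)
  drifted <- rbind(
    a = anchors_ref,
    b = 0.98 * anchors_ref + 10 + stats::rnorm(6, 0, 0.1),
    c = 1.02 * anchors_ref - 10 + stats::rnorm(6, 0, 0.1)
  )
  w <- align_runs(drifted)
  resid <- unlist(lapply(seq_len(nrow(drifted)), function(k) {
    warp_apply(w[[k]], drifted[k, ]) - apply(drifted, 2, stats::median)
  }))
  expect_lt(stats::median(abs(resid)), 0.5)
})

test_that("RT fill-in quantifies unfragmented peptides at the aligned position", {
  cfg <- synth_config(n_replicates = 3, seed = 21)
  spec <- data.frame(rt_apex = 300, width_sigma = 4, height = 5e3)
  cs <- generate_chromatogram_set(cfg, spec, noise_sd = 0,
                                  rt_shift = c(0, 8, -8))
  # anchors: true apexes of a pair of landmark peptides in each run
  anchors <- rbind(c(100, 300, 500), c(108, 308, 508), c(92, 292, 492))
  warps <- align_runs(anchors)
  true_area <- cs$true_areas[1]
  expected_rt <- 300   # reference-scale apex (median across runs)
  for (k in 1:3) {
    pc <- fill_missing(cs$chromatograms[[k]], warps[[k]], expected_rt)
    expect_identical(pc$method, "rt_fill")
    expect_lt(abs(pc$area - true_area) / true_area, 0.05)
  }
  # expected RT beyond the trace -> area 0 with a warning
  expect_warning(
    pc0 <- fill_missing(cs$chromatograms[[1]], warps[[1]], 9999),
    "outside")
  expect_equal(pc0$area, 0)
  # identity warp: identical to a fallback window centered there
  idw <- rt_warp(c(0, 600), c(0, 600))
  pc1 <- fill_missing(cs$chromatograms[[1]], idw, 300)
  pc2 <- fallback_integrate(cs$chromatograms[[1]], quant_params()$fallback_halfwidth,
                            center = 300)
  expect_equal(pc1$area, pc2$area)
})

test_that("the noise floor marks sub-floor areas missing, not zero", {
  calls <- data.frame(area = c(999, 1000, 0, 5000, NA))
  out <- apply_noise_floor(calls, floor = 1000)
  expect_true(is.na(out$area[1]))
  expect_equal(out$area[2], 1000)
  expect_true(is.na(out$area[3]))
  expect_equal(out$area[4], 5000)
  expect_true(is.na(out$area[5]))
})

test_that("spike normalization cancels run-to-run intensity drift", {
  tab <- data.frame(
    peptide = rep(c("DRVYHPF", "PEP1"), each = 2),
    replicate = rep(c("A", "B"), 2),
    area = c(2000, 4000, 4000, 8000)
  )
  out <- normalize_spike(tab)
  expect_equal(out$normalized_area[out$peptide == "DRVYHPF"], c(1, 1))
  # identical true amounts, 2x drifted run -> identical normalized values
  expect_equal(out$normalized_area[out$peptide == "PEP1"], c(2, 2))
  # scale invariance: multiplying one replicate's areas by c changes nothing
  tab2 <- tab
  tab2$area[tab2$replicate == "B"] <- tab2$area[tab2$replicate == "B"] * 7.3
  out2 <- normalize_spike(tab2)
  expect_equal(out2$normalized_area, out$normalized_area)
  # spike absent in a replicate is an error naming it
  expect_error(normalize_spike(tab[-2, ]), "replicate B")
})
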