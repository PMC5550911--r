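test_that("the exact U-test equals full enumeration of labelings", {
  # complete separation at 5 vs 5: 2 of the 252 labelings are as extreme
  p <- test_protein(1:5, 6:10)
  expect_equal(p[["p_u"]], 2 / 252)
  expect_equal(p[["p_u"]], u_enum_oracle(1:5, 6:10))
  # random tie-free inputs
  set.seed(101)
  for (i in 1:25) {
    ctrl <- stats::rnorm(5)
    elev <- stats::rnorm(5, mean = stats::runif(1, -2, 2))
    expect_equal(test_protein(ctrl, elev)[["p_u"]],
                 u_enum_oracle(ctrl, elev), tolerance = 1e-12)
  }
  # unbalanced groups too (4 vs 5, as left by the missingness filter)
  for (i in 1:10) {
    ctrl <- stats::rnorm(4)
    elev <- stats::rnorm(5, 1)
    expect_equal(test_protein(ctrl, elev)[["p_u"]],
                 u_enum_oracle(ctrl, elev), tolerance = 1e-12)
  }
})

test_that("identical and degenerate groups are handled by convention", {
  p <- test_protein(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p[["p_t"]], 1)
  expect_equal(p[["p_u"]], 1)
  # two constant equal groups
  expect_equal(test_protein(c(2, 2, 2), c(2, 2, 2))[["p_t"]], 1)
  # two constant unequal groups: perfect separation at zero variance
  expect_message(p0 <- test_protein(c(2, 2, 2), c(3, 3, 3)), "constant")
  expect_equal(p0[["p_t"]], 0)
})

test_that("null U-test p-values are valid (sub-uniform) despite discreteness", {
  set.seed(202)
  n_sim <- 4000
  p_u <- replicate(n_sim, {
    test_protein(stats::rnorm(5), stats::rnorm(5))[["p_u"]]
  })
  for (a in c(2 / 252, 8 / 252, 0.05, 0.1, 0.2, 0.5)) {
    emp <- mean(p_u <= a)
    expect_lte(emp, a + 3 * sqrt(a * (1 - a) / n_sim))
  }
  # and not wildly conservative at achievable levels
  expect_gt(mean(p_u <= 8 / 252), 8 / 252 - 3 * sqrt((8 / 252) / n_sim))
})

test_that("BH Q-values match the step-up formula oracle", {
  # equally spaced p on the BH boundary all share the largest value
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(bh_qvalues(0.037), 0.037)
  set.seed(303)
  for (i in 1:30) {
    m <- sample(2:200, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    q <- bh_qvalues(p)
    expect_equal(q, bh_step_up_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("fold change and its decibel score follow the group means", {
  fc <- fold_change(rep(100, 5), rep(200, 5))
  expect_equal(fc[["fold_change"]], 2)
  expect_equal(fc[["score_db"]], 10 * log10(2), tolerance = 1e-9)
  expect_equal(round(fc[["score_db"]], 2), 3.01)
  expect_equal(fold_change(c(5, 10), c(5, 10))[["fold_change"]], 1)
  expect_equal(fold_change(c(5, 10), c(5, 10))[["score_db"]], 0)
  # a 1.6-fold change scores 2.04 dB (the anchor case)
  expect_equal(round(fold_change(rep(100, 5), rep(160, 5))[["score_db"]], 2),
               2.04)
  # geometric basis back-transforms the log-mean difference
  fcg <- fold_change(c(10, 1000), c(100, 100), basis = "geometric_means")
  expect_equal(fcg[["fold_change"]], 1)
  fca <- fold_change(c(10, 1000), c(100, 100))
  expect_equal(fca[["fold_change"]], 100 / 505)
})

test_that("the anchor-derived cutoff truncates to one decimal", {
  res <- data.frame(protein = c("Hsc71", "big", "nsig"),
                    fold_change = c(1.6, 3.2, 1.1),
                    q = c(0.036, 0.001, 0.4))
  dc <- derive_cutoff(res)
  expect_equal(dc$cutoff_db, 2.0)
  expect_identical(dc$anchor, "Hsc71")
  # exact (untruncated) mode
  expect_equal(derive_cutoff(res, truncate = FALSE)$cutoff_db,
               10 * log10(1.6), tolerance = 1e-9)
  # a 2-fold anchor gives 3.0 dB (3.010 truncated)
  res$fold_change[1] <- 2.0
  expect_equal(derive_cutoff(res)$cutoff_db, 3.0)
  # down-regulated anchors count by fold-change magnitude
  res2 <- data.frame(protein = c("dn", "up"), fold_change = c(1 / 1.6, 3),
                     q = c(0.01, 0.02))
  expect_identical(derive_cutoff(res2)$anchor, "dn")
  expect_equal(derive_cutoff(res2)$cutoff_db, 2.0)
  # nothing under the Q ceiling -> instructive error
  expect_error(derive_cutoff(data.frame(protein = "x", fold_change = 2,
                                        q = 0.2)),
               "fixed cutoff_db")
})

test_that("the DE call is the conjunction of both tests and the fold-change cutoff", {
  # noise-free proteins with known fold changes (log10 values):
  rows <- list(
    fc1.5 = c(rep(2, 5), rep(log10(150), 5)),      # 1.76 dB < 2.0 -> ns
    fc4   = c(rep(2, 5), rep(log10(400), 5)),      # 6.02 dB -> up
    fc0.5 = c(rep(3, 5), rep(log10(500), 5)),      # -3.01 dB -> down
    null  = c(2, 2.01, 1.99, 2.02, 1.98, 2.0, 2.01, 1.99, 2.02, 1.98)
  )
  qm <- toy_log_matrix(rows)
  suppressMessages(
    de <- call_de(qm, de_config(cutoff_db = 2.0))
  )
  calls <- stats::setNames(de$call, de$protein)
  expect_identical(unname(calls[c("fc1.5", "fc4", "fc0.5", "null")]),
                   c("ns", "up", "down", "ns"))
  expect_equal(unname(round(attr(de, "thresholds"), 2)), c(1.58, 0.63))
})

test_that("DE calls equal the decision rule recomputed independently per protein", {
  sim <- generate_intensity_matrix(
    synth_config(n_proteins = 200, frac_up = 0.1, frac_down = 0.1,
                 log10_fc_up = 0.6, log10_fc_down = -0.6,
                 cv = 0.35, missing_rate = 0.05, seed = 77))
  lg <- log10_transform(filter_missingness(
    subset_quant_matrix(sim$matrix,
                        proteins = setdiff(rownames(sim$matrix$values),
                                           "DRVYHPF"))))
  cfg <- de_config(cutoff_db = 2.0)
  de <- call_de(lg, cfg)
  # partition property
  expect_true(all(de$call %in% c("up", "down", "ns")))
  expect_identical(sum(de$call == "up") + sum(de$call == "down") +
                     sum(de$call == "ns"), nrow(de))
  # recompute the rule from the reported columns
  expected_call <- with(de, ifelse(
    p_t < 0.05 & p_u < 0.05 & score_db > 2.0, "up",
    ifelse(p_t < 0.05 & p_u < 0.05 & score_db < -2.0, "down", "ns")))
  expect_identical(de$call, expected_call)
  # the conjunction must be doing work: some proteins pass one test only
  expect_gt(sum(de$p_t < 0.05 & de$p_u >= 0.05), 0)
  expect_true(all(de$call[de$p_t < 0.05 & de$p_u >= 0.05] == "ns"))
})

test_that("detection rate is monotone in the true fold change", {
  rate_at <- function(lfc) {
    hits <- 0L; total <- 0L
    for (seed in 1:5) {
      sim <- generate_intensity_matrix(
        synth_config(n_proteins = 150, frac_up = 0.4, frac_down = 0,
                     log10_fc_up = lfc, cv = 0.2, missing_rate = 0,
                     seed = 1000 + seed))
      lg <- log10_transform(subset_quant_matrix(
        sim$matrix,
        proteins = setdiff(rownames(sim$matrix$values), "DRVYHPF")))
      de <- call_de(lg, de_config(cutoff_db = 2.0))
      up_true <- sim$truth$protein[sim$truth$class == "up"]
      hits <- hits + sum(de$call[match(up_true, de$protein)] == "up")
      total <- total + length(up_true)
    }
    hits / total
  }
  rates <- vapply(c(0.15, 0.3, 0.45, 0.6), rate_at, numeric(1))
  # non-decreasing up to Monte Carlo noise
  expect_true(all(diff(rates) > -0.04))
  expect_gt(rates[4], rates[1])
})
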