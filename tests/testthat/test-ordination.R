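make_log_qm <- function(v, n_ctrl = NULL) {
  n <- ncol(v)
  if (is.null(n_ctrl)) n_ctrl <- n %/% 2
  colnames(v) <- c(paste0("R18_", LETTERS[seq_len(n_ctrl)]),
                   paste0("R22_", LETTERS[seq_len(n - n_ctrl)]))
  if (is.null(rownames(v))) rownames(v) <- sprintf("P%03d", seq_len(nrow(v)))
  quant_matrix(v, rep(c("control_18C", "elevated_22C"),
                      c(n_ctrl, n - n_ctrl)), log10 = TRUE)
}

test_that("a rank-one expression pattern loads entirely on PC1", {
  set.seed(1)
  pattern <- stats::rnorm(6)
  v <- outer(stats::runif(8, 0.5, 2), pattern) + 5
  pca <- run_pca(make_log_qm(v))
  expect_equal(pca$variance_pct[1], 100, tolerance = 1e-8)
  expect_true(all(diff(pca$variance_pct) <= 1e-8))
  expect_equal(sum(pca$variance_pct), 100, tolerance = 1e-8)
})

test_that("variance fractions are invariant to sample and protein reordering", {
  set.seed(2)
  v <- matrix(stats::rnorm(80, 5), 8, 10)
  qm <- make_log_qm(v, n_ctrl = 5)
  ref <- run_pca(qm)$variance_pct
  perm_s <- sample(colnames(qm$values))
  perm_p <- sample(rownames(qm$values))
  alt <- run_pca(subset_quant_matrix(qm, proteins = perm_p,
                                     samples = perm_s))$variance_pct
  expect_equal(alt, ref, tolerance = 1e-9)
})

test_that("retained components reconstruct the standardized matrix", {
  set.seed(3)
  v <- matrix(stats::rnorm(60, 5), 6, 10)
  qm <- make_log_qm(v, n_ctrl = 5)
  pca <- run_pca(qm)
  xs <- scale(t(qm$values), center = TRUE, scale = TRUE)
  recon <- pca$scores %*% t(pca$loadings)
  expect_lt(max(abs(recon - xs)), 1e-8)
})

test_that("a strong condition effect separates the groups on PC1", {
  for (seed in 1:10) {
    sim <- generate_intensity_matrix(
      synth_config(n_proteins = 150, frac_up = 0.1, frac_down = 0.1,
                   log10_fc_up = 1.0, log10_fc_down = -1.0,
                   cv = 0.2, missing_rate = 0, seed = seed))
    lg <- log10_transform(subset_quant_matrix(
      sim$matrix, proteins = sim$truth$protein[sim$truth$class != "null"]))
    pca <- run_pca(lg)
    pc1 <- pca$scores[, 1]
    ctrl <- pc1[pca$condition == "control_18C"]
    elev <- pc1[pca$condition == "elevated_22C"]
    margin <- max(min(elev) - max(ctrl), min(ctrl) - max(elev))
    expect_gt(margin, 0)
  }
})

test_that("promax rotation changes reported loadings but never the variance fractions", {
  set.seed(4)
  v <- matrix(stats::rnorm(120, 5), 12, 10)
  qm <- make_log_qm(v, n_ctrl = 5)
  plain <- run_pca(qm)
  rot <- run_pca(qm, rotation = "promax")
  expect_equal(rot$variance_pct, plain$variance_pct)
  expect_false(is.null(rot$rotated_loadings))
  expect_identical(dim(rot$rotated_loadings), c(nrow(qm$values), 2L))
})

test_that("Pearson clustering orders by correlation structure", {
  base <- c(1, 2, 3, 4, 5, 6)
  v <- rbind(twinA = base, twinB = base,
             anti = 7 - base + c(0, 0.1, -0.1, 0.05, -0.05, 0))
  v <- v + 10
  qm <- make_log_qm(v)
  cl <- pearson_cluster(qm)
  # identical rows are at distance 0 and merge first
  expect_lt(cl$row_tree$height[1], 1e-12)
  first_pair <- rownames(v)[-cl$row_tree$merge[1, ]]
  expect_setequal(first_pair, c("twinA", "twinB"))
  # the anti-correlated row sits at distance ~2 and merges last
  d <- 1 - stats::cor(t(v))
  expect_equal(max(d), 2, tolerance = 0.01)
  expect_setequal(stats::cutree(cl$row_tree, 2)[c("twinA", "twinB")], 1)
  expect_identical(unname(stats::cutree(cl$row_tree, 2)["anti"]), 2L)
  # orders are permutations of the labels
  expect_setequal(cl$row_order, rownames(qm$values))
  expect_setequal(cl$col_order, colnames(qm$values))
})

test_that("anti-correlated up/down blocks form the two top-level row clusters", {
  set.seed(5)
  pattern <- rep(c(-1, 1), each = 5)
  up <- t(replicate(6, 5 + pattern + stats::rnorm(10, 0, 0.05)))
  dn <- t(replicate(6, 5 - pattern + stats::rnorm(10, 0, 0.05)))
  v <- rbind(up, dn)
  rownames(v) <- c(sprintf("up%02d", 1:6), sprintf("dn%02d", 1:6))
  qm <- make_log_qm(v, n_ctrl = 5)
  cl <- pearson_cluster(qm)
  k2 <- stats::cutree(cl$row_tree, 2)
  expect_identical(length(unique(k2[1:6])), 1L)
  expect_identical(length(unique(k2[7:12])), 1L)
  expect_false(k2[1] == k2[7])
})

test_that("isolated missing values are mean-imputed within condition for ordination only", {
  v <- matrix(rep(c(1, 2, 3, 10, 11, 12), 3), 3, 6, byrow = TRUE) + 0
  v[1, 2] <- NA
  v[2, 5] <- NA
  qm <- make_log_qm(v)
  imp <- impute_condition_mean(qm)
  expect_equal(imp$values[1, 2], mean(c(1, 3)))
  expect_equal(imp$values[2, 5], mean(c(10, 12)))
  expect_false(anyNA(imp$values))
})
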