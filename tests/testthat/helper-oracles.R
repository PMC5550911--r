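# Independent oracles and small fixture builders used across the suite.

# Sampled Gaussian trace on a regular RT grid.
gaussian_trace <- function(sigma, height, apex = 300, rt = seq(0, 600, 0.5)) {
  chromatogram(rt, height * exp(-(rt - apex)^2 / (2 * sigma^2)))
}

# Hand trapezoid rule (oracle; independent of pracma).
trapz_hand <- function(rt, y) {
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
u_enum_oracle <- function(control, elevated) {
  all_v <- c(control, elevated)
  n_e <- length(elevated)
  idx <- utils::combn(length(all_v), n_e)
  u_stat <- function(ev, cv) sum(outer(ev, cv, ">")) + 0.5 * sum(outer(ev, cv, "=="))
  u_obs <- u_stat(elevated, control)
  u_all <- apply(idx, 2, function(j) u_stat(all_v[j], all_v[-j]))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Benjamini-Hochberg step-up by the textbook formula, in input order.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Two-sided hypergeometric p by direct enumeration with choose():
# sum of all outcome probabilities not exceeding the observed one
# (the usual exact 2x2 two-sided convention).
hyper_enum_oracle <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  pr <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  p_obs <- pr[ks == k]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Tiny two-condition matrix on the log10 scale, built cell by cell.
toy_log_matrix <- function(rows, n_rep = 5,
                           conditions = c("control_18C", "elevated_22C")) {
  v <- do.call(rbind, rows)
  colnames(v) <- c(paste0("R18_", LETTERS[1:n_rep]),
                   paste0("R22_", LETTERS[1:n_rep]))
  quant_matrix(v, rep(conditions, each = n_rep), log10 = TRUE)
}
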