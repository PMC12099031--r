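# Fieller-type modified-large-sample interval (Gui et al. construction,
# the form adapted by Cappelleri & Ting for the agreement ICC).
#
# Write rho in terms of the expected mean squares theta = (EMSS, EMSR, EMSE):
#   rho = n(theta1 - theta3) / (n theta1 + k theta2 + (nk-n-k) theta3),
# so rho >= lambda iff W(lambda) >= 0 where
#   W(lambda) = n(1-lambda) theta1 - lambda k theta2 - (n + lambda(nk-n-k)) theta3,
# a linear combination with one positive and two negative coefficients for
# lambda in [0,1].  Modified-large-sample (Graybill-Wang) one-sided bounds on
# W(lambda), exact in the limiting cases of each variance component, are
# root-solved in lambda to give the confidence limits.  The interval always
# contains rho_hat, since W(rho_hat) evaluated at the observed mean squares
# is exactly zero.

# Graybill-Wang constants for a difference sum_p c_p S_p^2 - sum_q d_q S_q^2
# with a single positive component (p = participants) and two negative ones
# (q = raters, error), at one-sided level 1 - a.
mlsg_constants <- function(n, k, a) {
  nu1 <- n - 1
  nu2 <- k - 1
  nu3 <- (n - 1) * (k - 1)
  G1 <- 1 - 1 / qf_inf(1 - a, nu1)
  H2 <- 1 / qf_inf(a, nu2) - 1
  H3 <- 1 / qf_inf(a, nu3) - 1
  F12 <- stats::qf(1 - a, nu1, nu2)
  F13 <- stats::qf(1 - a, nu1, nu3)
  G12 <- ((F12 - 1)^2 - G1^2 * F12^2 - H2^2) / F12
  G13 <- ((F13 - 1)^2 - G1^2 * F13^2 - H3^2) / F13
  H1 <- 1 / qf_inf(a, nu1) - 1
  G2 <- 1 - 1 / qf_inf(1 - a, nu2)
  G3 <- 1 - 1 / qf_inf(1 - a, nu3)
  f12 <- stats::qf(a, nu1, nu2)
  f13 <- stats::qf(a, nu1, nu3)
  H12 <- ((f12 - 1)^2 - H1^2 * f12^2 - G2^2) / f12
  H13 <- ((f13 - 1)^2 - H1^2 * f13^2 - G3^2) / f13
  list(G1 = G1, H2 = H2, H3 = H3, G12 = G12, G13 = G13,
       H1 = H1, G2 = G2, G3 = G3, H12 = H12, H13 = H13)
}

# Lower MLS bound on W(lambda); vectors s1, s2, s3 are the observed mean
# squares, lambda a vector of the same length.
mlsg_wlow <- function(lambda, s1, s2, s3, n, k, cst) {
  c1 <- n * (1 - lambda)
  d2 <- lambda * k
  d3 <- n + lambda * (n * k - n - k)
  v <- cst$G1^2 * c1^2 * s1^2 + cst$H2^2 * d2^2 * s2^2 + cst$H3^2 * d3^2 * s3^2 +
    cst$G12 * c1 * d2 * s1 * s2 + cst$G13 * c1 * d3 * s1 * s3
  c1 * s1 - d2 * s2 - d3 * s3 - sqrt(pmax(0, v))
}

mlsg_wupp <- function(lambda, s1, s2, s3, n, k, cst) {
  c1 <- n * (1 - lambda)
  d2 <- lambda * k
  d3 <- n + lambda * (n * k - n - k)
  v <- cst$H1^2 * c1^2 * s1^2 + cst$G2^2 * d2^2 * s2^2 + cst$G3^2 * d3^2 * s3^2 +
    cst$H12 * c1 * d2 * s1 * s2 + cst$H13 * c1 * d3 * s1 * s3
  c1 * s1 - d2 * s2 - d3 * s3 + sqrt(pmax(0, v))
}

# Vectorized bisection for the sign change of f(lambda) on [0, 1].
# f must be positive at 0 and negative at 1 for an interior root.
mlsg_root <- function(f, m, iters = 30L) {
  lo <- rep(0, m)
  hi <- rep(1, m)
  at_zero <- f(lo) <= 0
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  out <- (lo + hi) / 2
  out[at_zero] <- 0
  out
}

# Two-sided (1 - alpha) MLSG limits, vectorized over datasets.
mlsg_limits <- function(mss, msr, mse, n, k, alpha = 0.05) {
  if (any(mse <= 0)) icc_degenerate_error("MSE must be positive for the MLSG interval")
  m <- length(mss)
  cst <- mlsg_constants(n, k, alpha / 2)
  lower <- mlsg_root(function(l) mlsg_wlow(l, mss, msr, mse, n, k, cst), m)
  upper <- mlsg_root(function(l) mlsg_wupp(l, mss, msr, mse, n, k, cst), m)
  cbind(lower = lower, upper = upper)
}
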