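# Vectorized confidence-limit workers.  Each takes vectors of mean squares
# (one element per dataset) plus scalar n, k, alpha, and returns a two-column
# matrix cbind(lower, upper).  The scalar user-facing ci_*() functions and the
# simulation / sample-size machinery both funnel through these.

# quantile of the F(df, Inf) distribution, i.e. chi-square_df / df
qf_inf <- function(p, df) stats::qchisq(p, df) / df

# agreement ICC from mean squares, vectorized, no boundary handling
rho_hat_ms <- function(mss, msr, mse, n, k) {
  (mss - mse) / (mss + (k - 1) * mse + (k / n) * (msr - mse))
}

# Delta method on the log scale: Wald limits for log(rho), exponentiated.
# Plug-in uses the observed mean squares for the expected mean squares.
# Returns NA rows where rho_hat <= 0 (method undefined).
wlog_limits <- function(mss, msr, mse, n, k, alpha = 0.05) {
  rho <- rho_hat_ms(mss, msr, mse, n, k)
  v_mss <- 2 * mss^2 / (n - 1)
  v_msr <- 2 * msr^2 / (k - 1)
  v_mse <- 2 * mse^2 / ((n - 1) * (k - 1))
  cc <- k - 1 - k / n
  en <- mss - mse
  ed <- mss + (k / n) * msr + cc * mse
  vlog <- (v_mss + v_mse) / en^2 +
    (v_mss + (k / n)^2 * v_msr + cc^2 * v_mse) / ed^2 -
    2 * (v_mss - cc * v_mse) / (en * ed)
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(vlog)
  out <- cbind(lower = exp(log(rho) - half), upper = exp(log(rho) + half))
  out[!is.finite(rho) | rho <= 0, ] <- NA_real_
  attr(out, "var_log") <- vlog
  out
}

# Modified large-sample interval (Arteaga-style): closed-form limits for the
# transformation k*rho/(n*(1-rho)), mapped back to the rho scale with
# max(0, .) clamping.  F1 = MSS/MSE, F2 = MSR/MSE.
mlsa_limits <- function(mss, msr, mse, n, k, alpha = 0.05) {
  if (any(mse <= 0)) icc_degenerate_error("MSE must be positive for the MLSA interval")
  mlsa_limits_f(mss / mse, msr / mse, n, k, alpha)
}

# MLSA limits from the F ratios F1 = MSS/MSE, F2 = MSR/MSE directly
mlsa_limits_f <- function(F1, F2, n, k, alpha = 0.05) {
  qlo <- 1 / qf_inf(1 - alpha / 2, n - 1)  # F^{-1}_{n-1,Inf}(1 - alpha/2)
  qup <- 1 / qf_inf(alpha / 2, n - 1)      # F^{-1}_{n-1,Inf}(alpha/2)
  F3 <- stats::qf(1 - alpha / 2, n - 1, k - 1)
  F4 <- stats::qf(alpha / 2, n - 1, k - 1)
  F5 <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  F6 <- stats::qf(alpha / 2, n - 1, (n - 1) * (k - 1))
  l_star <- (-1 + qlo * F1 + (1 - qlo * F5) * F5 / F1) / (n - 1 + qlo * F3 * F2)
  u_star <- (-1 + qup * F1 + (1 - qup * F6) * F6 / F1) / (n - 1 + qup * F4 * F2)
  l_star <- pmax(0, l_star)
  u_star <- pmax(0, u_star)
  cbind(lower = n * l_star / (k + n * l_star),
        upper = n * u_star / (k + n * u_star))
}

# Variance-partitioning F-interval: Satterthwaite chi-square approximations
# for sigma_s^2 and sigma_E^2 = sigma_r^2 + sigma_e^2, then F quantiles.
# Covariance terms are excluded from the component variances by default.
vpf_limits <- function(mss, msr, mse, n, k, alpha = 0.05, include_cov = FALSE) {
  v_mss <- 2 * mss^2 / (n - 1)
  v_msr <- 2 * msr^2 / (k - 1)
  v_mse <- 2 * mse^2 / ((n - 1) * (k - 1))
  s2s <- pmax(0, (mss - mse) / k)
  s2E <- pmax(0, (msr - mse) / n) + mse
  v_s <- (v_mss + v_mse) / k^2
  v_E <- (v_msr + v_mse) / n^2 + v_mse
  if (include_cov) v_E <- v_E - 2 * v_mse / n  # + 2 Cov(sigma_r^2, sigma_e^2)
  df1 <- pmax(1, 2 * s2s^2 / v_s)
  df2 <- 2 * s2E^2 / v_E
  flo <- stats::qf(alpha / 2, df1, df2)
  fhi <- stats::qf(1 - alpha / 2, df1, df2)
  out <- cbind(lower = s2s * flo / (s2s * flo + s2E),
               upper = s2s * fhi / (s2s * fhi + s2E))
  out[s2s <= 0 | s2E <= 0, ] <- NA_real_
  attr(out, "df") <- cbind(df1 = df1, df2 = df2)
  out
}

# Beta-method limits (variance partitioning with a beta approximation to the
# distribution of rho_hat).  Vectorized over datasets; rows with rho_hat
# outside (0,1) are NA (method undefined).
vpb_limits <- function(mss, msr, mse, n, k, alpha = 0.05) {
  v_mss <- 2 * mss^2 / (n - 1)
  v_msr <- 2 * msr^2 / (k - 1)
  v_mse <- 2 * mse^2 / ((n - 1) * (k - 1))
  s2s <- pmax(0, (mss - mse) / k)
  s2E <- pmax(0, (msr - mse) / n) + mse
  s2T <- s2s + s2E
  v_s <- (v_mss + v_mse) / k^2
  v_E <- (v_msr + v_mse) / n^2 + v_mse - 2 * v_mse / n
  # Cov(s, E) = Cov(s, r) + Cov(s, e) = V(MSE)/(nk) - V(MSE)/k
  cov_sE <- v_mse / (n * k) - v_mse / k
  rho <- s2s / s2T
  v_rho <- (s2E^2 * v_s + s2s^2 * v_E - 2 * s2s * s2E * cov_sE) / s2T^4
  ok <- is.finite(rho) & rho > 0 & rho < 1 & v_rho > 0
  lower <- upper <- rep(NA_real_, length(rho))
  if (any(ok)) {
    ab <- beta_params_vec(rho[ok], v_rho[ok])
    lower[ok] <- stats::qbeta(alpha / 2, ab[, 1], ab[, 2])
    upper[ok] <- stats::qbeta(1 - alpha / 2, ab[, 1], ab[, 2])
  }
  cbind(lower = lower, upper = upper)
}

# Moment-matched beta parameters with the U-shape and negative-value fixes.
# Returns cbind(a, b) plus a "fix" attribute coding which fix fired.
beta_params_vec <- function(rho, v_rho) {
  a <- rho * (rho * (1 - rho) - v_rho) / v_rho
  b <- (1 - rho) * (rho * (1 - rho) - v_rho) / v_rho
  fix <- rep("none", length(rho))
  neg <- a <= 0 | b <= 0
  if (any(neg)) {
    lo <- neg & rho <= 0.5
    hi <- neg & rho > 0.5
    a[lo] <- rho[lo] / (1 - rho[lo]); b[lo] <- 1; fix[lo] <- "neg_low"
    a[hi] <- 1; b[hi] <- rho[hi] / (1 - rho[hi]); fix[hi] <- "neg_high"
  }
  ush <- !neg & a < 1 & b < 1
  if (any(ush)) {
    lo <- ush & rho <= 0.5   # ties at 0.5 take the <=0.5 branch
    hi <- ush & rho > 0.5
    b[lo] <- 1
    a[lo] <- rho[lo] * (rho[lo] * (1 - rho[lo]) - v_rho[lo]) / v_rho[lo]
    fix[lo] <- "u_shape_low"
    a[hi] <- 1
    b[hi] <- (1 - rho[hi]) * (rho[hi] * (1 - rho[hi]) - v_rho[hi]) / v_rho[hi]
    fix[hi] <- "u_shape_high"
  }
  out <- cbind(a = a, b = b)
  attr(out, "fix") <- fix
  out
}
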