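fixed_ms <- function(seed = 201, n = 100, k = 8, rho = 0.7, R = 0.1) {
  set.seed(seed)
  mean_squares(simulate_dataset(simulation_config(n, k, rho, R)))
}

test_that("log-scale delta interval matches a term-by-term oracle", {
  ms <- fixed_ms()
  n <- ms$n; k <- ms$k
  ci <- ci_wlog(ms)
  # independent composition of the three-term variance with plug-in
  # mean squares for the expected mean squares
  v1 <- 2 * ms$mss^2 / (n - 1)
  v2 <- 2 * ms$msr^2 / (k - 1)
  v3 <- 2 * ms$mse^2 / ((n - 1) * (k - 1))
  cc <- k - 1 - k / n
  en <- ms$mss - ms$mse
  ed <- ms$mss + (k / n) * ms$msr + cc * ms$mse
  vlog <- (v1 + v3) / en^2 +
    (v1 + (k / n)^2 * v2 + cc^2 * v3) / ed^2 -
    2 * (v1 - cc * v3) / (en * ed)
  rho_hat <- icc_agreement(ms)
  z <- qnorm(0.975)
  expect_equal(ci$lower, exp(log(rho_hat) - z * sqrt(vlog)), tolerance = 1e-12)
  expect_equal(ci$upper, exp(log(rho_hat) + z * sqrt(vlog)), tolerance = 1e-12)
  expect_equal(ci$diagnostics$var_log, vlog)

  # method undefined when the ICC estimate is nonpositive
  expect_error(ci_wlog(as_mean_squares(0.5, 1, 1, 20, 4)),
               class = "icc_method_undefined_error")
})

test_that("matrix-form delta interval follows its transcription", {
  set.seed(202)
  rt <- simulate_dataset(simulation_config(40, 4, 0.7, 0.5))
  sm <- matrix_summaries(rt)
  ci <- ci_wmat(rt)
  n <- sm$n; k <- sm$k; cc <- n * k - n - k
  rho <- eq_matrix_rho(rt)
  v <- rho^2 * ((1 - rho / n)^2 * 2 * sm$one_S_one^2 / (n + 1) +
                  (1 + cc * rho / n)^2 * 2 * sm$trace_S2 / (n + 1) -
                  2 * (1 - rho / n) * (1 + cc * rho / n) * 2 * sm$one_S2_one / (n + 1) +
                  k^2 * rho^2 * 2 * sm$yd_sq^2 / (k + 1)) /
    (sm$one_S_one - sm$trace_S)^2
  half <- qt(0.975, n + 1) * sqrt(v)
  expect_equal(ci$lower, rho - half, tolerance = 1e-12)
  expect_equal(ci$upper, rho + half, tolerance = 1e-12)

  # identical rater means: the rater-mean variance term vanishes
  y <- ratings_values(rt)
  y_centered <- sweep(y, 2L, colMeans(y)) + mean(y)
  expect_equal(matrix_summaries(y_centered)$yd_sq, 0, tolerance = 1e-18)

  expect_error(ci_wmat(matrix(3, 4, 3)), class = "icc_degenerate_error")
})

test_that("MLSA limits match an independent re-transcription and clamp at zero", {
  set.seed(203)
  ms <- mean_squares(simulate_dataset(simulation_config(20, 5, 0.7, 1)))
  ci <- ci_mlsa(ms)
  n <- ms$n; k <- ms$k; alpha <- 0.05
  F1 <- ms$mss / ms$mse
  F2 <- ms$msr / ms$mse
  iq <- function(p) (n - 1) / qchisq(p, n - 1)   # F^{-1}_{n-1,Inf}(p)
  F3 <- qf(1 - alpha / 2, n - 1, k - 1); F4 <- qf(alpha / 2, n - 1, k - 1)
  F5 <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  F6 <- qf(alpha / 2, n - 1, (n - 1) * (k - 1))
  ls <- (-1 + iq(1 - alpha / 2) * F1 + (1 - iq(1 - alpha / 2) * F5) * F5 / F1) /
    (n - 1 + iq(1 - alpha / 2) * F3 * F2)
  us <- (-1 + iq(alpha / 2) * F1 + (1 - iq(alpha / 2) * F6) * F6 / F1) /
    (n - 1 + iq(alpha / 2) * F4 * F2)
  expect_equal(ci$lower, n * max(0, ls) / (k + n * max(0, ls)), tolerance = 1e-12)
  expect_equal(ci$upper, n * max(0, us) / (k + n * max(0, us)), tolerance = 1e-12)

  # negative transformed lower limit clamps the interval at zero
  low <- ci_mlsa(as_mean_squares(1.05, 1, 1, 20, 5))
  expect_identical(low$lower, 0)
  expect_error(ci_mlsa(as_mean_squares(1, 1, 0, 20, 5)),
               class = "icc_degenerate_error")
})

test_that("MLSG interval always contains the point estimate, inside [0,1]", {
  set.seed(204)
  for (i in 1:60) {
    ms <- mean_squares(random_table(sample(8:40, 1), sample(2:8, 1),
                                    rho = runif(1, 0.3, 0.95), R = runif(1, 0, 2)))
    ci <- ci_mlsg(ms)
    rho_hat <- icc_agreement(ms)
    expect_gte(ci$upper + 1e-10, min(1, max(0, rho_hat)))
    expect_lte(ci$lower - 1e-10, max(0, rho_hat))
    expect_true(ci$lower >= 0 && ci$upper <= 1 && ci$lower <= ci$upper)
  }
})

test_that("MLSG and GCI widths agree at large n", {
  set.seed(205)
  ms <- mean_squares(simulate_dataset(simulation_config(5000, 10, 0.7, 0.1)))
  w_mlsg <- ci_mlsg(ms)$width
  w_gci <- ci_gci(ms, cfg = gci_config(1e5, rng_seed = 1))$width
  expect_lt(abs(w_mlsg - w_gci) / w_gci, 0.05)
})

test_that("variance-partitioning variance matches its term-by-term oracle", {
  vc <- variance_components(as_mean_squares(7, 4, 1, n = 20, k = 4))
  V <- vc$vcov
  vE <- V[2, 2] + V[3, 3] + 2 * V[2, 3]
  cSE <- V[1, 2] + V[1, 3]
  manual <- (vc$sigma2_E^2 * V[1, 1] + vc$sigma2_s^2 * vE -
               2 * vc$sigma2_s * vc$sigma2_E * cSE) / vc$sigma2_T^4
  expect_equal(var_rho_vp(vc), manual, tolerance = 1e-12)
  expect_error(var_rho_vp(variance_components(as_mean_squares(0, 0, 0, 5, 3))),
               class = "icc_degenerate_error")
})

test_that("delta variance approximates the sampling variance of the estimator", {
  cfg <- simulation_config(100, 5, rho = 0.8, ratio_R = 0.1, seed = 206)
  set.seed(206)
  d <- simulate_mean_squares(cfg, 4000)
  rho_hat <- (d$mss - d$mse) /
    (d$mss + 4 * d$mse + (5 / 100) * (d$msr - d$mse))
  v12 <- vapply(seq_len(2000), function(i) {
    var_rho_vp(variance_components(as_mean_squares(d$mss[i], d$msr[i], d$mse[i], 100, 5)))
  }, numeric(1))
  expect_lt(abs(var(rho_hat) - mean(v12)) / mean(v12), 0.15)
})

test_that("VPF uses floored Satterthwaite degrees of freedom and F quantiles", {
  ms <- as_mean_squares(7, 4, 1, n = 20, k = 4)
  ci <- ci_vpf(ms)
  s2s <- (7 - 1) / 4
  s2E <- (4 - 1) / 20 + 1
  lo <- qf(0.025, ci$diagnostics$df1, ci$diagnostics$df2)
  hi <- qf(0.975, ci$diagnostics$df1, ci$diagnostics$df2)
  expect_equal(ci$lower, s2s * lo / (s2s * lo + s2E), tolerance = 1e-12)
  expect_equal(ci$upper, s2s * hi / (s2s * hi + s2E), tolerance = 1e-12)
  expect_true(ci$lower > 0 && ci$upper < 1)

  # raw df1 below 1 is floored at 1 and flagged
  tiny <- ci_vpf(as_mean_squares(1.02, 1, 1, 4, 3))
  expect_equal(tiny$diagnostics$df1, 1)
  expect_true(tiny$diagnostics$df1_floored)

  expect_error(ci_vpf(as_mean_squares(0.5, 1, 1, 20, 4)),
               class = "icc_degenerate_error")
})

test_that("beta parameters follow the moment equations and their fixes", {
  bp <- fit_beta_params(0.75, 0.01)
  expect_equal(bp$a, 13.3125)
  expect_equal(bp$b, 4.4375)
  expect_identical(bp$fix_applied, "none")

  # variance exceeding rho(1-rho): pinned-parameter fix, as stated
  bp2 <- fit_beta_params(0.8, 0.3)
  expect_equal(bp2$a, 1)
  expect_equal(bp2$b, 4)
  expect_identical(bp2$fix_applied, "neg_high")

  # U-shaped raw estimates at the 0.5 tie take the lower branch
  bp3 <- fit_beta_params(0.5, 0.13)  # raw a = b ~ 0.46
  expect_identical(bp3$fix_applied, "u_shape_low")
  expect_equal(bp3$b, 1)
  expect_lt(bp3$a, 1)

  expect_error(fit_beta_params(1.2, 0.01), class = "icc_method_undefined_error")
  expect_error(fit_beta_params(0.5, -1), class = "icc_input_error")
})

test_that("beta interval quantiles come from the fitted beta distribution", {
  # moment equations give the uniform a = b = 1 exactly at rho = 0.5,
  # V = 1/12, whose quantile limits are (alpha/2, 1 - alpha/2)
  bp <- fit_beta_params(0.5, 1 / 12)
  expect_equal(c(bp$a, bp$b), c(1, 1))

  ms <- fixed_ms(seed = 207, n = 60, k = 5)
  ci <- ci_vpb(ms)
  expect_equal(ci$lower, qbeta(0.025, ci$diagnostics$a, ci$diagnostics$b),
               tolerance = 1e-12)
  expect_equal(ci$upper, qbeta(0.975, ci$diagnostics$a, ci$diagnostics$b),
               tolerance = 1e-12)
})

test_that("intervals are ordered and nested across confidence levels", {
  set.seed(208)
  rt <- simulate_dataset(simulation_config(30, 4, 0.7, 0.5))
  ms <- mean_squares(rt)
  vc <- variance_components(ms)
  makers <- list(
    function(a) ci_wlog(ms, a), function(a) ci_wmat(rt, a),
    function(a) ci_mlsa(ms, a), function(a) ci_mlsg(ms, a),
    function(a) ci_gci(ms, a, gci_config(5e3, rng_seed = 3)),
    function(a) ci_vpf(vc, a), function(a) ci_vpb(vc, a))
  for (mk in makers) {
    ci95 <- mk(0.05)
    ci99 <- mk(0.01)
    expect_lte(ci95$lower, ci95$upper)
    expect_lte(ci99$lower, ci95$lower + 1e-9)
    expect_gte(ci99$upper, ci95$upper - 1e-9)
    expect_equal(ci95$width, ci95$upper - ci95$lower)
  }
})

test_that("bounded methods stay in [0,1] over random inputs", {
  set.seed(209)
  d <- simulate_mean_squares(simulation_config(15, 3, 0.6, 1), 400)
  for (fn in list(iccagree:::mlsa_limits, iccagree:::mlsg_limits,
                  iccagree:::vpf_limits, iccagree:::vpb_limits)) {
    lim <- fn(d$mss, d$msr, d$mse, 15, 3, 0.05)
    ok <- is.finite(lim[, 1])
    expect_true(all(lim[ok, 1] >= 0 & lim[ok, 2] <= 1))
    expect_true(all(lim[ok, 1] <= lim[ok, 2] + 1e-12))
  }
})

test_that("the all-methods wrapper reports failures without aborting", {
  set.seed(210)
  rt <- simulate_dataset(simulation_config(25, 4, 0.7, 0.1))
  tab <- icc_ci(rt, gci = gci_config(2e3, rng_seed = 4))
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$lower <= tab$upper, na.rm = TRUE))

  # a table with a nonpositive estimate: Wlog/VPB degrade gracefully
  bad <- matrix(rnorm(40), 10, 4)  # pure noise, rho near 0
  tab2 <- icc_ci(bad, methods = c("wlog", "mlsa"), gci = gci_config(2e3))
  expect_equal(nrow(tab2), 2L)
})
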