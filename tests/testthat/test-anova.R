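test_that("mean squares match hand computation and the brute-force sums", {
  ms <- mean_squares(matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE))
  expect_equal(ms$mss, 2)
  expect_equal(ms$msr, 0)
  expect_equal(ms$mse, 0)
  expect_equal(c(ms$df_s, ms$df_r, ms$df_e), c(2L, 1L, 2L))

  const <- mean_squares(matrix(5, 4, 3))
  expect_equal(c(const$mss, const$msr, const$mse), c(0, 0, 0))

  set.seed(101)
  y <- ratings_values(random_table(20, 3))
  ms <- mean_squares(y)
  bf <- brute_mean_squares(y)
  expect_equal(ms$mss, bf$mss, tolerance = 1e-10)
  expect_equal(ms$msr, bf$msr, tolerance = 1e-10)
  expect_equal(ms$mse, bf$mse, tolerance = 1e-10)
})

test_that("the sum of squares decomposes exactly over random tables", {
  set.seed(102)
  for (i in 1:50) {
    y <- ratings_values(random_table(sample(5:30, 1), sample(2:6, 1)))
    ms <- mean_squares(y)
    total <- sum((y - mean(y))^2)
    decomp <- (ms$n - 1) * ms$mss + (ms$k - 1) * ms$msr + ms$df_e * ms$mse
    expect_equal(decomp, total, tolerance = 1e-9)
  }
})

test_that("invalid ratings tables are rejected", {
  expect_error(ratings_table(matrix(1:4, 1, 4)), class = "icc_dimension_error")
  expect_error(ratings_table(matrix(c(1, NA, 2, 3), 2, 2)), class = "icc_input_error")
  expect_error(ratings_table(matrix(letters[1:4], 2, 2)), class = "icc_input_error")
})

test_that("agreement estimator equals the matrix form on random tables", {
  set.seed(103)
  worst <- 0
  for (i in 1:300) {
    rt <- random_table(sample(5:40, 1), sample(2:8, 1),
                       rho = runif(1, 0.2, 0.95), R = runif(1, 0, 2))
    worst <- max(worst, abs(icc_agreement(rt) - eq_matrix_rho(rt)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ICC point estimators handle the boundary cases", {
  expect_equal(icc_agreement(as_mean_squares(3, 0, 0, 10, 3)), 1)
  expect_equal(icc_agreement(as_mean_squares(1, 1, 1, 10, 3)), 0)
  expect_equal(icc_consistency(as_mean_squares(3, 1, 0, 10, 3)), 1)
  expect_equal(icc_consistency(as_mean_squares(1, 2, 1, 10, 3)), 0)
  expect_error(icc_agreement(matrix(2, 3, 3)), class = "icc_degenerate_error")

  # consistency dominates agreement whenever MSR >= MSE
  set.seed(104)
  for (i in 1:50) {
    ms <- mean_squares(random_table(12, 4, rho = 0.6, R = 1))
    if (ms$msr >= ms$mse) {
      expect_gte(icc_consistency(ms), icc_agreement(ms))
    }
  }
})

test_that("matrix summaries satisfy their mean-square identities", {
  sm <- matrix_summaries(matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE))
  expect_equal(sm$trace_S, 2)
  expect_equal(sm$yd_sq, 0)
  expect_equal(sm$one_S_one, 4)  # k * MSS

  sm0 <- matrix_summaries(matrix(7, 5, 3))
  expect_equal(c(sm0$one_S_one, sm0$trace_S, sm0$yd_sq), c(0, 0, 0))

  set.seed(105)
  for (i in 1:30) {
    rt <- random_table(sample(5:25, 1), sample(2:6, 1))
    ms <- mean_squares(rt)
    sm <- matrix_summaries(rt)
    expect_equal(sm$one_S_one, ms$k * ms$mss, tolerance = 1e-10)
    expect_equal(sm$trace_S, ms$mss + (ms$k - 1) * ms$mse, tolerance = 1e-10)
    expect_equal(sm$yd_sq, (ms$k - 1) * ms$msr / ms$n, tolerance = 1e-10)
  }
})

test_that("variance components invert the expected mean squares", {
  vc <- variance_components(as_mean_squares(7, 4, 1, n = 10, k = 3))
  expect_equal(vc$sigma2_s, 2)
  expect_equal(vc$sigma2_r, 0.3)
  expect_equal(vc$sigma2_e, 1)
  expect_equal(vc$sigma2_T, vc$sigma2_s + vc$sigma2_r + vc$sigma2_e)
  expect_equal(vc$rho, 2 / 3.3)
  expect_false(any(vc$truncated))

  tr <- variance_components(as_mean_squares(0.5, 0.8, 1, n = 10, k = 3))
  expect_equal(tr$sigma2_s, 0)
  expect_true(tr$truncated["sigma2_s"])
  expect_lt(tr$untruncated["sigma2_s"], 0)
})

test_that("estimator covariance matches the chi-square formulas and simulation", {
  V <- vcov_variance_components(c(2, 0.3, 1), n = 10, k = 3)
  expect_equal(V["sigma2_e", "sigma2_e"], 2 * 1^2 / (9 * 2))
  expect_true(isSymmetric(V))
  expect_true(all(diag(V) > 0))
  expect_error(vcov_variance_components(c(0, 0, 0), 10, 3),
               class = "icc_degenerate_error")

  # sigma_r^2 does not influence the variance of sigma_s^2-hat
  V2 <- vcov_variance_components(c(2, 100, 1), n = 10, k = 3)
  expect_equal(V2["sigma2_s", "sigma2_s"], V["sigma2_s", "sigma2_s"])

  # empirical check of the diagonal against untruncated moment estimators
  n <- 50; k <- 5; rho <- 0.7; R <- 0.1
  cfg <- simulation_config(n, k, rho, R, seed = 106)
  set.seed(106)
  d <- simulate_mean_squares(cfg, 5000)
  est <- cbind((d$mss - d$mse) / k, (d$msr - d$mse) / n, d$mse)
  Vth <- vcov_variance_components(c(cfg$sigma2_s, cfg$sigma2_r, cfg$sigma2_e), n, k)
  for (j in 1:3) {
    emp <- var(est[, j])
    se <- emp * sqrt(2 / 5000) * 2  # rough se of a sample variance
    expect_lt(abs(emp - Vth[j, j]), 3 * se + 0.02 * Vth[j, j])
  }
})

test_that("moment estimators recover the generating components on average", {
  cfg <- simulation_config(200, 5, rho = 0.8, ratio_R = 0.5, seed = 107)
  set.seed(107)
  d <- simulate_mean_squares(cfg, 4000)
  est <- cbind(s = (d$mss - d$mse) / 5, r = (d$msr - d$mse) / 200, e = d$mse)
  truth <- c(cfg$sigma2_s, cfg$sigma2_r, cfg$sigma2_e)
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(4000)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se)
  }
})

test_that("simulated datasets reproduce the mean-square moments", {
  # full-data route: validates the generator against the expected mean
  # squares and their chi-square variances
  cfg <- simulation_config(15, 4, rho = 0.7, ratio_R = 1, seed = 108)
  set.seed(108)
  reps <- 4000
  mss <- msr <- mse <- numeric(reps)
  for (i in seq_len(reps)) {
    ms <- mean_squares(simulate_dataset(cfg))
    mss[i] <- ms$mss; msr[i] <- ms$msr; mse[i] <- ms$mse
  }
  t1 <- cfg$k * cfg$sigma2_s + 1
  t2 <- cfg$n * cfg$sigma2_r + 1
  ev <- c(t1, t2, 1)
  vv <- c(2 * t1^2 / 14, 2 * t2^2 / 3, 2 / (14 * 3))
  obs <- list(mss, msr, mse)
  for (j in 1:3) {
    expect_lt(abs(mean(obs[[j]]) - ev[j]), 3 * sd(obs[[j]]) / sqrt(reps))
    se_var <- var(obs[[j]]) * sqrt(2 / reps) * 2
    expect_lt(abs(var(obs[[j]]) - vv[j]), 3 * se_var + 0.05 * vv[j])
  }
})
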