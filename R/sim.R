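#' Configuration of the Monte Carlo study design
#'
#' Parameterizes the generative two-way random-effects model used
#' throughout the simulation and sample-size machinery.  The error
#' variance is fixed at \eqn{\sigma_e^2 = 1} by default; the rater
#' variance is \eqn{\sigma_r^2 = R\,\sigma_e^2} and the participant
#' variance follows from the planned ICC,
#' \eqn{\sigma_s^2 = \rho(R+1)\sigma_e^2/(1-\rho)}, so that the agreement
#' ICC of the generated data is exactly `rho`.  The grand mean is zero
#' (the ICC is location- and scale-free).
#'
#' @param n,k Numbers of participants and raters.
#' @param rho Planned ICC for agreement, in (0, 1).
#' @param ratio_R Rater-to-error variance ratio \eqn{R = \sigma_r^2/\sigma_e^2}.
#' @param sigma2_e Error variance (default 1).
#' @param reps Number of Monte Carlo replications for evaluation runs.
#' @param seed Optional integer master seed.
#' @param alpha Two-sided error rate for the intervals under study.
#' @param gci_draws Pivot draws per replicate for the generalized interval.
#' @return A list of class `sim_config` including the derived `sigma2_s`
#'   and `sigma2_r`.
#' @examples
#' simulation_config(n = 50, k = 5, rho = 0.7, ratio_R = 0.1)$sigma2_s
#' # 0.7 * 1.1 / 0.3 = 2.5667
#' @export
simulation_config <- function(n, k, rho, ratio_R, sigma2_e = 1,
                              reps = 1e4, seed = NULL, alpha = 0.05,
                              gci_draws = 1e4) {
  if (rho <= 0 || rho >= 1) icc_input_error("rho must be in (0, 1)")
  if (ratio_R < 0) icc_input_error("ratio_R must be nonnegative")
  if (sigma2_e <= 0) icc_input_error("sigma2_e must be positive")
  if (n < 2 || k < 2) icc_dimension_error("need n >= 2 and k >= 2")
  structure(
    list(n = as.integer(n), k = as.integer(k), rho = rho, ratio_R = ratio_R,
         sigma2_e = sigma2_e,
         sigma2_r = ratio_R * sigma2_e,
         sigma2_s = rho * (ratio_R + 1) * sigma2_e / (1 - rho),
         reps = as.integer(reps), seed = seed, alpha = alpha,
         gci_draws = as.integer(gci_draws)),
    class = "sim_config")
}

#' Simulate one ratings table from the two-way random model
#'
#' Draws independent normal participant effects, rater effects and errors
#' at the variances implied by the configuration and returns the complete
#' n x k table \eqn{y_{ij} = s_i + r_j + e_{ij}}.
#'
#' @param cfg A [simulation_config()].
#' @return A [ratings_table()].
#' @export
simulate_dataset <- function(cfg) {
  s <- stats::rnorm(cfg$n, 0, sqrt(cfg$sigma2_s))
  r <- if (cfg$sigma2_r > 0) stats::rnorm(cfg$k, 0, sqrt(cfg$sigma2_r)) else rep(0, cfg$k)
  e <- matrix(stats::rnorm(cfg$n * cfg$k, 0, sqrt(cfg$sigma2_e)), cfg$n, cfg$k)
  ratings_table(e + outer(s, rep(1, cfg$k)) + outer(rep(1, cfg$n), r))
}

#' Simulate mean squares directly from their exact sampling law
#'
#' Under the model the three mean squares are independent scaled
#' chi-squares: \eqn{MSS \sim (k\sigma_s^2+\sigma_e^2)\chi^2_{n-1}/(n-1)},
#' \eqn{MSR \sim (n\sigma_r^2+\sigma_e^2)\chi^2_{k-1}/(k-1)},
#' \eqn{MSE \sim \sigma_e^2 \chi^2_{(n-1)(k-1)}/((n-1)(k-1))}.  Sampling
#' them directly is distributionally identical to simulating full tables
#' (the mean squares are the sufficient statistics for every method that
#' consumes them) and much faster.
#'
#' @param cfg A [simulation_config()].
#' @param reps Number of replicate triples (defaults to `cfg$reps`).
#' @return A data frame with columns `mss`, `msr`, `mse`.
#' @export
simulate_mean_squares <- function(cfg, reps = cfg$reps) {
  t1 <- cfg$k * cfg$sigma2_s + cfg$sigma2_e
  t2 <- cfg$n * cfg$sigma2_r + cfg$sigma2_e
  t3 <- cfg$sigma2_e
  nu1 <- cfg$n - 1L
  nu2 <- cfg$k - 1L
  nu3 <- nu1 * nu2
  data.frame(
    mss = t1 * stats::rchisq(reps, nu1) / nu1,
    msr = t2 * stats::rchisq(reps, nu2) / nu2,
    mse = t3 * stats::rchisq(reps, nu3) / nu3)
}

#' Monte Carlo evaluation of interval methods
#'
#' Replicates the study design: simulate `cfg$reps` datasets, compute the
#' requested confidence intervals on each, and summarize empirical
#' coverage of the true `cfg$rho` and average width.  Replicates where a
#' method is undefined (for example a nonpositive ICC estimate for Wlog)
#' are excluded from both summaries and counted in `error_rate`.  All
#' methods see identical datasets (paired comparison).
#'
#' @param cfg A [simulation_config()]; `cfg$seed`, if set, makes the run
#'   reproducible.
#' @param methods Character vector of method names (see [icc_ci()]).
#' @return A data frame with one row per method: `method`, `coverage`,
#'   `avg_width`, `reps_used`, `error_rate`.
#' @export
evaluate_methods <- function(cfg, methods = c("wlog", "wmat", "mlsa", "mlsg",
                                              "gci", "vpf", "vpb")) {
  methods <- match.arg(methods, c("wlog", "wmat", "mlsa", "mlsg", "gci", "vpf", "vpb"),
                       several.ok = TRUE)
  if (cfg$reps < 100L) icc_input_error("need at least 100 replications")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  k <- cfg$k
  reps <- cfg$reps
  need_data <- "wmat" %in% methods
  mss <- msr <- mse <- numeric(reps)
  wmat_lim <- matrix(NA_real_, reps, 2L)
  gci_lim <- matrix(NA_real_, reps, 2L)
  for (i in seq_len(reps)) {
    rt <- simulate_dataset(cfg)
    msi <- mean_squares(rt)
    mss[i] <- msi$mss; msr[i] <- msi$msr; mse[i] <- msi$mse
    if (need_data) {
      lim <- tryCatch(ci_wmat(rt, cfg$alpha), icc_error = function(e) NULL)
      if (!is.null(lim)) wmat_lim[i, ] <- c(lim$lower, lim$upper)
    }
    if ("gci" %in% methods) {
      x1 <- stats::rchisq(cfg$gci_draws, n - 1)
      x2 <- stats::rchisq(cfg$gci_draws, k - 1)
      x3 <- stats::rchisq(cfg$gci_draws, (n - 1) * (k - 1))
      draws <- sort(gci_pivot_eval(msi$mss, msi$msr, msi$mse, n, k, x1, x2, x3))
      gci_lim[i, ] <- c(quantile_inv_ecdf(draws, cfg$alpha / 2),
                        quantile_inv_ecdf(draws, 1 - cfg$alpha / 2))
    }
  }
  limits_for <- function(m) {
    switch(m,
      wlog = wlog_limits(mss, msr, mse, n, k, cfg$alpha),
      mlsa = mlsa_limits(mss, msr, mse, n, k, cfg$alpha),
      mlsg = mlsg_limits(mss, msr, mse, n, k, cfg$alpha),
      vpf  = vpf_limits(mss, msr, mse, n, k, cfg$alpha),
      vpb  = vpb_limits(mss, msr, mse, n, k, cfg$alpha),
      wmat = wmat_lim,
      gci  = gci_lim)
  }
  rows <- lapply(methods, function(m) {
    lim <- limits_for(m)
    ok <- is.finite(lim[, 1]) & is.finite(lim[, 2])
    data.frame(
      method = toupper(m),
      coverage = mean(lim[ok, 1] <= cfg$rho & cfg$rho <= lim[ok, 2]),
      avg_width = mean(lim[ok, 2] - lim[ok, 1]),
      reps_used = sum(ok),
      error_rate = mean(!ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  out
}

#' Classify a coverage probability into the study's distance bands
#'
#' Bands are defined by the distance of the empirical coverage from the
#' nominal level \eqn{1-\alpha}: at most 0.01 (best), (0.01, 0.03],
#' (0.03, 0.04], (0.04, 0.05], and more than 0.05 (worst; for a 95%
#' interval this means coverage below 0.90 or above 1).  Over-coverage is
#' flagged with a `"+"`.
#'
#' @param coverage Empirical coverage in \[0, 1\].
#' @param alpha Nominal two-sided error rate.
#' @return A list with `band` (one of `"<=0.01"`, `"(0.01,0.03]"`,
#'   `"(0.03,0.04]"`, `"(0.04,0.05]"`, `">0.05"`), `over` (logical) and
#'   `distance`.
#' @export
classify_coverage_band <- function(coverage, alpha = 0.05) {
  if (coverage < 0 || coverage > 1) icc_input_error("coverage must be in [0, 1]")
  nominal <- 1 - alpha
  d <- abs(coverage - nominal)
  band <- if (d <= 0.01) "<=0.01"
  else if (d <= 0.03) "(0.01,0.03]"
  else if (d <= 0.04) "(0.03,0.04]"
  else if (d <= 0.05) "(0.04,0.05]"
  else ">0.05"
  list(band = band, over = coverage > nominal, distance = d)
}
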