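new_icc_ci <- function(method, alpha, lower, upper, diagnostics = list()) {
  lower <- unname(lower)
  upper <- unname(upper)
  diagnostics <- lapply(diagnostics, unname)
  structure(
    list(method = method, alpha = alpha,
         lower = lower, upper = upper, width = upper - lower,
         diagnostics = diagnostics),
    class = "icc_ci")
}

#' @export
print.icc_ci <- function(x, ...) {
  cat(sprintf("%s %.0f%% confidence interval for the agreement ICC: [%.4f, %.4f] (width %.4f)\n",
              x$method, 100 * (1 - x$alpha), x$lower, x$upper, x$width))
  invisible(x)
}

#' Delta-method interval on the log scale (Wlog)
#'
#' Wald confidence interval for \eqn{\log\rho} using the delta-method
#' variance of the log-transformed agreement ICC estimator (a three-term
#' expression in the variances of the independent mean squares), then
#' exponentiated back.  The plug-in inserts the estimated variance
#' components; the method is undefined when \eqn{\hat\rho \le 0}.
#'
#' @param ms An `icc_mean_squares` object (or anything [mean_squares()]
#'   accepts).
#' @param alpha Two-sided error rate; default 0.05 for a 95% interval.
#' @return An `icc_ci` object with fields `method`, `alpha`, `lower`,
#'   `upper`, `width` and `diagnostics` (here the estimated
#'   \eqn{V(\log\hat\rho)}).  The upper limit is not clipped at 1.
#' @export
ci_wlog <- function(ms, alpha = 0.05) {
  ms <- as_ms(ms)
  rho <- rho_hat_ms(ms$mss, ms$msr, ms$mse, ms$n, ms$k)
  if (!is.finite(rho) || rho <= 0) {
    icc_method_undefined_error("Wlog requires a positive ICC estimate (log undefined)")
  }
  lim <- wlog_limits(ms$mss, ms$msr, ms$mse, ms$n, ms$k, alpha)
  new_icc_ci("Wlog", alpha, lim[1, 1], lim[1, 2],
             list(var_log = attr(lim, "var_log")[1]))
}

#' Delta-method interval in matrix form (Wmat)
#'
#' Uses the matrix formulation of the agreement ICC estimator in terms of
#' the rater covariance matrix `S` and the rater-mean deviations, with a
#' delta-method variance built from the sample quantities \eqn{1'S1},
#' \eqn{\mathrm{tr}S}, \eqn{1'S^21}, \eqn{\mathrm{tr}S^2} and
#' \eqn{y_d'y_d}.  The limits use a t distribution with n + 1 degrees of
#' freedom, the (unusual) reference distribution this construction
#' prescribes, implemented as stated.
#'
#' @param data A [ratings_table()] or numeric ratings matrix (the method
#'   needs the raw data, not just the mean squares).
#' @inheritParams ci_wlog
#' @return An `icc_ci` object; diagnostics carry the estimated
#'   \eqn{V(\hat\rho)}.
#' @export
ci_wmat <- function(data, alpha = 0.05) {
  sm <- if (inherits(data, "icc_matrix_summaries")) data else matrix_summaries(data)
  n <- sm$n
  k <- sm$k
  A <- sm$one_S_one
  B <- sm$trace_S
  C <- sm$yd_sq
  if (A - B == 0) {
    icc_degenerate_error("1'S1 equals tr(S); the matrix-form estimator is degenerate")
  }
  cc <- n * k - n - k
  rho <- (A - B) / (A / n + cc * B / n + k * C)
  v_rho <- rho^2 * ((1 - rho / n)^2 * 2 * A^2 / (n + 1) +
                      (1 + cc * rho / n)^2 * 2 * sm$trace_S2 / (n + 1) -
                      2 * (1 - rho / n) * (1 + cc * rho / n) * 2 * sm$one_S2_one / (n + 1) +
                      k^2 * rho^2 * 2 * C^2 / (k + 1)) / (A - B)^2
  half <- stats::qt(1 - alpha / 2, n + 1) * sqrt(v_rho)
  new_icc_ci("Wmat", alpha, rho - half, rho + half, list(var_rho = v_rho))
}

#' Modified large-sample interval, Arteaga form (MLSA)
#'
#' Closed-form modified-large-sample limits for the transformed parameter
#' \eqn{k\rho/(n(1-\rho))}, built from \eqn{F_1 = MSS/MSE},
#' \eqn{F_2 = MSR/MSE} and five F quantiles, then mapped back to the
#' \eqn{\rho} scale with `max(0, .)` clamping.  Limits always lie in
#' \[0, 1\].
#'
#' @inheritParams ci_wlog
#' @return An `icc_ci` object.
#' @export
ci_mlsa <- function(ms, alpha = 0.05) {
  ms <- as_ms(ms)
  lim <- mlsa_limits(ms$mss, ms$msr, ms$mse, ms$n, ms$k, alpha)
  new_icc_ci("MLSA", alpha, lim[1, 1], lim[1, 2])
}

#' Modified large-sample interval, Gui form (MLSG)
#'
#' Fieller-type modified-large-sample interval: the agreement ICC is
#' characterized by the sign of a linear combination of expected mean
#' squares, \eqn{W(\lambda) = n(1-\lambda)\theta_1 - \lambda k \theta_2 -
#' (n + \lambda(nk-n-k))\theta_3}; Graybill-Wang one-sided bounds on
#' \eqn{W(\lambda)} (exact in the limiting cases of each variance
#' component) are root-solved in \eqn{\lambda}.  Limits lie in \[0, 1\]
#' and the interval always contains \eqn{\hat\rho}.
#'
#' @inheritParams ci_wlog
#' @return An `icc_ci` object.
#' @export
ci_mlsg <- function(ms, alpha = 0.05) {
  ms <- as_ms(ms)
  lim <- mlsg_limits(ms$mss, ms$msr, ms$mse, ms$n, ms$k, alpha)
  new_icc_ci("MLSG", alpha, lim[1, 1], lim[1, 2])
}

#' Delta-method variance of the ICC estimator (variance partitioning)
#'
#' The two-partition delta approximation
#' \deqn{\hat V(\hat\rho) \approx \frac{\hat\sigma_E^4 \hat V(\hat\sigma_s^2)
#'   + \hat\sigma_s^4 \hat V(\hat\sigma_E^2)
#'   - 2\hat\sigma_s^2\hat\sigma_E^2 \widehat{Cov}(\hat\sigma_s^2,\hat\sigma_E^2)}
#'   {\hat\sigma_T^8},}
#' where \eqn{\hat\sigma_E^2 = \hat\sigma_r^2 + \hat\sigma_e^2} and, with
#' `include_cov = TRUE` (the default, as used by the beta method),
#' \eqn{\hat V(\hat\sigma_E^2)} includes the
#' \eqn{2\widehat{Cov}(\hat\sigma_r^2,\hat\sigma_e^2)} term.
#'
#' @param vc An `icc_variance_components` object.
#' @param include_cov Include covariance terms (TRUE for the beta method;
#'   the F method performs better without them).
#' @return The estimated variance of \eqn{\hat\rho}.
#' @export
var_rho_vp <- function(vc, include_cov = TRUE) {
  if (!inherits(vc, "icc_variance_components")) vc <- variance_components(vc)
  if (vc$sigma2_T <= 0) {
    icc_degenerate_error("total variance is zero; the ICC variance is undefined")
  }
  V <- vc$vcov
  v_E <- V["sigma2_r", "sigma2_r"] + V["sigma2_e", "sigma2_e"]
  cov_sE <- 0
  if (include_cov) {
    v_E <- v_E + 2 * V["sigma2_r", "sigma2_e"]
    cov_sE <- V["sigma2_s", "sigma2_r"] + V["sigma2_s", "sigma2_e"]
  }
  (vc$sigma2_E^2 * V["sigma2_s", "sigma2_s"] +
      vc$sigma2_s^2 * v_E -
      2 * vc$sigma2_s * vc$sigma2_E * cov_sE) / vc$sigma2_T^4
}

#' Variance-partitioning F interval (VPF)
#'
#' Approximates \eqn{\hat\sigma_s^2} and
#' \eqn{\hat\sigma_E^2 = \hat\sigma_r^2 + \hat\sigma_e^2} by independent
#' Satterthwaite chi-squares with estimated degrees of freedom
#' \eqn{\hat{df}_1 = \max(1, 2\hat\sigma_s^4/\hat V(\hat\sigma_s^2))} and
#' \eqn{\hat{df}_2 = 2\hat\sigma_E^4/\hat V(\hat\sigma_E^2)}, so that
#' \eqn{\hat\rho} follows a scaled-F law; the limits are
#' \eqn{\sigma_s^2 F_q/(\sigma_s^2 F_q + \sigma_E^2)} at the two F
#' quantiles.  Covariance terms are excluded from the component variances
#' (the F method performs better without them); set `include_cov = TRUE`
#' to include them.
#'
#' @param vc An `icc_variance_components` object (or anything coercible).
#' @inheritParams ci_wlog
#' @param include_cov Include estimator covariance terms in the
#'   Satterthwaite variances (default FALSE).
#' @return An `icc_ci` object; diagnostics carry the estimated degrees of
#'   freedom and whether the df1 floor at 1 was applied.
#' @export
ci_vpf <- function(vc, alpha = 0.05, include_cov = FALSE) {
  if (!inherits(vc, "icc_variance_components")) vc <- variance_components(vc)
  ms <- vc$ms
  if (vc$sigma2_s <= 0 || vc$sigma2_E <= 0) {
    icc_degenerate_error("VPF requires positive participant and error-partition variance estimates")
  }
  lim <- vpf_limits(ms$mss, ms$msr, ms$mse, ms$n, ms$k, alpha, include_cov)
  df <- attr(lim, "df")
  raw_df1 <- 2 * vc$sigma2_s^2 /
    (vc$vcov["sigma2_s", "sigma2_s"])
  new_icc_ci("VPF", alpha, lim[1, 1], lim[1, 2],
             list(df1 = df[1, 1], df2 = df[1, 2],
                  df1_floored = df[1, 1] == 1 && raw_df1 < 1))
}

#' Moment-matched beta parameters for the ICC estimator
#'
#' Matches a beta(a, b) distribution to the estimated mean and variance of
#' \eqn{\hat\rho}:
#' \eqn{\hat a = \hat\rho[\hat\rho(1-\hat\rho)-\hat V]/\hat V},
#' \eqn{\hat b = (1-\hat\rho)[\hat\rho(1-\hat\rho)-\hat V]/\hat V}.
#' Two corrections are applied as stated by the method: (i) if both raw
#' parameters fall in (0, 1) (a U-shaped beta), the parameter on the far
#' side of \eqn{\hat\rho} is pinned at 1 (J shape); (ii) if the variance
#' exceeds \eqn{\hat\rho(1-\hat\rho)} (nonpositive raw parameters), the
#' pinned-parameter form \eqn{\hat\rho/(1-\hat\rho)} is used.  Ties at
#' \eqn{\hat\rho = 0.5} take the lower branch.
#'
#' @param rho_hat Estimated ICC, strictly inside (0, 1).
#' @param var_rho Estimated variance of the ICC estimator, positive.
#' @return A list with `a`, `b` and `fix_applied` (one of `"none"`,
#'   `"u_shape_low"`, `"u_shape_high"`, `"neg_low"`, `"neg_high"`).
#' @examples
#' fit_beta_params(0.75, 0.01)  # a = 13.3125, b = 4.4375
#' @export
fit_beta_params <- function(rho_hat, var_rho) {
  if (!is.finite(rho_hat) || rho_hat <= 0 || rho_hat >= 1) {
    icc_method_undefined_error("beta approximation requires an ICC estimate strictly inside (0, 1)")
  }
  if (!is.finite(var_rho) || var_rho <= 0) {
    icc_input_error("var_rho must be positive")
  }
  ab <- beta_params_vec(rho_hat, var_rho)
  list(a = unname(ab[1, 1]), b = unname(ab[1, 2]),
       fix_applied = attr(ab, "fix")[1])
}

#' Variance-partitioning beta interval (VPB)
#'
#' Approximates the sampling distribution of \eqn{\hat\rho} by a beta
#' distribution with moment-matched parameters (see [fit_beta_params()]),
#' using the full delta-method variance [var_rho_vp()] including
#' covariance terms; the limits are the \eqn{\alpha/2} and
#' \eqn{1-\alpha/2} beta quantiles.
#'
#' @inheritParams ci_vpf
#' @return An `icc_ci` object; diagnostics carry the fitted beta
#'   parameters and any boundary fix applied.
#' @export
ci_vpb <- function(vc, alpha = 0.05) {
  if (!inherits(vc, "icc_variance_components")) vc <- variance_components(vc)
  rho <- icc_agreement(vc$ms)
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    icc_method_undefined_error("VPB requires an ICC estimate strictly inside (0, 1)")
  }
  bp <- fit_beta_params(rho, var_rho_vp(vc, include_cov = TRUE))
  new_icc_ci("VPB", alpha,
             stats::qbeta(alpha / 2, bp$a, bp$b),
             stats::qbeta(1 - alpha / 2, bp$a, bp$b),
             list(a = bp$a, b = bp$b, fix_applied = bp$fix_applied))
}

#' All confidence intervals for the agreement ICC
#'
#' Convenience wrapper computing any subset of the seven interval methods
#' on one dataset.  Methods that are undefined for the data at hand (for
#' example Wlog when \eqn{\hat\rho \le 0}) are reported with `NA` limits
#' and the error message, without aborting the others.
#'
#' @param data A [ratings_table()] or numeric ratings matrix.
#' @param methods Character vector among
#'   `c("wlog", "wmat", "mlsa", "mlsg", "gci", "vpf", "vpb")`.
#' @param alpha Two-sided error rate.
#' @param gci Optional [gci_config()] for the generalized interval.
#' @return A data frame with one row per method: `method`, `lower`,
#'   `upper`, `width`, `note`.
#' @export
icc_ci <- function(data, methods = c("wlog", "wmat", "mlsa", "mlsg", "gci", "vpf", "vpb"),
                   alpha = 0.05, gci = gci_config()) {
  methods <- match.arg(methods, c("wlog", "wmat", "mlsa", "mlsg", "gci", "vpf", "vpb"),
                       several.ok = TRUE)
  ms <- mean_squares(data)
  vc <- variance_components(ms)
  one <- function(fn) {
    tryCatch({
      ci <- fn()
      data.frame(lower = ci$lower, upper = ci$upper, width = ci$width, note = "")
    }, icc_error = function(e) {
      data.frame(lower = NA_real_, upper = NA_real_, width = NA_real_,
                 note = conditionMessage(e))
    })
  }
  rows <- lapply(methods, function(m) {
    row <- switch(m,
      wlog = one(function() ci_wlog(ms, alpha)),
      wmat = one(function() ci_wmat(data, alpha)),
      mlsa = one(function() ci_mlsa(ms, alpha)),
      mlsg = one(function() ci_mlsg(ms, alpha)),
      gci  = one(function() ci_gci(ms, alpha, gci)),
      vpf  = one(function() ci_vpf(vc, alpha)),
      vpb  = one(function() ci_vpb(vc, alpha)))
    cbind(data.frame(method = toupper(m)), row)
  })
  out <- do.call(rbind, rows)
  attr(out, "rho_hat") <- icc_agreement(ms)
  attr(out, "alpha") <- alpha
  out
}
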