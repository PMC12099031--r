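#' ANOVA mean squares for a balanced two-way design
#'
#' Computes the between-participant, between-rater and residual mean squares
#' of the two-way crossed ANOVA without interaction,
#' \deqn{y_{ij} = \mu + s_i + r_j + e_{ij},}
#' together with their degrees of freedom.  Under normal, homoscedastic
#' random effects the three mean squares are independent scaled chi-square
#' variables with expectations \eqn{k\sigma_s^2+\sigma_e^2},
#' \eqn{n\sigma_r^2+\sigma_e^2} and \eqn{\sigma_e^2}.
#'
#' @param data A [ratings_table()] or numeric matrix (participants x raters).
#' @return An object of class `icc_mean_squares`: a list with `mss`, `msr`,
#'   `mse`, `df_s` (= n-1), `df_r` (= k-1), `df_e` (= (n-1)(k-1)), `n`, `k`.
#' @examples
#' ms <- mean_squares(matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE))
#' ms$mss  # 2
#' @export
mean_squares <- function(data) {
  y <- ratings_values(data)
  n <- nrow(y)
  k <- ncol(y)
  rm_ <- rowMeans(y)
  cm_ <- colMeans(y)
  gm <- mean(y)
  mss <- k * sum((rm_ - gm)^2) / (n - 1)
  msr <- n * sum((cm_ - gm)^2) / (k - 1)
  resid <- sweep(sweep(y, 1L, rm_), 2L, cm_) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  as_mean_squares(mss, msr, mse, n, k)
}

#' Assemble a mean-squares object from its components
#'
#' Useful when the mean squares are available directly (for example from a
#' published ANOVA table) rather than from raw ratings.
#'
#' @param mss,msr,mse Nonnegative mean squares.
#' @param n,k Numbers of participants and raters (both at least 2).
#' @return An `icc_mean_squares` object; see [mean_squares()].
#' @export
as_mean_squares <- function(mss, msr, mse, n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 2L || k < 2L) {
    icc_dimension_error("need n >= 2 and k >= 2")
  }
  if (any(c(mss, msr, mse) < 0) || anyNA(c(mss, msr, mse))) {
    icc_input_error("mean squares must be nonnegative")
  }
  structure(
    list(mss = mss, msr = msr, mse = mse,
         df_s = n - 1L, df_r = k - 1L, df_e = (n - 1L) * (k - 1L),
         n = n, k = k),
    class = "icc_mean_squares")
}

#' @export
print.icc_mean_squares <- function(x, ...) {
  cat("Two-way ANOVA mean squares\n")
  tab <- data.frame(
    source = c("participants", "raters", "error"),
    df = c(x$df_s, x$df_r, x$df_e),
    mean_square = c(x$mss, x$msr, x$mse))
  print(tab, row.names = FALSE)
  invisible(x)
}

as_ms <- function(x) {
  if (inherits(x, "icc_mean_squares")) return(x)
  if (inherits(x, "icc_variance_components")) return(x$ms)
  mean_squares(x)
}

#' Point estimate of the ICC for agreement
#'
#' The ICC for agreement is the proportion of the total variance
#' (participant + rater + error) attributable to participants,
#' \eqn{\rho = \sigma_s^2 / (\sigma_s^2 + \sigma_r^2 + \sigma_e^2)}.
#' Its ANOVA estimator is
#' \deqn{\hat\rho = \frac{MSS - MSE}{MSS + (k-1)MSE + (k/n)(MSR - MSE)}.}
#' The estimate is not clipped to \[0, 1\]; boundary handling is left to the
#' individual confidence-interval methods.
#'
#' @param x A `ratings_table`, ratings matrix, or `icc_mean_squares` object.
#' @return The estimated ICC for agreement (a single number).
#' @export
icc_agreement <- function(x) {
  ms <- as_ms(x)
  den <- ms$mss + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msr - ms$mse)
  if (den <= 0) {
    icc_degenerate_error("all scores are identical; the ICC for agreement is undefined")
  }
  (ms$mss - ms$mse) / den
}

#' Point estimate of the ICC for consistency
#'
#' The ICC for consistency ignores systematic rater shifts:
#' \eqn{\rho_c = \sigma_s^2/(\sigma_s^2+\sigma_e^2)}, estimated by
#' \eqn{(MSS - MSE)/(MSS + (k-1)MSE)}.  It is never smaller than the
#' agreement version when \eqn{MSR \ge MSE}.
#'
#' @inheritParams icc_agreement
#' @return The estimated ICC for consistency.
#' @export
icc_consistency <- function(x) {
  ms <- as_ms(x)
  den <- ms$mss + (ms$k - 1) * ms$mse
  if (den <= 0) {
    icc_degenerate_error("all scores are identical; the ICC for consistency is undefined")
  }
  (ms$mss - ms$mse) / den
}

#' Matrix-form summaries of a ratings table
#'
#' Computes the three quadratic summaries used by the matrix formulation of
#' the agreement ICC estimator: \eqn{1'S1} (sample variance of participant
#' totals), \eqn{\mathrm{tr}\,S} (sum of within-rater sample variances) and
#' \eqn{y_d'y_d} (sum of squared deviations of rater means from the grand
#' mean), where `S` is the k x k sample covariance matrix of the raters'
#' scores.  They satisfy the identities `one_S_one = k * MSS`,
#' `trace_S = MSS + (k-1) * MSE` and `yd_sq = (k-1) * MSR / n`.
#'
#' @param data A [ratings_table()] or numeric matrix.
#' @return A list of class `icc_matrix_summaries` with `one_S_one`,
#'   `trace_S`, `yd_sq`, plus the second-order quantities `one_S2_one`
#'   (\eqn{1'S^2 1}) and `trace_S2` (\eqn{\mathrm{tr}\,S^2}) needed by the
#'   matrix-form delta interval, and `n`, `k`.
#' @export
matrix_summaries <- function(data) {
  y <- ratings_values(data)
  n <- nrow(y)
  k <- ncol(y)
  S <- stats::cov(y)
  yd <- colMeans(y) - mean(y)
  structure(
    list(one_S_one = sum(S),
         trace_S = sum(diag(S)),
         yd_sq = sum(yd^2),
         one_S2_one = sum(S %*% S),
         trace_S2 = sum(S * S),
         n = n, k = k),
    class = "icc_matrix_summaries")
}

#' Method-of-moments variance components and their covariance
#'
#' Inverts the expected mean squares of the balanced two-way model:
#' \eqn{\hat\sigma_e^2 = MSE}, \eqn{\hat\sigma_s^2 = (MSS - MSE)/k},
#' \eqn{\hat\sigma_r^2 = (MSR - MSE)/n}.  Negative participant or rater
#' estimates are truncated at zero (with a recorded flag); the untruncated
#' values are kept for diagnostics and simulation-recovery checks.
#'
#' @param x A `ratings_table`, ratings matrix, or `icc_mean_squares`.
#' @return An object of class `icc_variance_components` with fields
#'   `sigma2_s`, `sigma2_r`, `sigma2_e` (truncated), `sigma2_E`
#'   (= `sigma2_r + sigma2_e`), `sigma2_T`, `rho`, `ratio_R`, `truncated`
#'   (named logical), `untruncated` (named numeric), `vcov` (3 x 3 estimator
#'   covariance), and the originating `ms`.
#' @examples
#' vc <- variance_components(as_mean_squares(7, 4, 1, n = 10, k = 3))
#' vc$sigma2_s  # 2
#' vc$sigma2_r  # 0.3
#' @export
variance_components <- function(x) {
  ms <- as_ms(x)
  n <- ms$n
  k <- ms$k
  s2e <- ms$mse
  s2s_raw <- (ms$mss - ms$mse) / k
  s2r_raw <- (ms$msr - ms$mse) / n
  s2s <- max(0, s2s_raw)
  s2r <- max(0, s2r_raw)
  s2E <- s2r + s2e
  s2T <- s2s + s2E
  structure(
    list(sigma2_s = s2s, sigma2_r = s2r, sigma2_e = s2e,
         sigma2_E = s2E, sigma2_T = s2T,
         rho = if (s2T > 0) s2s / s2T else NA_real_,
         ratio_R = if (s2e > 0) s2r / s2e else NA_real_,
         truncated = c(sigma2_s = s2s_raw < 0, sigma2_r = s2r_raw < 0),
         untruncated = c(sigma2_s = s2s_raw, sigma2_r = s2r_raw, sigma2_e = s2e),
         vcov = vcov_from_ms(ms$mss, ms$msr, ms$mse, n, k),
         ms = ms),
    class = "icc_variance_components")
}

#' @export
print.icc_variance_components <- function(x, ...) {
  cat("Variance components (two-way random-effects ANOVA)\n")
  comp <- c(participant = x$sigma2_s, rater = x$sigma2_r, error = x$sigma2_e)
  print(round(comp, 6))
  cat(sprintf("ICC for agreement: %.4f   rater-to-error ratio R: %.4f\n",
              x$rho, x$ratio_R))
  if (any(x$truncated)) {
    cat("note: negative moment estimate(s) truncated at zero:",
        paste(names(x$truncated)[x$truncated], collapse = ", "), "\n")
  }
  invisible(x)
}

# Covariance of the moment estimators, plugging in the observed mean squares
# for the expected mean squares (equivalent to the untruncated component
# plug-in, and always nonnegative).
vcov_from_ms <- function(mss, msr, mse, n, k) {
  v_mss <- 2 * mss^2 / (n - 1)
  v_msr <- 2 * msr^2 / (k - 1)
  v_mse <- 2 * mse^2 / ((n - 1) * (k - 1))
  build_vcov(v_mss, v_msr, v_mse, n, k)
}

build_vcov <- function(v_mss, v_msr, v_mse, n, k) {
  V <- matrix(0, 3L, 3L,
              dimnames = list(c("sigma2_s", "sigma2_r", "sigma2_e"),
                              c("sigma2_s", "sigma2_r", "sigma2_e")))
  V["sigma2_s", "sigma2_s"] <- (v_mss + v_mse) / k^2
  V["sigma2_r", "sigma2_r"] <- (v_msr + v_mse) / n^2
  V["sigma2_e", "sigma2_e"] <- v_mse
  V["sigma2_s", "sigma2_r"] <- V["sigma2_r", "sigma2_s"] <- v_mse / (n * k)
  V["sigma2_s", "sigma2_e"] <- V["sigma2_e", "sigma2_s"] <- -v_mse / k
  V["sigma2_r", "sigma2_e"] <- V["sigma2_e", "sigma2_r"] <- -v_mse / n
  V
}

#' Covariance matrix of the variance-component estimators
#'
#' Returns the exact sampling variance-covariance of the moment estimators
#' \eqn{(\hat\sigma_s^2, \hat\sigma_r^2, \hat\sigma_e^2)} for the balanced
#' two-way random model, derived from the independent scaled chi-square
#' distributions of the three mean squares (for this balanced design it
#' coincides with the inverse Fisher information).  All covariances among
#' the three estimators arise through the shared MSE.
#'
#' @param vc An `icc_variance_components` object, or a numeric vector of
#'   length 3 giving \eqn{(\sigma_s^2, \sigma_r^2, \sigma_e^2)} (for example
#'   the true values when computing a theoretical covariance).
#' @param n,k Numbers of participants and raters.
#' @return A symmetric 3 x 3 matrix with dimnames
#'   `c("sigma2_s","sigma2_r","sigma2_e")`.
#' @export
vcov_variance_components <- function(vc, n, k) {
  if (inherits(vc, "icc_variance_components")) {
    comp <- c(vc$sigma2_s, vc$sigma2_r, vc$sigma2_e)
    n <- vc$ms$n
    k <- vc$ms$k
  } else {
    comp <- as.numeric(vc)
  }
  if (length(comp) != 3L || any(comp < 0)) {
    icc_input_error("variance components must be three nonnegative numbers")
  }
  if (all(comp == 0)) {
    icc_degenerate_error("all variance components are zero; the information matrix is singular")
  }
  t1 <- k * comp[1] + comp[3]
  t2 <- n * comp[2] + comp[3]
  t3 <- comp[3]
  build_vcov(2 * t1^2 / (n - 1), 2 * t2^2 / (k - 1),
             2 * t3^2 / ((n - 1) * (k - 1)), n, k)
}
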