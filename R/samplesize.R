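# Chi-square CDF via the closed-form series (even df) or the half-integer
# recurrence from the normal CDF (odd df).  Equivalent to pchisq() but much
# faster on the large matrices used by the quantile solver below.
chisq_cdf_fast <- function(x, df) {
  df <- as.integer(df)
  # beyond ~5000 the CDF is 1 to machine precision for the df used here;
  # clamping also keeps the series finite for enormous arguments
  x <- pmin(x, 5000)
  if (df %% 2L == 0L) {
    m <- df %/% 2L
    term <- rep(1, length(x))
    s <- term
    if (m > 1L) {
      for (j in seq_len(m - 1L)) {
        term <- term * (x / 2) / j
        s <- s + term
      }
    }
    1 - exp(-x / 2) * s
  } else {
    p <- 2 * stats::pnorm(sqrt(x)) - 1
    if (df > 1L) {
      term <- sqrt(2 * x / pi) * exp(-x / 2)
      nu <- 1L
      while (nu < df) {
        p <- p - term
        nu <- nu + 2L
        term <- term * x / nu
      }
    }
    p
  }
}

new_width_estimate <- function(mean_width, mc_sd, mc_draws, n_undefined = 0L,
                               diagnostics = list()) {
  structure(
    list(mean_width = mean_width, mc_sd = mc_sd,
         se = mc_sd / sqrt(mc_draws), mc_draws = mc_draws,
         n_undefined = n_undefined, diagnostics = diagnostics),
    class = "icc_width_estimate")
}

#' @export
print.icc_width_estimate <- function(x, ...) {
  cat(sprintf("Expected CI width: %.4f (MC se %.5f, %d draws)\n",
              x$mean_width, x$se, x$mc_draws))
  invisible(x)
}

derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

# sigma_s^2 implied by the planned ICC and ratio, with sigma_e^2 = 1
plan_sigma2_s <- function(rho, R) rho * (R + 1) / (1 - rho)

#' Expected confidence-interval width by plain Monte Carlo
#'
#' Estimates the expected two-sided confidence-interval width at a planned
#' ICC `rho` and rater-to-error ratio `R`, averaging the width of the
#' chosen closed-form interval over `M` simulated replicates of the study.
#' With `route = "moments"` (default) the mean squares are drawn from
#' their exact scaled chi-square sampling law, which is distributionally
#' identical to simulating full ratings tables and much faster; with
#' `route = "datasets"` full tables are simulated via
#' [simulate_dataset()].  Replicates where the interval is undefined are
#' excluded and counted.
#'
#' @param method One of `"vpf"`, `"mlsg"`, `"mlsa"` (closed-form per
#'   replicate; for the generalized interval use [gci_width_rb()]).
#' @param rho Planned ICC in (0, 1).
#' @param R Planned rater-to-error variance ratio.
#' @param n,k Numbers of participants and raters.
#' @param alpha Two-sided error rate.
#' @param M Number of Monte Carlo replicates (at least 1000).
#' @param route `"moments"` or `"datasets"` (see above).
#' @param seed Optional seed; fixing it yields common random numbers
#'   across calls (used by the bisection search).
#' @return An `icc_width_estimate` with `mean_width`, `mc_sd` (sd of the
#'   individual widths), `se`, `mc_draws`, `n_undefined`.
#' @export
expected_width_mc <- function(method, rho, R, n, k, alpha = 0.05, M = 1e4,
                              route = c("moments", "datasets"), seed = NULL) {
  method <- match.arg(tolower(method), c("vpf", "mlsg", "mlsa"))
  route <- match.arg(route)
  if (M < 1000) icc_input_error("M must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (route == "moments") {
    t1 <- k * plan_sigma2_s(rho, R) + 1
    t2 <- n * R + 1
    nu1 <- n - 1L
    nu2 <- k - 1L
    nu3 <- nu1 * nu2
    # explicit inversion from uniforms so a fixed seed couples draws across n
    mss <- t1 * stats::qchisq(stats::runif(M), nu1) / nu1
    msr <- t2 * stats::qchisq(stats::runif(M), nu2) / nu2
    mse <- stats::qchisq(stats::runif(M), nu3) / nu3
  } else {
    cfg <- simulation_config(n, k, rho, R, reps = M)
    mss <- msr <- mse <- numeric(M)
    for (i in seq_len(M)) {
      msi <- mean_squares(simulate_dataset(cfg))
      mss[i] <- msi$mss; msr[i] <- msi$msr; mse[i] <- msi$mse
    }
  }
  lim <- switch(method,
                vpf = vpf_limits(mss, msr, mse, n, k, alpha),
                mlsg = mlsg_limits(mss, msr, mse, n, k, alpha),
                mlsa = mlsa_limits(mss, msr, mse, n, k, alpha))
  w <- lim[, 2] - lim[, 1]
  ok <- is.finite(w)
  new_width_estimate(mean(w[ok]), stats::sd(w[ok]), sum(ok), sum(!ok))
}

#' Moments of the control variate MSR/MSS
#'
#' Under the model \eqn{MSR/MSS = (\tau_2/\tau_1) F_{k-1,n-1}} exactly,
#' with \eqn{\tau_1 = k\sigma_s^2+\sigma_e^2},
#' \eqn{\tau_2 = n\sigma_r^2+\sigma_e^2}, giving
#' \deqn{E = \frac{\tau_2}{\tau_1}\frac{n-1}{n-3}, \qquad
#'   Var = \left(\frac{\tau_2}{\tau_1}\right)^2
#'   \frac{2(n-1)^2(n+k-4)}{(k-1)(n-3)^2(n-5)}.}
#' These are the known moments used by the control-variate adjustment of
#' the generalized-interval width estimator.
#'
#' @inheritParams expected_width_mc
#' @return A list with `mean` and `variance`.
#' @export
ratio_moments <- function(rho, R, n, k) {
  if (n <= 5) icc_domain_error("the variance of MSR/MSS requires n > 5")
  ratio <- (n * R + 1) / (k * plan_sigma2_s(rho, R) + 1)
  list(mean = ratio * (n - 1) / (n - 3),
       variance = ratio^2 * 2 * (n - 1)^2 * (n + k - 4) /
         ((k - 1) * (n - 3)^2 * (n - 5)))
}

#' Expected MLSA width by dependent conditioning
#'
#' Variance-reduced estimator of the expected MLSA interval width.  The
#' limits depend on the data only through \eqn{F_1 = MSS/MSE} and
#' \eqn{F_2 = MSR/MSE}, i.e. through
#' \eqn{X_{SE} = (MSS/(k\sigma_s^2+\sigma_e^2))/(MSE/\sigma_e^2) \sim
#' F_{n-1,(n-1)(k-1)}} and the dependent ratio \eqn{X_{RE}}.  The
#' estimator draws \eqn{x_{SE}} from its F marginal and then the
#' remaining randomness from its exact conditional law (the shared
#' error chi-square given \eqn{x_{SE}} is Gamma-distributed), averaging
#' the conditional expected limits numerically with `inner_draws` draws
#' per outer draw.
#'
#' @inheritParams expected_width_mc
#' @param M Number of outer draws of \eqn{x_{SE}}.
#' @param inner_draws Conditional draws of the remaining randomness per
#'   outer draw (1 already gives an unbiased estimator; larger values
#'   reduce the Monte Carlo variance further).
#' @return An `icc_width_estimate`.
#' @export
mlsa_width_estimator <- function(rho, R, n, k, alpha = 0.05, M = 1e5,
                                 inner_draws = 1L, seed = NULL) {
  if (M < 1000) icc_input_error("M must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  nu1 <- n - 1
  nu2 <- k - 1
  nu3 <- nu1 * nu2
  t1 <- k * plan_sigma2_s(rho, R) + 1
  t2 <- n * R + 1
  B <- as.integer(inner_draws)
  x_se <- stats::qf(stats::runif(M), nu1, nu3)
  # shared error chi-square given x_SE is Gamma((nu1+nu3)/2, (1+x nu1/nu3)/2)
  u_w <- matrix(stats::runif(M * B), M, B)
  u_v <- matrix(stats::runif(M * B), M, B)
  W <- stats::qgamma(u_w, shape = (nu1 + nu3) / 2, rate = (1 + x_se * nu1 / nu3) / 2)
  V <- stats::qchisq(u_v, nu2)
  x_re <- V * nu3 / (nu2 * W)
  F1 <- x_se * t1
  F2 <- x_re * t2
  lim <- mlsa_limits_f(rep(F1, B), as.vector(F2), n, k, alpha)
  w <- matrix(lim[, 2] - lim[, 1], M, B)
  wm <- rowMeans(w)  # E[U - L | x_SE], estimated
  new_width_estimate(mean(wm), stats::sd(wm), M)
}

#' Expected GCI width by inverse Rao-Blackwellization and control variates
#'
#' Variance-reduced estimator of the expected width of the generalized
#' confidence interval.  For each of `M` simulated studies (mean squares
#' drawn from their exact sampling law) the pivot quantiles are estimated
#' by inverse Rao-Blackwellization: with `inner_draws` Monte Carlo pairs
#' of the participant and error chi-squares, the conditional probability
#' over the remaining rater chi-square is available in closed form (the
#' rater term of the pivot is a scaled inverse-Gamma), and the quantile
#' is the smallest pivot value whose averaged conditional CDF reaches the
#' target level.  A control-variate adjustment then exploits the
#' approximately linear relationship between the limits and MSR/MSS
#' (whose exact moments are [ratio_moments()]; the linearity is an
#' approximation recommended for planned ICC above 0.7).
#'
#' @inheritParams expected_width_mc
#' @param M Number of simulated studies (outer draws).
#' @param inner_draws Monte Carlo pairs per quantile evaluation (default
#'   `min(M, 2000)`; cost scales with `M * inner_draws`).
#' @param use_control_variate Apply the MSR/MSS control-variate
#'   adjustment (requires n > 5).
#' @return An `icc_width_estimate`; diagnostics carry the control-variate
#'   coefficients and the unadjusted width.
#' @export
gci_width_rb <- function(rho, R, n, k, alpha = 0.05, M = 1e3,
                         inner_draws = min(M, 1000L),
                         use_control_variate = TRUE, seed = NULL) {
  if (M < 100) icc_input_error("M must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  nu1 <- n - 1
  nu2 <- k - 1
  nu3 <- nu1 * nu2
  t1 <- k * plan_sigma2_s(rho, R) + 1
  t2 <- n * R + 1
  mss <- t1 * stats::qchisq(stats::runif(M), nu1) / nu1
  msr <- t2 * stats::qchisq(stats::runif(M), nu2) / nu2
  mse <- stats::qchisq(stats::runif(M), nu3) / nu3
  x1 <- stats::qchisq(stats::runif(inner_draws), nu1)
  x3 <- stats::qchisq(stats::runif(inner_draws), nu3)
  A <- outer(nu1 * mss / k, 1 / x1)          # M x inner
  Bm <- outer(nu3 * mse / k, 1 / x3)
  num <- pmax(0, A - Bm)
  E <- A + Bm * (n * k - n - k) / n
  cc <- (k - 1) * msr / n                    # fixed per study
  solve_q <- function(q, hi) {
    lo <- rep(0, M)
    for (it in 1:13) {
      mid <- (lo + hi) / 2
      thr <- num / mid - E                   # recycles mid down each column
      H <- rowMeans(chisq_cdf_fast(cc / pmax(thr, 1e-300), nu2))
      up <- H < q
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    (lo + hi) / 2
  }
  U <- solve_q(1 - alpha / 2, rep(1, M))
  L <- solve_q(alpha / 2, U)
  diag_ <- list(raw_mean_width = mean(U - L), control_variate = FALSE)
  if (use_control_variate && n > 5) {
    rm_ <- ratio_moments(rho, R, n, k)
    ratio <- msr / mss
    beta_u <- stats::cov(U, ratio) / rm_$variance
    beta_l <- stats::cov(L, ratio) / rm_$variance
    U <- U - beta_u * (ratio - rm_$mean)
    L <- L - beta_l * (ratio - rm_$mean)
    diag_ <- list(raw_mean_width = diag_$raw_mean_width, control_variate = TRUE,
                  beta_upper = beta_u, beta_lower = beta_l)
  }
  v <- U - L
  new_width_estimate(mean(v), stats::sd(v), M, diagnostics = diag_)
}

#' Large-n limiting expected confidence-interval width
#'
#' Evaluates the expected width of a method along an increasing schedule
#' of n and checks stabilization; because the rater mean square keeps
#' only k - 1 degrees of freedom however large n grows, the limiting
#' width is positive whenever R > 0, and it bounds from below the width
#' achievable by any sample size.  Comparing it with a target width
#' before running a sample-size search tells whether the target is
#' feasible at all for the given rho, R and k.
#'
#' @param method One of `"mlsa"`, `"gci"`, `"vpf"`, `"mlsg"`.
#' @inheritParams expected_width_mc
#' @param n_schedule Increasing n values to evaluate (common random
#'   numbers across the schedule).
#' @param M Monte Carlo draws per evaluation (defaults per method:
#'   1e5 for MLSA, 2000 for GCI, 1e4 otherwise).
#' @param tol Required stabilization of the last two evaluations (beyond
#'   their Monte Carlo error).
#' @return The limiting width (last schedule value), with the full
#'   schedule in `attr(, "schedule")`.
#' @export
asymptotic_width <- function(method, rho, R, k, alpha = 0.05,
                             n_schedule = c(1e3, 1e4, 1e5), M = NULL,
                             seed = NULL, tol = 0.005) {
  method <- match.arg(tolower(method), c("mlsa", "gci", "vpf", "mlsg"))
  if (is.null(M)) {
    M <- switch(method, mlsa = 1e5, gci = 2000, 1e4)
  }
  n_schedule <- sort(as.integer(n_schedule))
  est <- lapply(seq_along(n_schedule), function(i) {
    n <- n_schedule[i]
    if (method == "mlsa") {
      mlsa_width_estimator(rho, R, n, k, alpha, M = M, seed = seed)
    } else if (method == "gci") {
      gci_width_rb(rho, R, n, k, alpha, M = M, seed = seed)
    } else {
      expected_width_mc(method, rho, R, n, k, alpha, M = M, seed = seed)
    }
  })
  w <- vapply(est, `[[`, numeric(1), "mean_width")
  se <- vapply(est, `[[`, numeric(1), "se")
  m <- length(w)
  if (m >= 2) {
    gap <- abs(w[m] - w[m - 1])
    if (gap > tol + 3 * sqrt(se[m]^2 + se[m - 1]^2)) {
      icc_error(sprintf(
        "expected width has not stabilized along the n schedule (last change %.4f)", gap),
        "icc_instability_error")
    }
  }
  structure(w[m], schedule = stats::setNames(w, n_schedule), se = se[m])
}

#' Specification of a sample-size search
#'
#' Bundles and validates the inputs of the two sample-size procedures.
#' Defaults follow the procedure conventions: the purely simulation-based
#' search (`"doros_lew"`, for VPF / MLSG / MLSA) uses 1e4 width
#' simulations and caps n at 500; the variance-reduced procedure
#' (`"dobbin_ionan"`, for MLSA / GCI) uses 1e5 draws for MLSA, 1e3 for
#' GCI, caps n at 1e7, and is meant to be repeated (default 100 times)
#' with the mean of the returned sizes as the planning value.
#'
#' @param method CI method: `"vpf"`, `"mlsg"`, `"mlsa"` or `"gci"`.
#' @param rho,ratio_R Planned ICC and rater-to-error variance ratio.
#' @param omega Target expected width, in (0, 1).
#' @param k Fixed number of raters (when searching n).
#' @param n Fixed number of participants (when searching k).
#' @param procedure `"doros_lew"` or `"dobbin_ionan"` (default chosen by
#'   method).
#' @param alpha Two-sided error rate.
#' @param mc_draws Monte Carlo draws per width evaluation (default by
#'   procedure/method, see above).
#' @param repeats Number of independent repetitions of the whole search.
#' @param n_max Search cap (500 for doros_lew, 1e7 for dobbin_ionan).
#' @param n_min Smallest admissible size (default 6, so that all degrees
#'   of freedom and the control-variate moments exist).
#' @param seed Optional master seed.
#' @return A list of class `icc_samplesize_request`.
#' @export
sample_size_request <- function(method, rho, ratio_R, omega,
                                k = NULL, n = NULL, procedure = NULL,
                                alpha = 0.05, mc_draws = NULL, repeats = NULL,
                                n_max = NULL, n_min = 6L, seed = NULL) {
  method <- match.arg(tolower(method), c("vpf", "mlsg", "mlsa", "gci"))
  if (is.null(procedure)) {
    procedure <- if (method %in% c("vpf", "mlsg")) "doros_lew" else "dobbin_ionan"
  }
  procedure <- match.arg(tolower(procedure), c("doros_lew", "dobbin_ionan"))
  if (procedure == "dobbin_ionan" && !method %in% c("mlsa", "gci")) {
    icc_input_error("the dobbin_ionan procedure supports only the MLSA and GCI methods")
  }
  if (procedure == "doros_lew" && method == "gci") {
    icc_input_error("the purely simulation-based search with GCI is impractical; use procedure = 'dobbin_ionan'")
  }
  if (omega <= 0 || omega >= 1) icc_input_error("omega must be in (0, 1)")
  if (rho <= 0 || rho >= 1) icc_input_error("rho must be in (0, 1)")
  if (is.null(k) && is.null(n)) icc_input_error("fix either k (search n) or n (search k)")
  if (is.null(mc_draws)) {
    mc_draws <- if (procedure == "doros_lew") 1e4
    else if (method == "mlsa") 1e5 else 1e3
  }
  if (is.null(repeats)) repeats <- if (procedure == "doros_lew") 1L else 100L
  if (is.null(n_max)) n_max <- if (procedure == "doros_lew") 500L else 1e7
  structure(
    list(method = method, procedure = procedure, rho = rho, ratio_R = ratio_R,
         omega = omega, k = k, n = n,
         fixed_dim = if (is.null(n)) "k" else "n",
         alpha = alpha, mc_draws = as.integer(mc_draws),
         repeats = as.integer(repeats), n_max = as.integer(n_max),
         n_min = as.integer(n_min), seed = seed),
    class = "icc_samplesize_request")
}

# Minimal size search: doubling bracket from n_min, then integer bisection.
# width_fn(n) must use common random numbers so the empirical width is
# (near-)monotone in n.  Returns the minimal n with width < omega, with the
# evaluated widths memoized for the minimality record.
search_min_n <- function(width_fn, omega, n_min, n_max) {
  memo <- new.env(parent = emptyenv())
  wf <- function(n) {
    key <- as.character(n)
    if (is.null(memo[[key]])) memo[[key]] <- width_fn(n)
    memo[[key]]
  }
  if (wf(n_min) < omega) {
    return(list(n_star = n_min, feasible_in_range = TRUE,
                width_at = wf(n_min), width_below = NA_real_, memo = memo))
  }
  lo <- n_min
  hi <- n_min
  repeat {
    hi <- min(n_max, hi * 2L)
    if (wf(hi) < omega) break
    lo <- hi
    if (hi >= n_max) {
      return(list(n_star = NA_integer_, feasible_in_range = FALSE,
                  width_at = wf(n_max), width_below = NA_real_, memo = memo))
    }
  }
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    if (wf(mid) < omega) hi <- mid else lo <- mid
  }
  list(n_star = hi, feasible_in_range = TRUE,
       width_at = wf(hi), width_below = wf(lo), memo = memo)
}

new_sample_size_result <- function(request, per_repeat, feasible, asym_width,
                                   width_at = NA_real_, width_below = NA_real_) {
  ok <- per_repeat[!is.na(per_repeat)]
  structure(
    list(request = request,
         n_star = if (length(ok)) as.integer(round(mean(ok))) else NA_integer_,
         per_repeat_values = per_repeat,
         repeat_mean = if (length(ok)) mean(ok) else NA_real_,
         repeat_sd = if (length(ok) > 1) stats::sd(ok) else if (length(ok) == 1) 0 else NA_real_,
         feasible = feasible,
         asymptotic_width = asym_width,
         width_at_n_star = width_at,
         width_below_n_star = width_below),
    class = "icc_sample_size")
}

#' @export
print.icc_sample_size <- function(x, ...) {
  rq <- x$request
  what <- if (rq$fixed_dim == "k") "participants n" else "raters k"
  cat(sprintf("Sample-size search (%s, %s): target width %.3f at rho = %.2f, R = %.2f\n",
              toupper(rq$method), rq$procedure, rq$omega, rq$rho, rq$ratio_R))
  if (!x$feasible) {
    cat(sprintf("INFEASIBLE: asymptotic width %.3f is not below omega = %.3f\n",
                x$asymptotic_width, rq$omega))
  } else {
    cat(sprintf("minimal %s: mean %.1f (sd %.2f) over %d repetition(s)\n",
                what, x$repeat_mean, x$repeat_sd, length(x$per_repeat_values)))
  }
  invisible(x)
}

# width evaluator for one (method, repeat) at fixed k, as a function of n
repeat_width_fn <- function(request, seed_r) {
  rq <- request
  switch(rq$method,
    vpf = ,
    mlsg = ,
    mlsa = if (rq$procedure == "doros_lew") {
      function(n) expected_width_mc(rq$method, rq$rho, rq$ratio_R, n, rq$k,
                                    rq$alpha, M = rq$mc_draws,
                                    seed = seed_r)$mean_width
    } else {
      function(n) mlsa_width_estimator(rq$rho, rq$ratio_R, n, rq$k, rq$alpha,
                                       M = rq$mc_draws, seed = seed_r)$mean_width
    },
    gci = function(n) gci_width_rb(rq$rho, rq$ratio_R, n, rq$k, rq$alpha,
                                   M = rq$mc_draws, seed = seed_r)$mean_width)
}

# width evaluator as a function of k at fixed n
repeat_width_fn_k <- function(request, seed_r) {
  rq <- request
  switch(rq$method,
    vpf = ,
    mlsg = ,
    mlsa = if (rq$procedure == "doros_lew") {
      function(k) expected_width_mc(rq$method, rq$rho, rq$ratio_R, rq$n, k,
                                    rq$alpha, M = rq$mc_draws,
                                    seed = seed_r)$mean_width
    } else {
      function(k) mlsa_width_estimator(rq$rho, rq$ratio_R, rq$n, k, rq$alpha,
                                       M = rq$mc_draws, seed = seed_r)$mean_width
    },
    gci = function(k) gci_width_rb(rq$rho, rq$ratio_R, rq$n, k, rq$alpha,
                                   M = rq$mc_draws, seed = seed_r)$mean_width)
}

run_size_search <- function(request, check_feasibility = TRUE) {
  rq <- request
  asym <- NA_real_
  feasible <- TRUE
  if (check_feasibility && rq$fixed_dim == "k") {
    asym <- tryCatch(
      as.numeric(asymptotic_width(rq$method, rq$rho, rq$ratio_R, rq$k, rq$alpha,
                                  seed = derive_seed(rq$seed, 0L))),
      icc_error = function(e) NA_real_)
    if (!is.na(asym) && asym >= rq$omega) {
      return(new_sample_size_result(rq, rep(NA_integer_, rq$repeats),
                                    feasible = FALSE, asym_width = asym))
    }
  }
  per <- integer(rq$repeats)
  width_at <- width_below <- NA_real_
  for (r in seq_len(rq$repeats)) {
    seed_r <- derive_seed(rq$seed, r)
    wf <- if (rq$fixed_dim == "k") repeat_width_fn(rq, seed_r)
          else repeat_width_fn_k(rq, seed_r)
    lo_dim <- if (rq$fixed_dim == "k") rq$n_min else max(2L, rq$n_min)
    res <- search_min_n(wf, rq$omega, lo_dim, rq$n_max)
    per[r] <- res$n_star
    if (r == 1L) {
      width_at <- res$width_at
      width_below <- res$width_below
    }
    if (!res$feasible_in_range) {
      feasible <- FALSE
      per[r] <- NA_integer_
    }
  }
  new_sample_size_result(rq, per, feasible = feasible, asym_width = asym,
                         width_at = width_at, width_below = width_below)
}

#' Minimal sample size by the purely simulation-based procedure
#'
#' Bisection search for the minimal number of participants (or raters)
#' whose expected confidence-interval width falls below `omega`, with the
#' width of the chosen closed-form interval (VPF, MLSG or MLSA) estimated
#' by plain Monte Carlo at every candidate size.  Common random numbers
#' are used across candidates within a repeat so the empirical width is
#' monotone and the bisection well defined; by construction the returned
#' size passes the width criterion and the next smaller size fails it.
#' Feasibility is pre-checked against the large-n limiting width.
#'
#' @param request An [sample_size_request()] with
#'   `procedure = "doros_lew"`.
#' @param check_feasibility Evaluate [asymptotic_width()] first and return
#'   an infeasible result when `omega` is unattainable.
#' @return An object of class `icc_sample_size` with the per-repeat sizes,
#'   their mean and sd, the feasibility flag, the asymptotic width, and
#'   the widths at the returned size and one below it.
#' @export
find_n_bisection <- function(request, check_feasibility = TRUE) {
  if (!inherits(request, "icc_samplesize_request")) {
    icc_input_error("request must be built with sample_size_request()")
  }
  run_size_search(request, check_feasibility)
}

#' Minimal sample size by the variance-reduced procedure
#'
#' Sample-size search driven by the variance-reduced width estimators:
#' [mlsa_width_estimator()] (dependent conditioning) for MLSA or
#' [gci_width_rb()] (inverse Rao-Blackwellization with control variates)
#' for GCI.  The bisection runs over the whole `(n_min, n_max)` range in
#' a single pass; the search is repeated `repeats` times with fresh
#' random streams and the per-repeat minima are summarized by their mean
#' and standard deviation — the recommended planning value is the mean.
#' Feasibility is pre-checked with the asymptotic width.
#'
#' @inheritParams find_n_bisection
#' @return An `icc_sample_size`; see [find_n_bisection()].
#' @export
sample_size_dobbin_ionan <- function(request, check_feasibility = TRUE) {
  if (!inherits(request, "icc_samplesize_request")) {
    icc_input_error("request must be built with sample_size_request()")
  }
  if (request$procedure != "dobbin_ionan") {
    icc_input_error("request$procedure must be 'dobbin_ionan'")
  }
  run_size_search(request, check_feasibility)
}
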