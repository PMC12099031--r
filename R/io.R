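#' Read a ratings table from CSV
#'
#' Two layouts are supported.  `"wide"`: header row, first column the
#' participant id, remaining columns one per rater.  `"long"`: columns
#' `participant`, `rater`, `value` (by name if present, else the first
#' three columns in that order).  The design must be complete: exactly
#' one numeric value for every (participant, rater) pair; duplicates and
#' missing cells are rejected with the offending pairs listed.
#'
#' @param path Path to a CSV file with a header.
#' @param layout `"wide"` or `"long"`.
#' @return A [ratings_table()].
#' @export
read_ratings <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 3L) icc_input_error("wide layout needs an id column plus at least two rater columns")
    vals <- df[, -1L, drop = FALSE]
    bad <- which(!vapply(vals, is.numeric, logical(1)))
    if (length(bad)) {
      icc_input_error(paste0("non-numeric rater column(s): ",
                             paste(names(vals)[bad], collapse = ", ")))
    }
    if (anyNA(vals)) {
      idx <- which(is.na(as.matrix(vals)), arr.ind = TRUE)
      pairs <- paste0("(", df[[1L]][idx[, 1]], ", ", names(vals)[idx[, 2]], ")")
      icc_input_error(paste0(
        "incomplete design (the methods require every rater to score every participant); missing cells: ",
        paste(utils::head(pairs, 10L), collapse = " ")))
    }
    return(ratings_table(as.matrix(vals),
                         participant_ids = as.character(df[[1L]]),
                         rater_ids = names(vals)))
  }
  nm <- tolower(names(df))
  pick <- function(target, fallback) {
    i <- match(target, nm)
    if (is.na(i)) fallback else i
  }
  p <- as.character(df[[pick("participant", 1L)]])
  r <- as.character(df[[pick("rater", 2L)]])
  v <- df[[pick("value", 3L)]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))
    icc_input_error(paste0("non-numeric value(s) in long layout at row(s): ",
                           paste(utils::head(bad, 10L), collapse = ", ")))
  }
  tab <- table(p, r)
  if (any(tab > 1L)) {
    idx <- which(tab > 1L, arr.ind = TRUE)
    pairs <- paste0("(", rownames(tab)[idx[, 1]], ", ", colnames(tab)[idx[, 2]], ")")
    icc_input_error(paste0("duplicate (participant, rater) cells: ",
                           paste(utils::head(pairs, 10L), collapse = " ")))
  }
  if (any(tab < 1L)) {
    idx <- which(tab < 1L, arr.ind = TRUE)
    pairs <- paste0("(", rownames(tab)[idx[, 1]], ", ", colnames(tab)[idx[, 2]], ")")
    icc_input_error(paste0(
      "incomplete design (the methods require every rater to score every participant); missing cells: ",
      paste(utils::head(pairs, 10L), collapse = " ")))
  }
  pid <- unique(p)
  rid <- unique(r)
  m <- matrix(NA_real_, length(pid), length(rid), dimnames = list(pid, rid))
  m[cbind(match(p, pid), match(r, rid))] <- v
  ratings_table(m, participant_ids = pid, rater_ids = rid)
}

report_header <- function(seed, params) {
  list(package = "iccagree",
       version = as.character(utils::packageVersion("iccagree")),
       seed = if (is.null(seed)) NA else seed,
       parameters = params)
}

write_report_json <- function(report, path) {
  if (is.null(path)) return(invisible(NULL))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Estimate the ICC and all requested confidence intervals for a dataset
#'
#' One-stop analysis of a ratings file (or in-memory table): point
#' estimates of the agreement and consistency ICCs, the rater-to-error
#' ratio and the variance components, plus the requested confidence
#' intervals.  Methods undefined for the data at hand are reported with a
#' note instead of aborting the rest.
#'
#' @param input Path to a CSV file, or a [ratings_table()] / matrix.
#' @param layout CSV layout for file input (see [read_ratings()]).
#' @param methods,alpha See [icc_ci()].
#' @param seed Seed for the generalized interval's pivot draws.
#' @param gci_draws Pivot draws for the generalized interval.
#' @param output_path Optional path for a JSON report.
#' @return The report list, invisibly; a formatted table is printed.
#' @export
run_ci <- function(input, layout = "wide",
                   methods = c("wlog", "wmat", "mlsa", "mlsg", "gci", "vpf", "vpb"),
                   alpha = 0.05, seed = NULL, gci_draws = 1e5,
                   output_path = NULL) {
  data <- if (is.character(input)) read_ratings(input, layout) else
    ratings_table(ratings_values(input))
  ms <- mean_squares(data)
  vc <- variance_components(ms)
  tab <- icc_ci(data, methods, alpha,
                gci = gci_config(mc_draws = gci_draws, rng_seed = seed))
  report <- c(
    report_header(seed, list(alpha = alpha, n = ms$n, k = ms$k,
                             gci_draws = gci_draws)),
    list(estimates = list(
           icc_agreement = icc_agreement(ms),
           icc_consistency = icc_consistency(ms),
           ratio_R = vc$ratio_R,
           sigma2_s = vc$sigma2_s, sigma2_r = vc$sigma2_r,
           sigma2_e = vc$sigma2_e),
         intervals = tab))
  write_report_json(report, output_path)
  cat(sprintf("n = %d participants, k = %d raters\n", ms$n, ms$k))
  cat(sprintf("ICC for agreement: %.3f   ICC for consistency: %.3f   R: %.3f\n",
              report$estimates$icc_agreement,
              report$estimates$icc_consistency, vc$ratio_R))
  cat(sprintf("%d%% confidence intervals:\n", round(100 * (1 - alpha))))
  fmt <- tab
  fmt$lower <- sprintf("%.3f", fmt$lower)
  fmt$upper <- sprintf("%.3f", fmt$upper)
  fmt$width <- sprintf("%.3f", fmt$width)
  print(fmt, row.names = FALSE)
  invisible(report)
}

#' Recommended interval method and sample-size procedure
#'
#' Encodes the planning guidance combining coverage and width results:
#' with few raters (k < 8) and a small rater-to-error ratio (R <= 0.1)
#' the F interval with the purely simulation-based search is preferred
#' (narrowest intervals with nominal coverage); in every other case the
#' generalized interval with the variance-reduced procedure is the robust
#' choice, with MLSG an equivalent interval alternative.
#'
#' @param k Planned number of raters.
#' @param R Planned rater-to-error variance ratio.
#' @return List with `ci_method`, `alternatives`, `procedure`, `note`.
#' @export
recommend_design <- function(k, R) {
  if (R <= 0.1 && k < 8) {
    list(ci_method = "vpf", alternatives = character(),
         procedure = "doros_lew",
         note = "small rater-to-error ratio and few raters: purely simulation-based procedure (VPF)")
  } else if (R <= 0.1) {
    list(ci_method = "gci", alternatives = "mlsg",
         procedure = "dobbin_ionan",
         note = "many raters: procedure according to Dobbin and Ionan (GCI); MLSG is an equivalent interval choice")
  } else {
    list(ci_method = "gci", alternatives = c("mlsg", if (R >= 2) "mlsa"),
         procedure = "dobbin_ionan",
         note = "rater-to-error ratio above 0.1: procedure according to Dobbin and Ionan (GCI)")
  }
}

#' Run a sample-size determination and report it
#'
#' Wraps [find_n_bisection()] / [sample_size_dobbin_ionan()] with a
#' recommendation banner and an optional JSON report.  Infeasible targets
#' are reported together with the asymptotic width and the advice to
#' check it before proceeding.
#'
#' @param method,rho,ratio_R,omega,k,n,procedure,alpha,mc_draws,repeats,n_max,seed
#'   See [sample_size_request()].
#' @param output_path Optional path for a JSON report.
#' @return The report list, invisibly.
#' @export
run_samplesize <- function(method, rho, ratio_R, omega, k = NULL, n = NULL,
                           procedure = NULL, alpha = 0.05, mc_draws = NULL,
                           repeats = NULL, n_max = NULL, seed = NULL,
                           output_path = NULL) {
  rq <- sample_size_request(method, rho, ratio_R, omega, k = k, n = n,
                            procedure = procedure, alpha = alpha,
                            mc_draws = mc_draws, repeats = repeats,
                            n_max = n_max, seed = seed)
  rec <- recommend_design(if (is.null(k)) 8 else k, ratio_R)
  cat(sprintf("recommended design for k = %s, R = %.2f: %s with the %s procedure (%s)\n",
              if (is.null(k)) "(searched)" else k, ratio_R,
              toupper(rec$ci_method), rec$procedure, rec$note))
  res <- if (rq$procedure == "doros_lew") find_n_bisection(rq)
         else sample_size_dobbin_ionan(rq)
  print(res)
  if (!res$feasible) {
    cat("advice: check the asymptotic width for your rho, R and k before proceeding;",
        "the requested width cannot be reached at any sample size.\n")
  }
  report <- c(
    report_header(seed, rq[c("method", "procedure", "rho", "ratio_R", "omega",
                             "k", "n", "alpha", "mc_draws", "repeats", "n_max")]),
    list(recommendation = rec,
         n_star = res$n_star,
         feasible = res$feasible,
         asymptotic_width = res$asymptotic_width,
         per_repeat_values = res$per_repeat_values,
         repeat_mean = res$repeat_mean,
         repeat_sd = res$repeat_sd))
  write_report_json(report, output_path)
  invisible(report)
}

#' Run a coverage/width evaluation over a parameter grid
#'
#' Evaluates the requested interval methods at every row of a parameter
#' grid and writes a tidy table (one row per grid point and method) with
#' coverage, average width, replicates used and error rate.
#'
#' @param grid Data frame with columns `n`, `k`, `rho`, `R`.
#' @param reps Replications per grid point.
#' @param methods Methods to evaluate (see [icc_ci()]).
#' @param alpha Two-sided error rate.
#' @param gci_draws Pivot draws per replicate for the generalized interval.
#' @param seed Master seed (one substream per grid point).
#' @param output_path Optional path for a tidy TSV.
#' @return The tidy results data frame, invisibly.
#' @export
run_coverage <- function(grid, reps = 1e4,
                         methods = c("wlog", "mlsa", "mlsg", "gci", "vpf", "vpb"),
                         alpha = 0.05, gci_draws = 1e4, seed = NULL,
                         output_path = NULL) {
  need <- c("n", "k", "rho", "R")
  if (!all(need %in% names(grid))) {
    icc_input_error("grid must have columns n, k, rho, R")
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simulation_config(grid$n[i], grid$k[i], grid$rho[i], grid$R[i],
                             reps = reps, seed = derive_seed(seed, i),
                             alpha = alpha, gci_draws = gci_draws)
    cbind(grid[i, need, drop = FALSE],
          evaluate_methods(cfg, methods),
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$reps <- reps
  if (!is.null(output_path)) {
    utils::write.table(out, output_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Report the asymptotic (large-n) expected width
#'
#' @param method,rho,ratio_R,k,alpha,seed See [asymptotic_width()].
#' @param output_path Optional path for a JSON report.
#' @return The report list, invisibly.
#' @export
run_asymwidth <- function(method, rho, ratio_R, k, alpha = 0.05, seed = NULL,
                          output_path = NULL) {
  w <- asymptotic_width(method, rho, ratio_R, k, alpha, seed = seed)
  cat(sprintf("asymptotic %d%% %s width at rho = %.2f, R = %.2f, k = %d: %.3f\n",
              round(100 * (1 - alpha)), toupper(method), rho, ratio_R, k,
              as.numeric(w)))
  report <- c(report_header(seed, list(method = method, rho = rho,
                                       ratio_R = ratio_R, k = k, alpha = alpha)),
              list(asymptotic_width = as.numeric(w),
                   schedule = as.list(attr(w, "schedule"))))
  write_report_json(report, output_path)
  invisible(report)
}
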