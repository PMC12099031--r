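#' Ratings table for a balanced two-way reliability design
#'
#' Container for the complete n x k table of quantitative scores arising
#' when each of n participants is rated once by the same k raters.  The
#' two-way random-effects ANOVA model behind every method in this package
#' assumes this design is balanced and complete: exactly one numeric score
#' per (participant, rater) cell and no missing values.
#'
#' @param values Numeric matrix (or object coercible to one) with one row
#'   per participant and one column per rater.
#' @param participant_ids Optional character vector of participant labels
#'   (defaults to row names or `P1..Pn`).
#' @param rater_ids Optional character vector of rater labels (defaults to
#'   column names or `R1..Rk`).
#'
#' @return An object of class `ratings_table` with elements `values`,
#'   `participant_ids` and `rater_ids`.
#' @examples
#' rt <- ratings_table(matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE))
#' mean_squares(rt)
#' @export
ratings_table <- function(values, participant_ids = NULL, rater_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    icc_input_error("ratings must be numeric")
  }
  if (anyNA(values)) {
    icc_input_error("ratings table contains missing values; the methods require a complete balanced design")
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) {
    icc_dimension_error(sprintf(
      "need at least 2 participants and 2 raters (got n = %d, k = %d)", n, k))
  }
  if (is.null(participant_ids)) {
    participant_ids <- rownames(values)
    if (is.null(participant_ids)) participant_ids <- paste0("P", seq_len(n))
  }
  if (is.null(rater_ids)) {
    rater_ids <- colnames(values)
    if (is.null(rater_ids)) rater_ids <- paste0("R", seq_len(k))
  }
  if (length(participant_ids) != n || length(rater_ids) != k) {
    icc_input_error("id lengths do not match the dimensions of the ratings matrix")
  }
  dimnames(values) <- list(participant_ids, rater_ids)
  structure(
    list(values = values,
         participant_ids = as.character(participant_ids),
         rater_ids = as.character(rater_ids)),
    class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("Ratings table: %d participants x %d raters\n",
              nrow(x$values), ncol(x$values)))
  utils::str(x$values, give.attr = FALSE)
  invisible(x)
}

# Coerce ratings_table / matrix / data.frame input to a validated matrix.
ratings_values <- function(data) {
  if (inherits(data, "ratings_table")) {
    return(data$values)
  }
  ratings_table(data)$values
}
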