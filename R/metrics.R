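# Evaluation measures: MRE/MMRE, Pearson and Spearman correlation, and the
# determination coefficient of a cubic curve fit.

#' Mean magnitude of relative error (percent)
#'
#' `100 * mean(|actual - predicted| / actual)`.  The search objective and
#' headline accuracy measure, always computed on the decoded percent scale.
#' Actuals must be strictly positive: a zero denominator is an error, never
#' silently patched.
#'
#' @param actual Positive numeric vector (actual percentages).
#' @param predicted Numeric vector of the same length.
#' @return MMRE in percent (a single non-negative number).
#' @examples
#' mmre(c(10, 20), c(9, 22))   # mean of 10% and 10% -> 10
#' @export
mmre <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1L)
    stop("actual and predicted must have equal positive length",
         call. = FALSE)
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("zero or negative actual value: relative error undefined",
         call. = FALSE)
  100 * mean(abs(actual - predicted) / actual)
}

#' Magnitude of relative error per observation
#'
#' @inheritParams mmre
#' @return Vector of `|actual - predicted| / actual` (fractions, not
#'   percent).
#' @export
mre <- function(actual, predicted) {
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("zero or negative actual value: relative error undefined",
         call. = FALSE)
  abs(actual - predicted) / actual
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need vectors of equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
}

#' Pearson and Spearman correlation
#'
#' Thin wrappers over [stats::cor()] with the input checks the evaluation
#' report requires (length >= 3, non-constant input; Spearman uses average
#' ranks for ties).
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson
#' @export
spearman <- function(x, y) {
  check_corr_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Determination coefficient of a cubic curve fit
#'
#' Ordinary least-squares fit of `predicted` on
#' `1, actual, actual^2, actual^3` (the standard "cubic" curve estimation),
#' returning `R^2 = 1 - SS_res / SS_tot`.  Because the cubic span contains
#' the linear span, this is never below the squared Pearson correlation of
#' the same data.
#'
#' @param actual Numeric vector with at least 5 observations and at least 4
#'   distinct values.
#' @param predicted Numeric vector of the same length.
#' @return `R^2` in `[0, 1]`.
#' @export
r2_cubic <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 5L)
    stop("need at least 5 paired observations", call. = FALSE)
  if (length(unique(actual)) < 4L)
    stop("rank-deficient cubic design: need >= 4 distinct actual values",
         call. = FALSE)
  fit <- stats::lm(predicted ~ stats::poly(actual, 3, raw = TRUE))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  if (ss_tot == 0) return(0)
  max(0, 1 - ss_res / ss_tot)
}

#' Evaluation report row
#'
#' Bundles the Tables 6/7-style measures for one model and phase.
#'
#' @param model Model identifier (e.g. `"ANN-L36-Fuzzy"`).
#' @param phase `"training"` or `"testing"`.
#' @param year Year panel label.
#' @param actual,predicted Percent-scale vectors.
#' @return One-row data frame with `model`, `phase`, `year`, `mmre`,
#'   `pearson`, `spearman`, `r2_cubic`.
#' @export
evaluation_report <- function(model, phase, year, actual, predicted) {
  data.frame(model = model, phase = phase, year = year,
             mmre = mmre(actual, predicted),
             pearson = pearson(actual, predicted),
             spearman = spearman(actual, predicted),
             r2_cubic = if (length(actual) >= 5L &&
                            length(unique(actual)) >= 4L)
               r2_cubic(actual, predicted) else NA_real_,
             stringsAsFactors = FALSE)
}
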