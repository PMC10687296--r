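# Closed-form 2x2 contingency statistics: odds ratio with Woolf (log-normal)
# confidence interval and the pooled two-proportion z test.

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' `OR = ad / bc` with the log-normal interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided Wald
#' p-value.  Zero cells are an error; apply the Haldane--Anscombe 0.5
#' correction explicitly via `correct = TRUE` if that is intended.
#'
#' @param a,b,c,d Cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases.
#' @param conf_level Confidence level (default 0.95).
#' @param correct Add 0.5 to every cell (Haldane--Anscombe) before
#'   computing; default `FALSE`.
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `conf_level`.
#' @examples
#' odds_ratio(20, 10, 10, 20)   # OR 4, CI ~ (1.37, 11.7)
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95, correct = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  if (correct) cells <- cells + 0.5
  if (any(cells == 0))
    stop("zero cell in 2x2 table; pass correct = TRUE to apply the 0.5 ",
         "continuity correction explicitly", call. = FALSE)
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald <- log(or) / se
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       p_value = unname(2 * stats::pnorm(-abs(wald))),
       conf_level = conf_level)
}

#' Pooled two-proportion z test
#'
#' Tests equality of two binomial proportions with the pooled standard
#' error; two-sided p-value.  Equivalent to the chi-squared test without
#' continuity correction (`z^2` equals the test statistic of
#' `prop.test(correct = FALSE)`).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p_value`, and the two sample proportions.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("require 0 <= x <= n with n > 0 in both groups", call. = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    stop("degenerate pooled proportion (0 or 1)", call. = FALSE)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}
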