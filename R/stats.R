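#' Mean, SD and coefficient of variation of a condition
#'
#' Summary used for both MEP amplitudes (mV) and per-stimulus times (s):
#' sample mean, sample standard deviation (\eqn{n-1} denominator), and
#' their ratio, the coefficient of variation CV = SD / mean.
#'
#' @param values Numeric sample, at least two values, nonzero mean.
#' @return A list of class \code{"condition_summary"} with \code{mean},
#'   \code{sd}, \code{cv}, \code{n}.
#' @export
#' @examples
#' summarize_condition(c(1, 2, 3))   # mean 2, sd 1, cv 0.5
summarize_condition <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least two values are required", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values", call. = FALSE)
  m <- mean(values)
  if (m == 0)
    stop("zero mean: coefficient of variation undefined", call. = FALSE)
  s <- stats::sd(values)
  structure(list(mean = m, sd = s, cv = s / m, n = length(values)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> n = %d, mean = %.4g, SD = %.4g, CV = %.4g\n",
              x$n, x$mean, x$sd, x$cv))
  invisible(x)
}

#' Mean band coherence of a per-stimulus series
#'
#' @param values Non-empty numeric vector of Coh(beta) values.
#' @return Arithmetic mean.
#' @export
mean_coh <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("empty coherence series", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values", call. = FALSE)
  mean(values)
}

#' Two-sided variance-ratio (F) test
#'
#' Compares the variances of two samples by their ratio
#' \eqn{F = s_a^2 / s_b^2} against the F distribution with
#' \eqn{(n_a - 1, n_b - 1)} degrees of freedom. The two-sided p-value is
#' \eqn{p = \min(1,\; 2 \min(P(F \le f),\, P(F \ge f)))}.
#'
#' @param a,b Numeric samples, each of size at least 2 and with nonzero
#'   variance.
#' @param alpha Significance level for the \code{significant} flag.
#' @return A list of class \code{"variance_test_result"}:
#'   \code{f_statistic}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{significant}, \code{alpha}.
#' @export
#' @examples
#' set.seed(1)
#' variance_ratio_test(rnorm(30, sd = 2), rnorm(30, sd = 1))
variance_ratio_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least two values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0)
    stop("zero variance in a sample: the variance ratio is degenerate",
         call. = FALSE)
  f <- va / vb
  df1 <- length(a) - 1L
  df2 <- length(b) - 1L
  p <- min(1, 2 * min(stats::pf(f, df1, df2),
                      stats::pf(f, df1, df2, lower.tail = FALSE)))
  structure(list(f_statistic = f, df1 = df1, df2 = df2, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "variance_test_result")
}

#' @export
print.variance_test_result <- function(x, ...) {
  cat(sprintf(
    "<variance_test_result> F(%d, %d) = %.4g, two-sided p = %.4g (%ssignificant at alpha = %g)\n",
    x$df1, x$df2, x$f_statistic, x$p_value,
    if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Count strict CV reductions across paired conditions
#'
#' Given per-participant coefficients of variation under the
#' coherence-triggered and control conditions, counts the participants
#' whose triggered CV is strictly below their control CV.
#'
#' @param triggered,control Equal-length numeric vectors of CVs.
#' @return Integer count.
#' @export
count_cv_reductions <- function(triggered, control) {
  stopifnot(is.numeric(triggered), is.numeric(control))
  if (length(triggered) != length(control) || length(triggered) == 0L)
    stop("triggered and control must be non-empty and of equal length",
         call. = FALSE)
  sum(triggered < control)
}
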