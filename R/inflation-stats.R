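# Genomic inflation factors, observed alpha, Q-Q coordinates, and moments of
# scan test-statistic distributions.
#
# The inflation factor lambda for a scan is the median squared test statistic
# divided by the median of the chi-square distribution with 1 df. Two
# denominator conventions are supported: the exact chi-square median
# qchisq(0.5, 1) = 0.4549364, and the conventional rounded value 0.455 used
# in published lambda arithmetic.

lambda_denominator <- function(denominator = c("exact", "printed")) {
  switch(match.arg(denominator),
         exact = stats::qchisq(0.5, df = 1),
         printed = 0.455)
}

#' Genomic inflation factor from t statistics
#'
#' `lambda = median(t^2) / median(chi-square_1)`. An even-length median is
#' the mean of the two central order statistics (the [stats::median()]
#' convention).
#'
#' @param t_values numeric vector of t statistics from one scan.
#' @param denominator `"exact"` (chi-square_1 median, default) or
#'   `"printed"` (0.455).
#' @return a single non-negative number.
#' @export
#' @examples
#' lambda_from_tstats(c(-0.6745, 0.6745), denominator = "printed")
lambda_from_tstats <- function(t_values, denominator = c("exact", "printed")) {
  t_values <- t_values[is.finite(t_values)]
  if (length(t_values) == 0)
    stop_lambdascan("input", "no finite t statistics supplied")
  stats::median(t_values^2) / lambda_denominator(denominator)
}

#' Genomic inflation factor from P-values
#'
#' Maps each P-value to the chi-square 1-df deviate with that upper-tail
#' probability, then divides the median deviate by the chosen denominator.
#' This is how lambda is put on a common 1-df scale for multi-df F tests.
#'
#' @param p_values numeric vector of P-values in (0, 1]. Zeros are capped at
#'   1e-300 with a warning.
#' @inheritParams lambda_from_tstats
#' @return a single non-negative number.
#' @export
lambda_from_pvalues <- function(p_values, denominator = c("exact", "printed")) {
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) == 0)
    stop_lambdascan("input", "no finite P-values supplied")
  if (any(p_values < 0 | p_values > 1))
    stop_lambdascan("input", "P-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("P-values of 0 capped at 1e-300 before chi-square mapping")
    p_values[p_values == 0] <- 1e-300
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / lambda_denominator(denominator)
}

#' Observed alpha: empirical rejection fraction
#'
#' Fraction of P-values strictly below `level`. The strict inequality is a
#' documented convention; P-values exactly at the level do not count as
#' rejections.
#'
#' @param p_values numeric vector of P-values.
#' @param level nominal significance level (default 0.05).
#' @return proportion in \[0, 1\].
#' @export
observed_alpha <- function(p_values, level = 0.05) {
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) == 0) stop_lambdascan("input", "no P-values supplied")
  mean(p_values < level)
}

#' Q-Q plot coordinates on the -log10 scale
#'
#' Observed coordinates are the sorted `-log10(P)`; expected coordinates use
#' the `(i - 0.5)/m` quantile convention for rank `i` counted from the
#' largest P-value.
#'
#' @param p_values numeric vector of P-values in (0, 1].
#' @return a `qq_series` data frame with non-decreasing columns
#'   `expected_neglog10` and `observed_neglog10`.
#' @export
qq_coordinates <- function(p_values) {
  p_values <- p_values[is.finite(p_values)]
  m <- length(p_values)
  if (m == 0) stop_lambdascan("input", "no P-values supplied")
  out <- data.frame(
    expected_neglog10 = -log10(((m:1) - 0.5) / m),
    observed_neglog10 = sort(-log10(p_values))
  )
  class(out) <- c("qq_series", "data.frame")
  out
}

#' Moments of a scan's test-statistic distribution
#'
#' Sample mean (a noncentrality proxy), variance, skewness and excess
#' kurtosis of the t statistics from one scan. A constant vector yields
#' variance 0 with skewness/kurtosis flagged undefined.
#'
#' @param t_values numeric vector, length >= 4.
#' @return list with `mean`, `variance`, `skewness`, `excess_kurtosis`, and
#'   logical `degenerate`.
#' @export
stat_moments <- function(t_values) {
  t_values <- t_values[is.finite(t_values)]
  m <- length(t_values)
  if (m < 4) stop_lambdascan("input", "need at least 4 finite statistics")
  mu <- mean(t_values)
  v <- stats::var(t_values)
  if (v == 0)
    return(list(mean = mu, variance = 0, skewness = NA_real_,
                excess_kurtosis = NA_real_, degenerate = TRUE))
  d <- t_values - mu
  list(mean = mu,
       variance = v,
       skewness = mean(d^3) / (mean(d^2))^1.5,
       excess_kurtosis = mean(d^4) / (mean(d^2))^2 - 3,
       degenerate = FALSE)
}
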