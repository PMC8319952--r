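# Evaluation statistics: MSE, R-squared, delta, Pearson r, paired t-test.

#' Mean squared error
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 1L) stop("need at least one observation")
  mean((actual - predicted)^2)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, the proportion of variance in `actual`
#' explained by `predicted`.  Undefined when `actual` is constant.
#'
#' @param actual,predicted Equal-length numeric vectors, length >= 2.
#' @return R-squared (<= 1; can be negative for predictions worse than the
#'   mean).
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2L) stop("need at least two observations")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("undefined R-squared: 'actual' is constant")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Per-plan absolute prediction error (delta)
#'
#' `delta = |actual - predicted|` per plan, the quality-assurance statistic
#' for predicted D2cm3/Dprescription ratios, with its mean and sample
#' standard deviation.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return List with `delta` (vector), `mean`, `sd` (sample sd; `NA` for a
#'   single observation).
#' @export
delta_stat <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  d <- abs(actual - predicted)
  list(delta = d, mean = mean(d), sd = stats::sd(d))
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation coefficient with the usual two-sided p-value from the
#' t-transform on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least three observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = a - b`,
#' with the two-sided p-value on `n - 1` degrees of freedom.  When all
#' differences are exactly zero the statistic is reported as `t = 0, p = 1`;
#' identical nonzero differences (zero variance, nonzero mean) are an error.
#'
#' @param a,b Equal-length numeric vectors, length >= 2.
#' @return List with `t`, `p`, `df`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2L) stop("need at least two pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L))
    stop("zero-variance nonzero differences: t statistic is unbounded")
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
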