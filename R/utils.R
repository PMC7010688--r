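#' @importFrom stats rnorm rbinom rnbinom rbeta runif plogis pchisq p.adjust
#'   cor cor.test prcomp optimize lm loess predict fisher.test sd var
#'   complete.cases model.matrix kmeans smooth.spline quantile setNames
#'   rlnorm aggregate median ks.test
#' @importFrom utils head read.table write.table
NULL

# Numeric day from labels like "day0".."day3"; errors on anything else.
day_to_numeric <- function(day) {
  out <- suppressWarnings(as.numeric(sub("^day", "", as.character(day))))
  if (anyNA(out)) {
    bad <- unique(as.character(day)[is.na(out)])
    stop("unknown day label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Gaussian likelihood-ratio statistic for nested least-squares fits
#'
#' With the residual variance profiled out, the deviance difference between
#' two nested Gaussian linear models is `n * log(RSS0 / RSS1)`.
#'
#' @param rss0,rss1 residual sums of squares of the null and full model.
#' @param n number of observations.
#' @param df degrees of freedom of the test.
#' @return list with `stat` and `p` (chi-square upper tail).
#' @keywords internal
lrt_gaussian <- function(rss0, rss1, n, df) {
  rss1 <- max(rss1, .Machine$double.eps)
  stat <- max(0, n * (log(rss0) - log(rss1)))
  list(stat = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}

# Residual sum of squares of y on design X (with intercept included by
# caller). Returns list(rss, coef).
ols_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

# z-score a vector; constant input maps to zeros.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Row-wise z-scoring of a matrix, constant rows to zero.
zscore_rows <- function(m) {
  t(apply(m, 1L, zscore))
}
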