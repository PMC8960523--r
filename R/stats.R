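#' Median and range of a sample
#'
#' Midpoint convention for even n (the mean of the two central order
#' statistics), as used throughout cohort dosimetry reports.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, min, max)`.
#' @export
median_range <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    stop("median_range: empty or non-finite input")
  }
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Two-tailed Wilcoxon-Mann-Whitney test
#'
#' Rank-sum test for two independent samples. The U statistic is computed
#' from midrank-tied rank sums. Two p-value methods are provided:
#'
#' * `normal_cc` (default): normal approximation with continuity
#'   correction, `z = (|U - n1*n2/2| - 0.5) / sigma_U`, where `sigma_U^2 =
#'   n1*n2/12 * ((N+1) - sum(t^3 - t)/(N*(N-1)))` includes the standard tie
#'   correction. This is the method used by common spreadsheet and legacy
#'   clinical analyses.
#' * `exact_enumeration`: enumerates all `choose(n1+n2, n1)` assignments of
#'   the pooled midranks and reports the exact two-sided tail probability
#'   `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`. Limited to `n1 + n2 <= 20`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param method `"normal_cc"` or `"exact_enumeration"`.
#' @return Object of class `test_result`: `statistic` (U of sample `x`),
#'   `p_value`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), method = "exact_enumeration")$p_value # 1/3
mann_whitney <- function(x, y, method = c("normal_cc", "exact_enumeration")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("mann_whitney: empty sample")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  if (any(!is.finite(pooled))) stop("mann_whitney: non-finite values")
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- if (method == "normal_cc") {
    nn <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      1
    } else {
      z <- max(abs(u - mu) - 0.5, 0) / sqrt(sigma2)
      min(1, 2 * stats::pnorm(-z))
    }
  } else {
    if (n1 + n2 > 20) {
      stop("mann_whitney: exact_enumeration limited to n1 + n2 <= 20")
    }
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
  }
  structure(
    list(statistic = u, p_value = p, method = method, n1 = n1, n2 = n2),
    class = "test_result"
  )
}

#' Paired Wilcoxon signed-rank test (non-default alternative)
#'
#' Exposed for sensitivity analyses of delivered-versus-expected dose
#' comparisons; the package default treats the two dose sets as independent
#' samples ([mann_whitney()]).
#'
#' @param x,y Paired numeric samples of equal length.
#' @return A `test_result` with the signed-rank statistic V.
#' @export
signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("signed_rank: unequal lengths")
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "signed_rank_normal_cc", n1 = length(x), n2 = length(y)),
    class = "test_result"
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of the midranks of the two margins (equal
#' to `1 - 6*sum(d^2)/(n*(n^2-1))` when there are no ties). The two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length, n >= 3.
#' @return A `test_result` with `statistic` = rho, plus field `n`.
#' @export
#' @examples
#' spearman(1:5, c(2, 4, 6, 8, 10))$statistic # 1
spearman <- function(a, b) {
  if (length(a) != length(b)) stop("spearman: unequal lengths")
  n <- length(a)
  if (n < 3) stop("spearman: need at least 3 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("spearman: non-finite values")
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("spearman: constant input (zero rank variance)")
  }
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(statistic = rho, p_value = p, method = "t_approx", n = n,
         n1 = n, n2 = n),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}
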