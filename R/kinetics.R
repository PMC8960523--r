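#' Fit a mono-exponential clearance model to the late phase of a series
#'
#' The effective half-life of a structure is obtained by ordinary least
#' squares of `log(rate)` on time over the samples at or after
#' `window_start_h` (default 24 h, i.e. the 24/48/72 h scans of the nominal
#' schedule; the 4 h uptake-phase sample is excluded). The slope must be
#' negative; `t_eff_h = log(2) / lambda` with `lambda = -slope`.
#'
#' The fit is unweighted and performed on the natural-log scale, so it is
#' exact on noiseless mono-exponential data and interpolates any two-point
#' window exactly.
#'
#' @param series A [dose_rate_series()] or a data.frame with columns
#'   `time_h` and `rate_gy_per_h`.
#' @param window_start_h Start of the fit window in hours (default 24).
#' @return Object of class `monoexp_fit` with fields `rate_lambda` (1/h),
#'   `t_eff_h`, `log_amplitude` (log of the extrapolated rate at t = 0),
#'   `fit_window_start_h`, `n_points`, and `r_squared_log`.
#' @export
#' @examples
#' s <- data.frame(time_h = c(24, 48, 72), rate_gy_per_h = c(1, 0.5, 0.25))
#' fit <- fit_monoexponential(s)
#' fit$t_eff_h  # 24: the rate halves every 24 h
fit_monoexponential <- function(series, window_start_h = 24) {
  samples <- if (inherits(series, "dose_rate_series")) series$samples else
    as.data.frame(series)
  t <- samples$time_h
  r <- samples$rate_gy_per_h
  keep <- which(t >= window_start_h)
  if (length(keep) < 2) {
    stop("fit_monoexponential: insufficient points (need >= 2 samples at or after ",
         window_start_h, " h, got ", length(keep), ")")
  }
  if (any(r[keep] <= 0)) {
    stop("fit_monoexponential: non-positive rate in fit window")
  }
  x <- t[keep]
  y <- log(r[keep])
  # closed-form OLS; cheap enough to call tens of thousands of times in
  # simulation studies
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  if (slope >= 0) {
    stop("fit_monoexponential: non-decaying series (slope >= 0 in fit window)")
  }
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  lambda <- -slope
  structure(
    list(
      rate_lambda = lambda,
      t_eff_h = log(2) / lambda,
      log_amplitude = intercept,
      fit_window_start_h = window_start_h,
      n_points = length(keep),
      r_squared_log = r2
    ),
    class = "monoexp_fit"
  )
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> t_eff = %.3g h (lambda = %.4g /h), %d points from %g h, R2(log) = %.4f\n",
    x$t_eff_h, x$rate_lambda, x$n_points, x$fit_window_start_h, x$r_squared_log
  ))
  invisible(x)
}

#' Predict the dose rate of a fitted clearance model
#'
#' @param fit A `monoexp_fit`.
#' @param time_h Time in hours post injection (>= 0); vectorised.
#' @return Predicted absorbed dose rate(s), Gy/h; strictly positive and
#'   strictly decreasing in time.
#' @export
predict_rate <- function(fit, time_h) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (any(time_h < 0)) stop("predict_rate: negative time")
  exp(fit$log_amplitude - fit$rate_lambda * time_h)
}
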