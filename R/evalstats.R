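#' Regress actual values on estimates
#'
#' Ordinary least squares with the actual value as the dependent variable,
#' as used to judge the fit between true and recovered shunt.  With perfect
#' agreement the slope, intercept and R^2 are 1, 0 and 1.
#'
#' @param actual numeric vector of true values.
#' @param estimate numeric vector of recovered values.
#' @param level confidence level for the slope CI.
#' @return An object of class `regression_report` with `slope`, `intercept`,
#'   `r_squared`, `ci` (slope CI), `p_value` and `n`.
#' @export
#' @examples
#' regress_actual_on_estimate(1:10, 1:10)
regress_actual_on_estimate <- function(actual, estimate, level = 0.95) {
  stopifnot(length(actual) == length(estimate), length(actual) >= 3)
  if (var(estimate) == 0) stop("estimate vector has zero variance")
  fit <- lm(actual ~ estimate)
  sm <- summary(fit)
  ci <- confint(fit, "estimate", level = level)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 ci = c(ci[1], ci[2]),
                 p_value = sm$coefficients["estimate", "Pr(>|t|)"],
                 n = length(actual), fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Actual-on-estimate regression (n = %d)\n", x$n))
  cat(sprintf("  slope %+0.3f (95%% CI %+0.3f, %+0.3f), intercept %+0.3f, R^2 %.3f, p %.3g\n",
              x$slope, x$ci[1], x$ci[2], x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Summarize estimation errors
#'
#' Statistics of the per-record deviation between actual and estimated
#' values.  The default sign convention is `actual - estimate`, so a positive
#' mean indicates systematic underestimation; set `convention =
#' "estimate-actual"` to flip.
#'
#' @param actual,estimate numeric vectors of equal length (>= 3).
#' @param convention `"actual-estimate"` (default) or `"estimate-actual"`.
#' @return An object of class `error_summary` with mean, SD, median, IQR,
#'   range, skewness and the Shapiro-Wilk normality p-value.
#' @export
error_summary <- function(actual, estimate,
                          convention = c("actual-estimate", "estimate-actual")) {
  stopifnot(length(actual) == length(estimate), length(actual) >= 3)
  convention <- match.arg(convention)
  err <- if (convention == "actual-estimate") actual - estimate else estimate - actual
  sw <- if (sd(err) > 0 && length(err) >= 3 && length(err) <= 5000)
    shapiro.test(err)$p.value else NA_real_
  structure(list(mean = mean(err), sd = sd(err), median = median(err),
                 iqr = unname(quantile(err, c(0.25, 0.75))),
                 range = range(err),
                 skewness = e1071::skewness(err, type = 2),
                 shapiro_p = sw,
                 convention = convention, n = length(err), errors = err),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Error summary (%s, n = %d)\n", x$convention, x$n))
  cat(sprintf("  mean %+0.3f (SD %.3f), median %+0.3f (IQR %+0.3f, %+0.3f)\n",
              x$mean, x$sd, x$median, x$iqr[1], x$iqr[2]))
  cat(sprintf("  range %+0.3f to %+0.3f, skewness %+0.2f, Shapiro-Wilk p %.3g\n",
              x$range[1], x$range[2], x$skewness, x$shapiro_p))
  invisible(x)
}

#' Kernel density overlay of actual and estimated values
#'
#' Gaussian-kernel density estimates of the two samples on a shared grid
#' (Silverman bandwidth by default), as used to compare the distribution of
#' recovered values with the truth.
#'
#' @param actual,estimate numeric vectors (n >= 2).
#' @param bw bandwidth, or `"nrd0"` for Silverman's rule.
#' @param n grid size.
#' @return Data frame with `x`, `density_actual`, `density_estimate`.
#' @export
kde_overlay <- function(actual, estimate, bw = "nrd0", n = 512) {
  stopifnot(length(actual) >= 2, length(estimate) >= 2)
  lo <- min(actual, estimate); hi <- max(actual, estimate)
  pad <- 3 * max(stats::bw.nrd0(actual), stats::bw.nrd0(estimate))
  da <- density(actual, bw = bw, n = n, from = lo - pad, to = hi + pad)
  de <- density(estimate, bw = if (identical(bw, "nrd0")) stats::bw.nrd0(estimate) else bw,
                n = n, from = lo - pad, to = hi + pad)
  data.frame(x = da$x, density_actual = da$y, density_estimate = de$y)
}
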