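#' Hazard-ratio estimate
#'
#' A hazard ratio with its 95% confidence interval and the standard error of
#' \eqn{\ln HR}. If `log_se` is not supplied it is derived from the interval
#' assuming normality on the log scale,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`; an explicit `log_se`
#' overrides the interval-derived value.
#'
#' @param hr Positive point estimate.
#' @param ci_low,ci_high Positive 95% CI bounds (optional if `log_se` given).
#' @param log_se Standard error of `log(hr)` (optional).
#' @return An object of class `hr_estimate`.
#' @export
hr_estimate <- function(hr, ci_low = NULL, ci_high = NULL, log_se = NULL) {
  stopifnot(is.numeric(hr), length(hr) == 1L, is.finite(hr))
  if (hr <= 0) stop("hr_estimate: `hr` must be > 0", call. = FALSE)
  if (is.null(log_se)) {
    if (is.null(ci_low) || is.null(ci_high))
      stop("hr_estimate: supply either a CI or `log_se`", call. = FALSE)
    if (ci_low <= 0 || ci_high <= 0 || ci_low > ci_high)
      stop("hr_estimate: require 0 < ci_low <= ci_high", call. = FALSE)
    log_se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  }
  if (log_se < 0) stop("hr_estimate: `log_se` must be >= 0", call. = FALSE)
  if (is.null(ci_low)) ci_low <- exp(log(hr) - stats::qnorm(0.975) * log_se)
  if (is.null(ci_high)) ci_high <- exp(log(hr) + stats::qnorm(0.975) * log_se)
  structure(list(hr = hr, ci_low = ci_low, ci_high = ci_high,
                 log_se = log_se),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), SE of log HR %.4f\n",
              x$hr, x$ci_low, x$ci_high, x$log_se))
  invisible(x)
}

#' Fixed-effect pooling of hazard-ratio estimates
#'
#' Inverse-variance (fixed-effect) meta-analysis on the \eqn{\ln HR} scale,
#' delegated to [metafor::rma()] with `method = "EE"`.
#'
#' @param estimates A list of [hr_estimate()] objects (a single estimate may
#'   be passed bare).
#' @return The pooled [hr_estimate()], with the pooled `log_se`.
#' @export
pool_hazard_ratios <- function(estimates) {
  if (inherits(estimates, "hr_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0L)
    stop("pool_hazard_ratios: empty estimate list", call. = FALSE)
  stopifnot(all(vapply(estimates, inherits, logical(1L), "hr_estimate")))
  yi <- vapply(estimates, function(e) log(e$hr), numeric(1L))
  sei <- vapply(estimates, function(e) e$log_se, numeric(1L))
  if (any(!is.finite(sei)) || any(sei <= 0))
    stop("pool_hazard_ratios: every estimate needs a finite positive log-HR SE",
         call. = FALSE)
  fit <- metafor::rma(yi = yi, sei = sei, method = "EE")
  hr_estimate(hr = exp(as.numeric(fit$beta)),
              ci_low = exp(fit$ci.lb),
              ci_high = exp(fit$ci.ub),
              log_se = fit$se)
}
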