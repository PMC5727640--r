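#' Weibull survival curve
#'
#' Constructs a Weibull survival curve in the scale/shape parameterisation
#' used throughout the model, \eqn{S(t) = \exp(-\lambda t^\gamma)}, with time
#' measured in weeks. The shape \eqn{\gamma} controls whether the hazard rises
#' (\eqn{\gamma > 1}) or falls (\eqn{\gamma < 1}) over time; the scale
#' \eqn{\lambda} sets the time unit.
#'
#' @param scale Positive scale parameter \eqn{\lambda} (per week^shape).
#' @param shape Positive shape parameter \eqn{\gamma} (dimensionless).
#' @return An object of class `weibull_curve`.
#' @examples
#' pfs <- weibull_curve(scale = 0.04191, shape = 1.4165)
#' weibull_survival(pfs, 10)
#' @export
weibull_curve <- function(scale, shape) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("weibull_curve: `scale` must be > 0", call. = FALSE)
  if (shape <= 0) stop("weibull_curve: `shape` must be > 0", call. = FALSE)
  structure(list(scale = scale, shape = shape), class = "weibull_curve")
}

#' @export
print.weibull_curve <- function(x, ...) {
  cat(sprintf("Weibull survival curve: S(t) = exp(-%g * t^%g), t in weeks\n",
              x$scale, x$shape))
  cat(sprintf("  median survival: %.2f weeks\n", weibull_median(x)))
  invisible(x)
}

#' Evaluate Weibull survival
#'
#' @param curve A [weibull_curve()].
#' @param t Vector of non-negative times in weeks.
#' @return Survival probabilities in (0, 1].
#' @export
weibull_survival <- function(curve, t) {
  stopifnot(inherits(curve, "weibull_curve"), is.numeric(t))
  if (any(t < 0)) stop("weibull_survival: `t` must be >= 0", call. = FALSE)
  exp(-curve$scale * t^curve$shape)
}

#' Median survival time of a Weibull curve
#'
#' Solves \eqn{\lambda t^\gamma = \ln 2} for \eqn{t}.
#'
#' @param curve A [weibull_curve()].
#' @return Median survival time in weeks.
#' @export
weibull_median <- function(curve) {
  stopifnot(inherits(curve, "weibull_curve"))
  (log(2) / curve$scale)^(1 / curve$shape)
}

#' Apply a hazard ratio to a reference survival curve
#'
#' Under proportional hazards the active-arm survival is
#' \eqn{S_{active}(t) = S_{ref}(t)^{HR}}; for a Weibull reference this is
#' again Weibull with scale \eqn{\lambda \cdot HR} and unchanged shape.
#'
#' @param reference A [weibull_curve()].
#' @param hr Positive hazard ratio (a number or an [hr_estimate()], in which
#'   case its point estimate is used).
#' @return The adjusted `weibull_curve`.
#' @export
adjust_survival <- function(reference, hr) {
  if (inherits(hr, "hr_estimate")) hr <- hr$hr
  stopifnot(is.numeric(hr), length(hr) == 1L, is.finite(hr))
  if (hr <= 0) stop("adjust_survival: `hr` must be > 0", call. = FALSE)
  weibull_curve(scale = reference$scale * hr, shape = reference$shape)
}

#' Fit a Weibull curve to Kaplan-Meier survival points
#'
#' Ordinary least squares on the complementary log-log transform: for
#' \eqn{S(t) = \exp(-\lambda t^\gamma)},
#' \eqn{\ln(-\ln S) = \ln\lambda + \gamma \ln t}, so the slope of the
#' regression of \eqn{\ln(-\ln S)} on \eqn{\ln t} estimates the shape and the
#' intercept the log scale. Points with survival exactly 0 or 1 are undefined
#' on this scale and are dropped with a warning.
#'
#' @param points A data frame with columns `time_weeks` and `survival`
#'   (e.g. from [km_estimate()]), times strictly positive.
#' @return A `weibull_fit`: list with elements `curve` ([weibull_curve()]),
#'   `r_squared`, `adj_r_squared`, `scale_se` (SE of the intercept, i.e. of
#'   \eqn{\ln\lambda}) and `shape_se` (SE of the slope), plus `n_points`.
#' @export
fit_weibull <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("time_weeks", "survival") %in% names(points)))
  t <- points$time_weeks
  s <- points$survival
  if (any(t <= 0)) stop("fit_weibull: times must be > 0", call. = FALSE)
  usable <- s > 0 & s < 1
  if (any(!usable)) {
    warning(sprintf(
      "fit_weibull: dropping %d point(s) with survival 0 or 1 (undefined on the cloglog scale)",
      sum(!usable)), call. = FALSE)
    t <- t[usable]
    s <- s[usable]
  }
  if (length(unique(t)) < 2L)
    stop("fit_weibull: need at least 2 usable points with distinct times",
         call. = FALSE)
  fit <- stats::lm(log(-log(s)) ~ log(t))
  # summary.lm warns on noiseless (perfect-fit) input; that case is valid here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(
    curve = weibull_curve(scale = exp(co[1L, 1L]), shape = co[2L, 1L]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    scale_se = co[1L, 2L],
    shape_se = co[2L, 2L],
    n_points = length(t)
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (cloglog least squares, %d points)\n", x$n_points))
  cat(sprintf("  scale = %.5g (SE of log-scale %.3g), shape = %.5g (SE %.3g)\n",
              x$curve$scale, x$scale_se, x$curve$shape, x$shape_se))
  cat(sprintf("  r^2 = %.4f (adjusted %.4f)\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}
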