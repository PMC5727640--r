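#' Simulate a censored survival cohort from a Weibull curve
#'
#' Event times are Weibull draws matching the model parameterisation
#' (`rweibull` with shape \eqn{\gamma} and scale \eqn{\lambda^{-1/\gamma}});
#' censoring times are independent exponentials with the given weekly
#' hazard. The observed time is the minimum and the status records whether
#' the event was observed. Stands in for trial-level time-to-event data when
#' exercising the curve-fitting step.
#'
#' @param curve Generating [weibull_curve()].
#' @param n Number of subjects.
#' @param censor_hazard Weekly exponential censoring hazard (0 for none).
#' @param seed Integer seed.
#' @return A `simulated_cohort` data frame with columns `time` (weeks) and
#'   `status` (1 = event, 0 = censored); the generating curve, censor hazard
#'   and seed are kept as attributes.
#' @export
simulate_cohort <- function(curve, n, censor_hazard = 0, seed = 1L) {
  stopifnot(inherits(curve, "weibull_curve"), n >= 1, censor_hazard >= 0)
  set.seed(seed)
  event <- stats::rweibull(n, shape = curve$shape,
                           scale = curve$scale^(-1 / curve$shape))
  censor <- if (censor_hazard > 0) stats::rexp(n, censor_hazard) else Inf
  out <- data.frame(time = pmin(event, censor),
                    status = as.integer(event <= censor))
  attr(out, "curve") <- curve
  attr(out, "censor_hazard") <- censor_hazard
  attr(out, "seed") <- seed
  class(out) <- c("simulated_cohort", "data.frame")
  out
}

#' Kaplan-Meier survival points from a cohort
#'
#' Product-limit estimation via [survival::survfit()] (deaths precede
#' censorings at tied times), evaluated on a grid of times. The default grid
#' runs every 2 weeks up to the 95th percentile of the observed times,
#' emulating points read off a published curve while avoiding the unstable
#' tail.
#'
#' @param cohort A [simulate_cohort()] result, or any data frame with `time`
#'   and `status` columns.
#' @param eval_times Evaluation times in weeks (optional).
#' @return A `km_points` data frame with columns `time_weeks`, `survival`,
#'   `n_risk`. Times before the first event return survival 1.
#' @export
km_estimate <- function(cohort, eval_times = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L,
            all(c("time", "status") %in% names(cohort)))
  if (is.null(eval_times)) {
    upper <- stats::quantile(cohort$time, 0.95, names = FALSE)
    eval_times <- seq(2, upper, by = 2)
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = cohort)
  sm <- summary(fit, times = eval_times, extend = TRUE)
  out <- data.frame(time_weeks = sm$time, survival = sm$surv,
                    n_risk = sm$n.risk)
  class(out) <- c("km_points", "data.frame")
  out
}

#' Simulate a trial-level hazard-ratio estimate
#'
#' The log hazard ratio is drawn normal around the true log HR with the
#' standard large-sample SE \eqn{\sqrt{1/d_1 + 1/d_2}} for \eqn{d} events
#' per arm; the 95% CI follows from the same SE. Stands in for the per-trial
#' inputs of the hazard-ratio meta-analysis.
#'
#' @param true_hr True hazard ratio (> 0).
#' @param events_per_arm Events in each arm (>= 2; a length-2 vector gives
#'   unequal arms).
#' @param seed Integer seed.
#' @return An [hr_estimate()].
#' @export
simulate_trial_hr <- function(true_hr, events_per_arm, seed = 1L) {
  stopifnot(true_hr > 0, all(events_per_arm >= 2),
            length(events_per_arm) %in% c(1L, 2L))
  d <- rep(events_per_arm, length.out = 2L)
  se <- sqrt(1 / d[1L] + 1 / d[2L])
  set.seed(seed)
  log_hr <- stats::rnorm(1L, log(true_hr), se)
  hr_estimate(hr = exp(log_hr), log_se = se)
}
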