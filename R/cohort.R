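#' Per-cycle discount factors
#'
#' Annual discounting applied continuously across cycles:
#' \eqn{(1 + r)^{-k / c}} for cycle index \eqn{k} with \eqn{c} cycles per
#' year, so cycle 0 is undiscounted and one year out the factor is
#' \eqn{1/(1+r)}.
#'
#' @param cycle_index Vector of non-negative cycle indices.
#' @param config The `config` element of a `model_inputs` object.
#' @return Discount factors in (0, 1].
#' @export
discount_factor <- function(cycle_index, config) {
  stopifnot(all(cycle_index >= 0))
  (1 + config$annual_discount_rate)^(-cycle_index / cycles_per_year(config))
}

#' Build the three-state cohort trace
#'
#' Partitioned-survival occupancy: at the start of cycle \eqn{k} (time
#' \eqn{t_k = k \times} cycle length) the progression-free fraction is
#' \eqn{S_{PFS}(t_k)}, the dead fraction \eqn{1 - S_{OS}(t_k)}, and the
#' progressed fraction the difference \eqn{S_{OS} - S_{PFS}}, clamped at zero
#' (with a warning) if the curves cross. The whole cohort enters
#' progression-free.
#'
#' @param pfs_curve,os_curve [weibull_curve()] objects for the strategy.
#' @param config The `config` element of a `model_inputs` object.
#' @return A `cohort_trace` data frame with one row per cycle (`cycle` =
#'   0..N-1) and columns `week`, `pfs`, `pd`, `dead`, `incident_deaths`,
#'   `discount_factor`.
#' @export
build_trace <- function(pfs_curve, os_curve, config) {
  n <- n_cycles(config)
  k <- seq_len(n) - 1L
  t <- k * config$cycle_length_weeks
  s_pfs <- weibull_survival(pfs_curve, t)
  s_os <- weibull_survival(os_curve, t)
  if (any(s_pfs > s_os + 1e-12))
    warning("build_trace: PFS curve exceeds OS curve at some cycles; ",
            "progressed occupancy clamped at 0", call. = FALSE)
  pfs <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- s_os - pfs
  trace <- data.frame(
    cycle = k,
    week = t,
    pfs = pfs,
    pd = pd,
    dead = dead,
    incident_deaths = diff(c(0, dead)),
    discount_factor = discount_factor(k, config)
  )
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

#' Discounted life-years from a cohort trace
#'
#' Sum over cycles of occupancy x cycle length (in years) x discount factor.
#'
#' @param trace A [build_trace()] result.
#' @param config The `config` element of a `model_inputs` object.
#' @param state `"alive"` (progression-free + progressed) or `"pfs"`.
#' @return Discounted life-years.
#' @export
life_years <- function(trace, config, state = c("alive", "pfs")) {
  state <- match.arg(state)
  occ <- if (state == "alive") trace$pfs + trace$pd else trace$pfs
  cycle_years <- config$cycle_length_weeks / 52
  sum(occ * trace$discount_factor) * cycle_years
}

#' Discounted quality-adjusted life-years from a cohort trace
#'
#' @param trace A [build_trace()] result.
#' @param utilities The `utilities` element of a `model_inputs` object
#'   ([ranged()] utilities for the progression-free and progressed states).
#' @param config The `config` element of a `model_inputs` object.
#' @return Discounted QALYs.
#' @export
qalys <- function(trace, utilities, config) {
  u_pfs <- utilities$u_pfs$value
  u_pd <- utilities$u_pd$value
  cycle_years <- config$cycle_length_weeks / 52
  sum((u_pfs * trace$pfs + u_pd * trace$pd) * trace$discount_factor) *
    cycle_years
}

#' Strategy tags
#'
#' The three competing strategies: supportive care only (`control`), daily
#' apatinib until progression at full price (`apatinib_no_pap`), and daily
#' apatinib under the patient assistance programme in which only an initial
#' period of drug is paid for (`apatinib_pap`).
#'
#' @return Character vector of the valid strategy tags.
#' @export
strategies <- function() c("control", "apatinib_no_pap", "apatinib_pap")

#' Accrue discounted payer costs over a cohort trace
#'
#' Per cycle, the payer pays `coverage_fraction` of: drug charges while
#' progression-free (apatinib strategies only; zeroed after the paid period
#' under the assistance programme), supportive care while progression-free
#' (control arm, or any arm if `pfs_supportive_with_drug` is set), supportive
#' care while progressed, and a one-time end-of-life palliative charge at the
#' cycle of incident death. All terms are discounted.
#'
#' @param trace A [build_trace()] result.
#' @param inputs A `model_inputs` object.
#' @param strategy One of [strategies()].
#' @return A `cost_breakdown`: list with `cost_pfs_state`, `cost_pd_state`,
#'   `cost_death` and `total` (all discounted USD, payer perspective).
#' @export
accrue_costs <- function(trace, inputs, strategy) {
  if (!strategy %in% strategies())
    stop("accrue_costs: unknown strategy tag: ", strategy, call. = FALSE)
  costs <- inputs$costs
  config <- inputs$config
  cov <- costs$coverage_fraction$value
  supp <- costs$supportive_care_per_cycle$value
  df <- trace$discount_factor

  on_drug <- strategy != "control"
  drug_cycle <- if (on_drug) {
    paid <- if (strategy == "apatinib_pap")
      trace$cycle < pap_paid_cycles(inputs$pap, config)
    else rep(TRUE, nrow(trace))
    ifelse(paid, daily_drug_charge(costs) * 7 * config$cycle_length_weeks, 0)
  } else 0
  pfs_supp <- if (!on_drug || isTRUE(costs$pfs_supportive_with_drug)) supp else 0

  cost_pfs <- sum(cov * trace$pfs * (drug_cycle + pfs_supp) * df)
  cost_pd <- sum(cov * trace$pd * supp * df)
  cost_death <- sum(cov * trace$incident_deaths *
                      costs$end_of_life_palliative$value * df)
  structure(list(
    cost_pfs_state = cost_pfs,
    cost_pd_state = cost_pd,
    cost_death = cost_death,
    total = cost_pfs + cost_pd + cost_death
  ), class = "cost_breakdown")
}

#' Run one strategy through the full cohort model
#'
#' Applies the pooled hazard ratios to the control-arm curves (apatinib
#' strategies; HR = 1 for control), builds the trace, and accrues discounted
#' life-years, QALYs and payer costs.
#'
#' @param inputs A `model_inputs` object.
#' @param strategy One of [strategies()].
#' @return An `outcome_summary`: list with `strategy`, `disease_free_ly`,
#'   `overall_ly`, `qalys`, `costs` (a `cost_breakdown`), and the `config`
#'   used.
#' @export
run_strategy <- function(inputs, strategy) {
  if (!strategy %in% strategies())
    stop("run_strategy: unknown strategy tag: ", strategy, call. = FALSE)
  on_drug <- strategy != "control"
  pfs_curve <- if (on_drug) adjust_survival(inputs$control_pfs, inputs$hr_pfs)
               else inputs$control_pfs
  os_curve <- if (on_drug) adjust_survival(inputs$control_os, inputs$hr_os)
              else inputs$control_os
  trace <- build_trace(pfs_curve, os_curve, inputs$config)
  structure(list(
    strategy = strategy,
    disease_free_ly = life_years(trace, inputs$config, "pfs"),
    overall_ly = life_years(trace, inputs$config, "alive"),
    qalys = qalys(trace, inputs$utilities, inputs$config),
    costs = accrue_costs(trace, inputs, strategy),
    config = inputs$config
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Strategy: %s\n", x$strategy))
  cat(sprintf("  disease-free LYs %.3f | overall LYs %.3f | QALYs %.3f\n",
              x$disease_free_ly, x$overall_ly, x$qalys))
  cat(sprintf("  costs: PFS $%.0f + PD $%.0f + death $%.0f = $%.0f\n",
              x$costs$cost_pfs_state, x$costs$cost_pd_state,
              x$costs$cost_death, x$costs$total))
  invisible(x)
}
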