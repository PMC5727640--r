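#' Ranged parameter
#'
#' A base-case value with the (low, high) range used by the sensitivity
#' analyses. Requires `low <= value <= high`.
#'
#' @param value Base-case (median) value.
#' @param low,high Range bounds.
#' @return A list with elements `value`, `low`, `high`, class `ranged`.
#' @export
ranged <- function(value, low = value, high = value) {
  stopifnot(is.numeric(value), is.numeric(low), is.numeric(high))
  if (!(low <= value && value <= high))
    stop(sprintf("ranged: require low <= value <= high (got %g, %g, %g)",
                 low, value, high), call. = FALSE)
  structure(list(value = value, low = low, high = high), class = "ranged")
}

#' Base-case model inputs
#'
#' The packaged base case of the analysis: 1-week cycles over a 10-year
#' horizon, 5% annual discounting, a $22,200/QALY willingness-to-pay
#' threshold, control-arm Weibull PFS/OS curves, pooled hazard ratios for
#' apatinib, payer costs at 60% insurance coverage, utilities 0.88
#' (progression-free) and 0.41 (progressed), a 3+X patient assistance
#' programme, and the budget-impact demographics for a one-million-person
#' region.
#'
#' @return A validated `model_inputs` object.
#' @export
default_inputs <- function() {
  inputs <- structure(list(
    schema = 1L,
    config = list(
      cycle_length_weeks = 1,
      horizon_years = 10,
      annual_discount_rate = 0.05,
      wtp_threshold = 22200,
      currency_year = 2015
    ),
    utilities = list(
      u_pfs = ranged(0.88, 0.80, 0.97),
      u_pd = ranged(0.41, 0.28, 0.63)
    ),
    costs = list(
      apatinib_unit_cost = ranged(106.5, 53.2, 106.5),
      unit_strength_mg = 425,
      daily_dose_mg = 850,
      # "per_day": the unit cost is the daily charge; "per_unit": daily
      # charge = (daily_dose_mg / unit_strength_mg) * unit cost.
      drug_charge_basis = "per_day",
      supportive_care_per_cycle = ranged(117.1, 32.3, 322.6),
      end_of_life_palliative = ranged(1483.9, 1072.3, 2119.3),
      coverage_fraction = ranged(0.60, 0.45, 0.75),
      pfs_supportive_with_drug = FALSE
    ),
    pap = list(enabled = TRUE, variant = "3+X", paid_months = 3),
    control_pfs = weibull_curve(scale = 0.04191, shape = 1.4165),
    control_os = weibull_curve(scale = 0.02143, shape = 1.18716),
    hr_pfs = hr_estimate(0.34, ci_low = 0.27, ci_high = 0.595),
    hr_os = hr_estimate(0.57, ci_low = 0.537, ci_high = 0.937),
    budget = list(
      population = 1e6,
      annual_incident_gc_per_million = 215.5,
      fraction_advanced = 2 / 3,
      fraction_reaching_third_line = 0.7,
      uptake_by_year = c(0.8, 1, 1, 1, 1)
    )
  ), class = "model_inputs")
  validate_inputs(inputs)
}

#' Validate a set of model inputs
#'
#' Checks completeness and every declared bound; returns the inputs
#' invisibly augmented (ranged fields coerced to [ranged()]).
#'
#' @param inputs A `model_inputs` object or a plain list with the same shape.
#' @return The validated `model_inputs`.
#' @export
validate_inputs <- function(inputs) {
  required <- c("config", "utilities", "costs", "pap", "control_pfs",
                "control_os", "hr_pfs", "hr_os", "budget")
  missing <- setdiff(required, names(inputs))
  if (length(missing) > 0L)
    stop("model inputs: missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  cfg <- inputs$config
  for (f in c("cycle_length_weeks", "horizon_years", "annual_discount_rate",
              "wtp_threshold"))
    if (is.null(cfg[[f]]))
      stop("model inputs: missing config field: ", f, call. = FALSE)
  if (cfg$cycle_length_weeks <= 0)
    stop("model inputs: cycle_length_weeks must be > 0", call. = FALSE)
  if (cfg$horizon_years * 52 < cfg$cycle_length_weeks)
    stop("model inputs: horizon must cover at least one cycle", call. = FALSE)
  if (cfg$annual_discount_rate < 0 || cfg$annual_discount_rate >= 1)
    stop("model inputs: annual_discount_rate must be in [0, 1)", call. = FALSE)
  if (cfg$wtp_threshold <= 0)
    stop("model inputs: wtp_threshold must be > 0", call. = FALSE)

  as_ranged <- function(x, name) {
    if (inherits(x, "ranged")) return(x)
    if (is.list(x) && all(c("value", "low", "high") %in% names(x)))
      return(ranged(x$value, x$low, x$high))
    if (is.numeric(x) && length(x) == 1L) return(ranged(x))
    stop("model inputs: cannot interpret `", name, "` as a ranged parameter",
         call. = FALSE)
  }
  for (f in c("u_pfs", "u_pd"))
    inputs$utilities[[f]] <- as_ranged(inputs$utilities[[f]], f)
  for (f in c("apatinib_unit_cost", "supportive_care_per_cycle",
              "end_of_life_palliative", "coverage_fraction"))
    inputs$costs[[f]] <- as_ranged(inputs$costs[[f]], f)

  for (f in c("u_pfs", "u_pd")) {
    u <- inputs$utilities[[f]]
    if (u$low < 0 || u$high > 1)
      stop("model inputs: utility `", f, "` range must lie in [0, 1]",
           call. = FALSE)
  }
  for (f in c("apatinib_unit_cost", "supportive_care_per_cycle",
              "end_of_life_palliative"))
    if (inputs$costs[[f]]$low < 0)
      stop("model inputs: cost `", f, "` must be >= 0", call. = FALSE)
  cov <- inputs$costs$coverage_fraction
  if (cov$low < 0 || cov$high > 1)
    stop("model inputs: coverage_fraction must lie in [0, 1]", call. = FALSE)
  if (inputs$costs$daily_dose_mg <= 0 ||
      inputs$costs$daily_dose_mg %% inputs$costs$unit_strength_mg != 0)
    stop("model inputs: daily_dose_mg must be a positive multiple of unit_strength_mg",
         call. = FALSE)
  if (!inputs$costs$drug_charge_basis %in% c("per_day", "per_unit"))
    stop("model inputs: drug_charge_basis must be 'per_day' or 'per_unit'",
         call. = FALSE)

  if (!inputs$pap$variant %in% c("none", "1+X", "2+X", "3+X"))
    stop("model inputs: pap variant must be one of none, 1+X, 2+X, 3+X",
         call. = FALSE)
  if (inputs$pap$paid_months < 0)
    stop("model inputs: pap paid_months must be >= 0", call. = FALSE)

  for (f in c("control_pfs", "control_os"))
    if (!inherits(inputs[[f]], "weibull_curve"))
      inputs[[f]] <- weibull_curve(inputs[[f]]$scale, inputs[[f]]$shape)
  for (f in c("hr_pfs", "hr_os"))
    if (!inherits(inputs[[f]], "hr_estimate"))
      inputs[[f]] <- do.call(hr_estimate, inputs[[f]][
        intersect(names(inputs[[f]]), c("hr", "ci_low", "ci_high", "log_se"))])

  inputs$budget$uptake_by_year <- as.numeric(unlist(inputs$budget$uptake_by_year))
  b <- inputs$budget
  if (b$population <= 0)
    stop("model inputs: budget population must be > 0", call. = FALSE)
  for (f in c("fraction_advanced", "fraction_reaching_third_line"))
    if (b[[f]] < 0 || b[[f]] > 1)
      stop("model inputs: budget `", f, "` must lie in [0, 1]", call. = FALSE)
  if (length(b$uptake_by_year) != 5L ||
      any(b$uptake_by_year < 0 | b$uptake_by_year > 1))
    stop("model inputs: uptake_by_year must be 5 fractions in [0, 1]",
         call. = FALSE)
  if (b$annual_incident_gc_per_million < 0)
    stop("model inputs: incidence must be >= 0", call. = FALSE)

  class(inputs) <- "model_inputs"
  inputs
}

#' Load model inputs from a YAML configuration file
#'
#' Reads a `schema: 1` YAML file; any field not present takes its base-case
#' default from [default_inputs()]. The packaged base case is at
#' `system.file("extdata", "base_case.yaml", package = "apatinibCEA")` and is
#' loaded when `path` is omitted.
#'
#' @param path Path to the YAML config, or `NULL` for the packaged base case.
#' @return A validated `model_inputs` object.
#' @export
load_inputs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "base_case.yaml", package = "apatinibCEA")
  if (!file.exists(path))
    stop("load_inputs: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema) || raw$schema != 1L)
    stop("load_inputs: config must declare `schema: 1`", call. = FALSE)
  merged <- modify_defaults(unclass(default_inputs()), raw)
  validate_inputs(merged)
}

# Recursive overlay of user config onto the defaults. Leaf lists carrying
# value/low/high replace the default wholesale (partial ranges make no sense).
modify_defaults <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]) &&
        !all(c("value", "low", "high") %in% names(user[[nm]])) &&
        !inherits(defaults[[nm]], c("ranged", "weibull_curve", "hr_estimate"))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Write model inputs to a YAML configuration file
#'
#' Inverse of [load_inputs()]: a written file loads back to identical values.
#'
#' @param inputs A `model_inputs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "model_inputs"))
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(strip(unclass(inputs)), path, precision = 15L)
  invisible(path)
}

#' Model cycles per calendar year
#'
#' Uses the 52-week year convention, so 1-week cycles give 52 cycles/year.
#'
#' @param config The `config` element of a `model_inputs` object.
#' @return Number of cycles per year.
#' @export
cycles_per_year <- function(config) {
  52 / config$cycle_length_weeks
}

#' Total number of model cycles over the horizon
#'
#' @inheritParams cycles_per_year
#' @return `floor(horizon / cycle_length)`.
#' @export
n_cycles <- function(config) {
  floor(config$horizon_years * 52 / config$cycle_length_weeks)
}

# Cycles of drug the patient pays for under the assistance programme:
# "m+X" means m months paid, with a month = 52/12 weeks (3 months = 13
# weekly cycles).
pap_paid_cycles <- function(pap, config) {
  if (!isTRUE(pap$enabled) || identical(pap$variant, "none")) return(Inf)
  round(pap$paid_months * (52 / 12) / config$cycle_length_weeks)
}

# Daily apatinib charge under the configured unit interpretation.
daily_drug_charge <- function(costs, unit_cost = costs$apatinib_unit_cost$value) {
  switch(costs$drug_charge_basis,
         per_day = unit_cost,
         per_unit = (costs$daily_dose_mg / costs$unit_strength_mg) * unit_cost,
         stop("unknown drug_charge_basis", call. = FALSE))
}

#' @export
print.model_inputs <- function(x, ...) {
  cat("Model inputs (payer-perspective cost-effectiveness model)\n")
  cat(sprintf("  cycles: %d x %g week(s); discount %g%%/yr; WTP $%g/QALY\n",
              n_cycles(x$config), x$config$cycle_length_weeks,
              100 * x$config$annual_discount_rate, x$config$wtp_threshold))
  cat(sprintf("  control PFS: Weibull(%g, %g); OS: Weibull(%g, %g)\n",
              x$control_pfs$scale, x$control_pfs$shape,
              x$control_os$scale, x$control_os$shape))
  cat(sprintf("  HR PFS %.2f, HR OS %.2f; utilities %.2f / %.2f; coverage %.0f%%\n",
              x$hr_pfs$hr, x$hr_os$hr, x$utilities$u_pfs$value,
              x$utilities$u_pd$value,
              100 * x$costs$coverage_fraction$value))
  cat(sprintf("  PAP: %s\n",
              if (isTRUE(x$pap$enabled)) x$pap$variant else "none"))
  invisible(x)
}
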