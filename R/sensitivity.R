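# Registry of the parameters varied in the one-way and probabilistic
# sensitivity analyses: each entry carries its base value, (low, high) range,
# the PSA distribution family, and a setter producing modified inputs.
sens_parameter_table <- function(inputs) {
  set_ranged <- function(path) {
    force(path)
    function(inputs, v) {
      old <- inputs[[path[1L]]][[path[2L]]]
      inputs[[path[1L]]][[path[2L]]] <- ranged(v, min(v, old$low),
                                               max(v, old$high))
      inputs
    }
  }
  set_hr <- function(field) {
    force(field)
    function(inputs, v) {
      old <- inputs[[field]]
      inputs[[field]] <- hr_estimate(v, log_se = old$log_se)
      inputs
    }
  }
  ranged_entry <- function(path, dist) {
    p <- inputs[[path[1L]]][[path[2L]]]
    list(base = p$value, low = p$low, high = p$high, dist = dist,
         set = set_ranged(path))
  }
  hr_entry <- function(field) {
    h <- inputs[[field]]
    list(base = h$hr, low = h$ci_low, high = h$ci_high, dist = "lognormal",
         log_se = h$log_se, set = set_hr(field))
  }
  list(
    apatinib_unit_cost = ranged_entry(c("costs", "apatinib_unit_cost"), "triangle"),
    supportive_care_per_cycle = ranged_entry(c("costs", "supportive_care_per_cycle"), "triangle"),
    end_of_life_palliative = ranged_entry(c("costs", "end_of_life_palliative"), "triangle"),
    coverage_fraction = ranged_entry(c("costs", "coverage_fraction"), "beta"),
    u_pfs = ranged_entry(c("utilities", "u_pfs"), "beta"),
    u_pd = ranged_entry(c("utilities", "u_pd"), "beta"),
    hr_pfs = hr_entry("hr_pfs"),
    hr_os = hr_entry("hr_os")
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Each parameter is set in turn to its low and high bound (all others at
#' base) and the incremental cost-effectiveness ratio of the comparison is
#' recomputed. Hazard-ratio bounds are their 95% confidence limits; cost and
#' utility bounds are the declared ranges. Entries are sorted by descending
#' span with an alphabetical tie-break.
#'
#' @param inputs A `model_inputs` object.
#' @param comparison Character pair `c(reference, alternative)` of
#'   [strategies()] tags.
#' @return A data frame with columns `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `span`.
#' @export
one_way_sensitivity <- function(inputs,
                                comparison = c("control", "apatinib_pap")) {
  stopifnot(length(comparison) == 2L, all(comparison %in% strategies()))
  table <- sens_parameter_table(inputs)
  icer_at <- function(modified) {
    ref <- run_strategy(modified, comparison[1L])
    alt <- run_strategy(modified, comparison[2L])
    compute_icer(ref, alt)$icer
  }
  rows <- lapply(names(table), function(nm) {
    p <- table[[nm]]
    data.frame(parameter = nm, low = p$low, high = p$high,
               icer_low = icer_at(p$set(inputs, p$low)),
               icer_high = icer_at(p$set(inputs, p$high)))
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_high - out$icer_low)
  out[order(-out$span, out$parameter), , drop = FALSE]
}
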