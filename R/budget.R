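#' Five-year budget-impact projection
#'
#' Projects the incremental (undiscounted) payer expenditure of listing
#' apatinib with the patient assistance programme for a defined population.
#' Each fiscal year's treated pool is
#' `population x incidence x fraction_advanced x fraction_reaching_third_line
#' x uptake`, and each treated patient costs the payer the per-patient
#' incremental cost of the `apatinib_pap` strategy over `control` from the
#' cohort model (the payer subsidises its coverage fraction of the paid drug
#' period plus non-drug care).
#'
#' @param inputs A `model_inputs` object (its `budget` element supplies the
#'   demographics and uptake schedule).
#' @return A `budget_result` data frame with columns `fiscal_year`,
#'   `patients`, `per_patient_incremental_cost`,
#'   `incremental_expenditure_usd`.
#' @export
project_budget <- function(inputs) {
  b <- inputs$budget
  if (is.null(b$uptake_by_year) || length(b$uptake_by_year) != 5L)
    stop("project_budget: uptake_by_year must give 5 fiscal years",
         call. = FALSE)
  ctrl <- run_strategy(inputs, "control")
  pap <- run_strategy(inputs, "apatinib_pap")
  per_patient <- pap$costs$total - ctrl$costs$total
  incidence <- b$population * b$annual_incident_gc_per_million / 1e6
  eligible <- incidence * b$fraction_advanced * b$fraction_reaching_third_line
  patients <- eligible * b$uptake_by_year
  out <- data.frame(
    fiscal_year = seq_len(5L),
    patients = patients,
    per_patient_incremental_cost = per_patient,
    incremental_expenditure_usd = patients * per_patient
  )
  class(out) <- c("budget_result", "data.frame")
  out
}
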