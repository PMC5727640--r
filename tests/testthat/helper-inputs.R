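# Packaged base case, loaded once per test run.
base_inputs <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_inputs()
    cached
  }
})

# Random valid Weibull curve for property loops.
random_curve <- function() {
  weibull_curve(scale = runif(1, 0.005, 0.1), shape = runif(1, 0.5, 2.5))
}

# Inputs with every PSA/tornado distribution collapsed to a point mass.
degenerate_inputs <- function(inputs = base_inputs()) {
  for (f in c("u_pfs", "u_pd"))
    inputs$utilities[[f]] <- ranged(inputs$utilities[[f]]$value)
  for (f in c("apatinib_unit_cost", "supportive_care_per_cycle",
              "end_of_life_palliative", "coverage_fraction"))
    inputs$costs[[f]] <- ranged(inputs$costs[[f]]$value)
  for (f in c("hr_pfs", "hr_os"))
    inputs[[f]] <- hr_estimate(inputs[[f]]$hr, log_se = 0)
  inputs
}

# Inputs under which apatinib differs from control only through the drug:
# free drug, hazard ratios forced to 1, supportive care charged in both arms.
neutralized_inputs <- function(inputs = base_inputs()) {
  inputs$costs$apatinib_unit_cost <- ranged(0)
  inputs$costs$pfs_supportive_with_drug <- TRUE
  inputs$hr_pfs <- hr_estimate(1, log_se = inputs$hr_pfs$log_se)
  inputs$hr_os <- hr_estimate(1, log_se = inputs$hr_os$log_se)
  inputs
}
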