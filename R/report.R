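# Outcome table across the three strategies, shaped like the published
# base-case summary: metrics as rows, strategies as columns.
outcome_table <- function(summaries) {
  metric <- c("cost_pfs_state", "cost_pd_state", "cost_death", "total_cost",
              "disease_free_ly", "overall_ly", "qalys")
  cols <- lapply(summaries, function(s)
    c(s$costs$cost_pfs_state, s$costs$cost_pd_state, s$costs$cost_death,
      s$costs$total, s$disease_free_ly, s$overall_ly, s$qalys))
  out <- data.frame(metric = metric)
  for (s in summaries) out[[s$strategy]] <- cols[[s$strategy]]
  out
}

write_manifest <- function(out_dir, config_path, seeds, files) {
  manifest <- list(
    artifact = "apatinibCEA",
    version = as.character(utils::packageVersion("apatinibCEA")),
    config_md5 = unname(tools::md5sum(config_path)),
    seeds = seeds,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the base-case analysis and write its tables
#'
#' Runs all three strategies, writes the outcome table
#' (`table3.csv`, metrics by strategy), both incremental comparisons
#' (`icers.json`), and a run manifest. Deterministic: identical configs give
#' byte-identical tables.
#'
#' @param config_path Path to a YAML config, or `NULL` for the packaged base
#'   case.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the summaries, ICER results, and file
#'   paths.
#' @export
run_base_case <- function(config_path = NULL, out_dir = ".") {
  if (is.null(config_path))
    config_path <- system.file("extdata", "base_case.yaml",
                               package = "apatinibCEA")
  inputs <- load_inputs(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summaries <- lapply(strategies(), function(s) run_strategy(inputs, s))
  names(summaries) <- strategies()
  icers <- list(
    apatinib_no_pap = compute_icer(summaries$control,
                                   summaries$apatinib_no_pap),
    apatinib_pap = compute_icer(summaries$control, summaries$apatinib_pap)
  )

  table_path <- file.path(out_dir, "table3.csv")
  utils::write.csv(outcome_table(summaries), table_path, row.names = FALSE)
  icer_path <- file.path(out_dir, "icers.json")
  jsonlite::write_json(lapply(icers, unclass), icer_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- basename(c(table_path, icer_path))
  manifest <- write_manifest(out_dir, config_path, seeds = list(),
                             files = files)
  message("base case written to ", out_dir)
  invisible(list(inputs = inputs, summaries = summaries, icers = icers,
                 files = c(table_path, icer_path, manifest)))
}

#' Run the full analysis suite and write all outputs
#'
#' Extends [run_base_case()] with the tornado analysis (`tornado.csv`), the
#' probabilistic sensitivity analysis (`psa.csv`), its acceptability curves
#' (`ceac.csv`), and the budget projection (`budget.csv`); the manifest
#' records the seed.
#'
#' @inheritParams run_base_case
#' @param n Number of PSA draws.
#' @param seed Integer seed for the PSA.
#' @param wtp_max Upper end of the WTP grid (USD/QALY, step 1000).
#' @return Invisibly, a list with every result object and file path.
#' @export
run_full <- function(config_path = NULL, out_dir = ".", n = 1000, seed = 1L,
                     wtp_max = 60000) {
  if (is.null(config_path))
    config_path <- system.file("extdata", "base_case.yaml",
                               package = "apatinibCEA")
  base <- run_base_case(config_path, out_dir)
  inputs <- base$inputs

  tornado <- one_way_sensitivity(inputs)
  tornado_path <- file.path(out_dir, "tornado.csv")
  utils::write.csv(tornado, tornado_path, row.names = FALSE)

  psa <- run_psa(inputs, n = n, seed = seed)
  psa_path <- file.path(out_dir, "psa.csv")
  utils::write.csv(psa$draws, psa_path, row.names = FALSE)

  curve <- ceac(psa, wtp_grid = seq(0, wtp_max, by = 1000))
  ceac_path <- file.path(out_dir, "ceac.csv")
  utils::write.csv(curve, ceac_path, row.names = FALSE)

  budget <- project_budget(inputs)
  budget_path <- file.path(out_dir, "budget.csv")
  utils::write.csv(budget, budget_path, row.names = FALSE)

  files <- basename(c(base$files[1:2], tornado_path, psa_path, ceac_path,
                      budget_path))
  manifest <- write_manifest(out_dir, config_path,
                             seeds = list(psa = seed), files = files)
  message("full analysis written to ", out_dir)
  invisible(list(base = base, tornado = tornado, psa = psa, ceac = curve,
                 budget = budget,
                 files = c(base$files[1:2], tornado_path, psa_path,
                           ceac_path, budget_path, manifest)))
}
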