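#' Incremental cost-effectiveness ratio
#'
#' Computes \eqn{\Delta C}, \eqn{\Delta E} (QALYs, with a life-year variant)
#' and their ratio between two strategies run under the same configuration.
#' The ratio is only reported when both differences share a sign; otherwise a
#' dominance tag is set: `dominant` (alternative cheaper and more effective),
#' `dominated` (dearer and less effective), or `equivalent`.
#'
#' @param reference,alternative `outcome_summary` objects from
#'   [run_strategy()] under the same config.
#' @return An `icer_result`: list with `delta_cost`, `delta_qalys`,
#'   `delta_ly`, `icer` (USD/QALY, `NA` when a dominance tag applies),
#'   `icer_per_ly`, and `tag` (`"icer"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`).
#' @export
compute_icer <- function(reference, alternative) {
  stopifnot(inherits(reference, "outcome_summary"),
            inherits(alternative, "outcome_summary"))
  if (!identical(reference$config, alternative$config))
    stop("compute_icer: summaries come from different model configs",
         call. = FALSE)
  dc <- alternative$costs$total - reference$costs$total
  de <- alternative$qalys - reference$qalys
  dly <- alternative$overall_ly - reference$overall_ly
  ratio_or_na <- function(dc, de) {
    if (de != 0 && sign(dc) == sign(de)) dc / de else NA_real_
  }
  tag <- if (dc == 0 && de == 0) "equivalent"
         else if (dc <= 0 && de >= 0) "dominant"
         else if (dc >= 0 && de <= 0) "dominated"
         else "icer"
  structure(list(
    reference = reference$strategy,
    alternative = alternative$strategy,
    delta_cost = dc,
    delta_qalys = de,
    delta_ly = dly,
    icer = if (tag == "icer") ratio_or_na(dc, de) else NA_real_,
    icer_per_ly = if (tag == "icer") ratio_or_na(dc, dly) else NA_real_,
    tag = tag
  ), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost $%.0f, dQALY %.3f",
              x$alternative, x$reference, x$delta_cost, x$delta_qalys))
  if (x$tag == "icer")
    cat(sprintf(" -> ICER $%.0f/QALY ($%.0f/LY)\n", x$icer, x$icer_per_ly))
  else cat(sprintf(" -> %s\n", x$tag))
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' \eqn{NMB = WTP \times QALYs - cost}; the incremental NMB between two
#' strategies is positive exactly when the ICER falls below the
#' willingness-to-pay (for a QALY-gaining comparison).
#'
#' @param summary An `outcome_summary` from [run_strategy()].
#' @param wtp Willingness to pay per QALY (USD, >= 0).
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(summary, wtp) {
  stopifnot(inherits(summary, "outcome_summary"), wtp >= 0)
  wtp * summary$qalys - summary$costs$total
}
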