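#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes the incremental direct cost, healthy life-years gained (baseline
#' life-years lost minus alternative life-years lost) and the ICER for two
#' generation results from the same scenario, generation and population. A
#' negative ICER with positive health gain means the alternative is dominant
#' (cost-saving and health-improving). When no life-years separate the
#' strategies the ICER is flagged undefined rather than reported as infinite.
#'
#' @param baseline,alternative `brca_generation_result` objects (see
#'   [run_model()]).
#' @return A `brca_icer` list with `delta_cost_total`,
#'   `delta_cost_per_year_per_person`, `delta_hly`, `icer`, `icer_defined`.
#' @export
compare_models <- function(baseline, alternative) {
  stopifnot(inherits(baseline, "brca_generation_result"),
            inherits(alternative, "brca_generation_result"))
  if (baseline$scenario_label != alternative$scenario_label)
    stopf("cannot compare different scenarios ('%s' vs '%s')",
          baseline$scenario_label, alternative$scenario_label)
  if (baseline$generation_index != alternative$generation_index)
    stopf("cannot compare different generations (%d vs %d)",
          baseline$generation_index, alternative$generation_index)
  if (baseline$population_size != alternative$population_size)
    stopf("cannot compare different population sizes")

  delta_cost <- alternative$cost$total - baseline$cost$total
  delta_hly <- baseline$outcome$hly_lost - alternative$outcome$hly_lost
  defined <- abs(delta_hly) > 0
  structure(list(
    baseline_model = baseline$model_id,
    alternative_model = alternative$model_id,
    generation_index = baseline$generation_index,
    scenario_label = baseline$scenario_label,
    delta_cost_total = delta_cost,
    delta_cost_per_year_per_person = alternative$cost$per_year_per_person -
      baseline$cost$per_year_per_person,
    delta_hly = delta_hly,
    icer = if (defined) delta_cost / delta_hly else NA_real_,
    icer_defined = defined
  ), class = "brca_icer")
}

#' Detection-rate gain in percentage points
#'
#' Difference between the alternative's and baseline's detected-carrier
#' counts, as a percentage of the total carrier pool (the headline "+41.8%"
#' and "+68.3%" figures are percentage-point differences of detection rates).
#'
#' @param baseline,alternative `brca_generation_result` objects sharing the
#'   same carrier total.
#' @return Percentage points.
#' @export
detection_gain_pp <- function(baseline, alternative) {
  C <- baseline$detection$carriers_total
  if (abs(C - alternative$detection$carriers_total) > 1e-9)
    stopf("carrier totals differ between the compared results")
  100 * (alternative$detection$carriers_detected -
           baseline$detection$carriers_detected) / C
}

#' Relative reduction in BRCA-related cancers
#'
#' @param baseline,alternative `brca_generation_result` objects.
#' @return Percent reduction relative to the baseline's total cancers.
#' @export
cancer_reduction_pct <- function(baseline, alternative) {
  base <- baseline$outcome$cancers_total
  if (base <= 0) stopf("baseline cancer count is zero; reduction undefined")
  100 * (base - alternative$outcome$cancers_total) / base
}

#' @export
print.brca_icer <- function(x, ...) {
  cat(sprintf("Model %d vs model %d, generation %d (%s scenario)\n",
              x$alternative_model, x$baseline_model, x$generation_index, x$scenario_label))
  cat(sprintf("  incremental cost: %+.2f EUR/year/person (%+.1f M EUR total)\n",
              x$delta_cost_per_year_per_person, x$delta_cost_total / 1e6))
  cat(sprintf("  healthy life-years gained: %+.0f\n", x$delta_hly))
  if (x$icer_defined) cat(sprintf("  ICER: %.2f EUR per healthy life-year\n", x$icer))
  else cat("  ICER: undefined (no life-year difference)\n")
  invisible(x)
}
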