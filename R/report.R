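#' Flatten generation results to a data frame
#'
#' One row per model x generation with every compartment, life-year and cost
#' field at full precision (rounding is applied only by the table builders
#' and report writers). The life-year column is labelled both `hly_lost` and
#' `daly` - the published tables use the latter term for the same quantity.
#'
#' @param results A list of `brca_generation_result` (as returned by
#'   [run_model()]) or the named list from [run_scenario()].
#' @return A `data.frame`.
#' @export
results_to_df <- function(results) {
  if (!is.null(names(results)) && all(grepl("^model", names(results))))
    results <- unlist(results, recursive = FALSE)
  rows <- lapply(results, function(r) {
    data.frame(
      model_id = r$model_id,
      scenario = r$scenario_label,
      generation = r$generation_index,
      eligible_for_testing = r$detection$eligible_for_testing,
      carriers_total = r$detection$carriers_total,
      carriers_detected = r$detection$carriers_detected,
      detected_by_screening = r$detection$carriers_detected_by_screening,
      detected_by_clinical = r$detection$carriers_detected_by_clinical,
      detected_by_cascade = r$detection$carriers_detected_by_cascade,
      carriers_undetected = r$detection$carriers_undetected,
      cancers_aware = r$outcome$cancers_aware,
      cancers_unaware = r$outcome$cancers_unaware,
      cancers_total = r$outcome$cancers_total,
      breast_involved = r$outcome$breast_involved,
      ovarian_involved = r$outcome$ovarian_involved,
      both_cancers = r$outcome$both_cancers,
      hly_lost_daly = r$outcome$hly_lost,
      cost_testing = r$cost$testing,
      cost_screening = r$cost$screening,
      cost_prophylactic_surgery = r$cost$prophylactic_surgery,
      cost_cancer_treatment = r$cost$cancer_treatment,
      cost_follow_up = r$cost$follow_up,
      cost_total = r$cost$total,
      cost_per_year_per_person = r$cost$per_year_per_person,
      awareness_end = r$awareness_end,
      awareness_fraction_end = r$awareness_fraction_end,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write CSV/JSON reports and a run manifest
#'
#' Writes `results.csv` (RFC-4180, dot decimal separator), `results.json`
#' and `manifest.json` into `dir`. The manifest records the package version,
#' timestamp, scenario, model ids, an MD5 hash of the parameter/config
#' objects and the applied cost-rule ledger, so every report file can be
#' traced to the configuration that produced it. The payload files contain
#' no timestamp, so re-running with the same configuration reproduces them
#' byte-identically.
#'
#' @param results Output of [run_scenario()] or a list of
#'   `brca_generation_result`.
#' @param dir Output directory (created if needed).
#' @param params The `brca_scenario` used.
#' @param rules The `brca_cost_rules` applied.
#' @return Invisibly, the manifest as a list.
#' @export
write_reports <- function(results, dir, params, rules = cost_rules()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- results_to_df(results)
  write.csv(df, file.path(dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(df, file.path(dir, "results.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  manifest <- list(
    tool = "brcascreen",
    version = as.character(packageVersion("brcascreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenario = params$scenario_label,
    models = sort(unique(df$model_id)),
    config_hash = config_hash(list(params = unclass(params), rules = unclass(rules))),
    cost_rules = unclass(rules),
    files = c("results.csv", "results.json")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# MD5 of a serialized R object (version-3 serialization, no references).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}
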