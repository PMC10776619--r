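#' Run a carrier-identification model over successive generations
#'
#' Each generation is a fresh cohort of `population_size` 18-year-old women
#' with the scenario's carrier prevalence; the only state carried across
#' generations is the fraction of carriers aware of their status at the end
#' of the previous cycle, which drives cascade testing. Models 2 and 3 run
#' the radiogenomic screen in the generations listed in the configuration
#' (default 1 and 2, with the screen withdrawn in generation 3); model 1 runs
#' identically in every generation.
#'
#' @param params A `brca_scenario`.
#' @param config A `brca_model_config`.
#' @param rules A `brca_cost_rules`.
#' @return A list of `brca_generation_result` objects, one per generation,
#'   each holding `detection`, `outcome`, `cost`, `awareness_end` and
#'   `awareness_fraction_end`.
#' @export
run_model <- function(params, config, rules = cost_rules()) {
  stopifnot(inherits(params, "brca_scenario"), inherits(config, "brca_model_config"))
  if (config$generations < 1) stopf("'generations' must be >= 1")
  C <- carriers_total(params)
  results <- vector("list", config$generations)
  awareness_fraction <- 0
  use_cascade <- !is.null(config$screening) || config$cascade_for_model1

  for (g in seq_len(config$generations)) {
    screening_active <- !is.null(config$screening) &&
      g %in% config$screening_active_generations
    detection <- if (g == 1L || !use_cascade) {
      d <- detect_generation1(params, config)
      d$generation_index <- as.integer(g)
      d
    } else {
      detect_cascade_generation(params, config, awareness_fraction,
                                screening_active, generation_index = g)
    }
    outcome <- expected_cancers(detection, params)
    cost <- total_cost(detection, outcome, params,
                       screening_active = screening_active, rules = rules)
    awareness_end <- awareness_end_of_cycle(detection, outcome$cancers_unaware)
    if (use_cascade) awareness_fraction <- if (C > 0) min(1, awareness_end / C) else 0
    results[[g]] <- structure(list(
      model_id = config$model_id,
      scenario_label = params$scenario_label,
      generation_index = as.integer(g),
      population_size = params$population_size,
      detection = detection,
      outcome = outcome,
      cost = cost,
      awareness_end = awareness_end,
      awareness_fraction_end = if (C > 0) min(1, awareness_end / C) else 0
    ), class = "brca_generation_result")
  }
  results
}

#' Run all three models for one scenario
#'
#' Convenience wrapper running model 1 (clinical criteria alone) and models 2
#' and 3 (adding the radiogenomic screen at current and improved
#' performance) for the same scenario.
#'
#' @param params A `brca_scenario` or a scenario label passed to
#'   [builtin_scenario()].
#' @param generations Number of generations (default 3).
#' @param rules A `brca_cost_rules`.
#' @param sensitivity2 Optional model-2 sensitivity override (e.g. 0.47).
#' @return Named list `model1`, `model2`, `model3`, each a list of
#'   `brca_generation_result`.
#' @export
run_scenario <- function(params, generations = 3, rules = cost_rules(),
                         sensitivity2 = NULL) {
  if (is.character(params)) params <- builtin_scenario(params)
  list(
    model1 = run_model(params, model_config(1, generations = generations), rules),
    model2 = run_model(params, model_config(2, sensitivity = sensitivity2,
                                            generations = generations), rules),
    model3 = run_model(params, model_config(3, generations = generations), rules)
  )
}

#' Results table across models and generations
#'
#' Assembles the published-results layout: one column per model x generation
#' (a single column for model 1, whose results are generation-invariant) and
#' one row per reported quantity, with display rounding applied (integers
#' half away from zero; euros to 2 decimals).
#'
#' @param scenario_results Output of [run_scenario()].
#' @return A `data.frame` with a `quantity` column and one column per model
#'   x generation.
#' @export
build_table2 <- function(scenario_results) {
  if (!length(scenario_results) || !all(c("model1", "model2", "model3") %in% names(scenario_results)))
    stopf("'scenario_results' must be the output of run_scenario()")
  cols <- c(list(model1 = scenario_results$model1[[1]]),
            setNames(scenario_results$model2,
                     paste0("model2_gen", seq_along(scenario_results$model2))),
            setNames(scenario_results$model3,
                     paste0("model3_gen", seq_along(scenario_results$model3))))
  quantity <- c("eligible_for_testing", "carriers_detected", "cancers_aware",
                "cancers_unaware", "cancers_total", "hly_lost_daly",
                "cost_total_billion_eur", "cost_per_year_per_person_eur")
  tab <- data.frame(quantity = quantity, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    r <- cols[[nm]]
    tab[[nm]] <- c(
      round_half_away(r$detection$eligible_for_testing),
      round_half_away(r$detection$carriers_detected),
      round_half_away(r$outcome$cancers_aware),
      round_half_away(r$outcome$cancers_unaware),
      round_half_away(r$outcome$cancers_total),
      round_half_away(r$outcome$hly_lost),
      round_half_away(r$cost$total / 1e9, 2),
      round_half_away(r$cost$per_year_per_person, 2)
    )
  }
  tab
}

#' ICER table across generations and scenarios
#'
#' For each scenario, compares models 2 and 3 against model 1 of the same
#' generation and tabulates the ICER (EUR per healthy life-year gained),
#' mirroring the published three-generation comparison.
#'
#' @param scenario_labels Scenario labels to include.
#' @param generations Number of generations.
#' @param rules A `brca_cost_rules`.
#' @param digits Display rounding for the ICER values (default 0; use `NA`
#'   for unrounded).
#' @return A `data.frame` with columns `generation`, `model` and one column
#'   per scenario.
#' @export
build_table3 <- function(scenario_labels = c("central", "best", "worst"),
                         generations = 3, rules = cost_rules(), digits = 0) {
  rows <- expand.grid(generation = seq_len(generations), model = c(2L, 3L))
  rows <- rows[order(rows$generation, rows$model), ]
  tab <- data.frame(generation = rows$generation, model = rows$model)
  for (lab in scenario_labels) {
    res <- run_scenario(lab, generations = generations, rules = rules)
    vals <- mapply(function(g, m) {
      cmp <- compare_models(res$model1[[g]], res[[paste0("model", m)]][[g]])
      cmp$icer
    }, rows$generation, rows$model)
    tab[[lab]] <- if (is.na(digits)) vals else round_half_away(vals, digits)
  }
  tab
}

#' @export
print.brca_generation_result <- function(x, ...) {
  cat(sprintf("Model %d, %s scenario, generation %d\n",
              x$model_id, x$scenario_label, x$generation_index))
  print(x$detection)
  print(x$outcome)
  print(x$cost)
  cat(sprintf("  aware by cycle end: %.1f (%.1f%% of carriers)\n",
              x$awareness_end, 100 * x$awareness_fraction_end))
  invisible(x)
}
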