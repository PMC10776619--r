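#' @importFrom stats rbinom runif setNames
#' @importFrom utils write.csv packageVersion
NULL

SURGERY_STRATA <- c("none", "rrm_only", "rrso_only", "both")
CANCER_TYPES <- c("breast_only", "ovarian_only", "both_cancers", "no_cancer")
SCENARIO_LABELS <- c("central", "best", "worst")

COST_FIELDS <- c(
  "gyn_visit_us", "genetic_counselling_testing", "rrso", "rrm",
  "ovarian_cancer_surgery", "breast_cancer_mastectomy", "chemotherapy",
  "parp_inhibitor", "radiotherapy", "fu_brca_positive_per_year",
  "fu_brca_negative_or_unknown_per_year"
)

# Italian NHS tariffs (EUR); one value per item, shared by all scenarios.
.builtin_costs <- list(
  gyn_visit_us                         = 51.65,
  genetic_counselling_testing          = 1099.48,
  rrso                                 = 1436.00,
  rrm                                  = 1960.00,
  ovarian_cancer_surgery               = 6791.00,
  breast_cancer_mastectomy             = 3524.45,
  chemotherapy                         = 2226.00,
  parp_inhibitor                       = 82344.00,
  radiotherapy                         = 6000.00,
  fu_brca_positive_per_year            = 198.20,
  fu_brca_negative_or_unknown_per_year = 69.60
)

# Per-scenario epidemiology, surgery uptake, lifetime cancer-risk strata and
# age milestones. Rows of each risk matrix: surgery stratum; columns:
# breast-only / ovarian-only / both cancers / no cancer.
.builtin_scenarios <- list(
  central = list(
    prevalence_carriers = 0.0067,
    clinical_eligibility_rate = 0.0098,
    positivity_among_eligible = 0.10,
    prevalence_in_not_eligible = 0.0058,
    surgery_mix = c(none = 0.2385, rrm_only = 0.2115, rrso_only = 0.2915, both = 0.2585),
    cancer_risks = rbind(
      none      = c(0.4900, 0.0900, 0.2150, 0.2050),
      rrm_only  = c(0.0441, 0.2856, 0.0194, 0.6509),
      rrso_only = c(0.3413, 0.0080, 0.0042, 0.6465),
      both      = c(0.0349, 0.0118, 0.0004, 0.9529)
    ),
    cancer_onset_age = 45, prophylactic_surgery_age = 40
  ),
  best = list(
    prevalence_carriers = 0.0059,
    clinical_eligibility_rate = 0.0047,
    positivity_among_eligible = 0.10,
    prevalence_in_not_eligible = 0.0051,
    surgery_mix = c(none = 0.1584, rrm_only = 0.2016, rrso_only = 0.2816, both = 0.3584),
    cancer_risks = rbind(
      none      = c(0.4820, 0.0870, 0.1481, 0.2831),  # prints 100.02%; renormalised
      rrm_only  = c(0.0096, 0.2320, 0.0030, 0.7554),
      rrso_only = c(0.2309, 0.0072, 0.0022, 0.7597),
      both      = c(0.0062, 0.0093, 0.0001, 0.9844)
    ),
    cancer_onset_age = 60, prophylactic_surgery_age = 45
  ),
  worst = list(
    prevalence_carriers = 0.0077,
    clinical_eligibility_rate = 0.0179,
    positivity_among_eligible = 0.10,
    prevalence_in_not_eligible = 0.0068,
    surgery_mix = c(none = 0.3630, rrm_only = 0.1870, rrso_only = 0.2970, both = 0.1530),
    cancer_risks = rbind(
      none      = c(0.4758, 0.0858, 0.3042, 0.1342),
      rrm_only  = c(0.1808, 0.2744, 0.1156, 0.4292),
      rrso_only = c(0.4675, 0.0385, 0.0395, 0.4545),
      both      = c(0.1582, 0.0646, 0.0134, 0.7638)
    ),
    cancer_onset_age = 35, prophylactic_surgery_age = 35
  )
)

#' Built-in parameter scenarios
#'
#' Returns the fully populated parameter set for one of the three published
#' scenario columns: `central` (average Italian values), `best` (lowest
#' carrier prevalence / latest cancer onset) or `worst` (highest prevalence
#' and cancer risks). Costs are identical across scenarios. The function is
#' pure and deterministic.
#'
#' @param label One of `"central"`, `"best"`, `"worst"`.
#' @param population_size Cohort size; defaults to 274,000, the generation of
#'   18-year-old women in Italy.
#' @return A validated `brca_scenario` object: a list with prevalence and
#'   eligibility rates, `surgery_mix`, `cancer_risks` matrix (rows = surgery
#'   strata, columns = cancer outcome), `costs`, and `timeline`.
#' @export
#' @examples
#' p <- builtin_scenario("central")
#' p$prevalence_carriers
builtin_scenario <- function(label = c("central", "best", "worst"),
                             population_size = 274000) {
  if (!is.character(label) || length(label) != 1 || !label %in% SCENARIO_LABELS) {
    stopf("unknown scenario label '%s'; valid labels are: %s",
          paste(format(label), collapse = ","), paste(SCENARIO_LABELS, collapse = ", "))
  }
  s <- .builtin_scenarios[[label]]
  onset <- s$cancer_onset_age
  p <- list(
    scenario_label = label,
    population_size = population_size,
    prevalence_carriers = s$prevalence_carriers,
    clinical_eligibility_rate = s$clinical_eligibility_rate,
    positivity_among_eligible = s$positivity_among_eligible,
    prevalence_in_not_eligible = s$prevalence_in_not_eligible,
    surgery_mix = s$surgery_mix[SURGERY_STRATA],
    cancer_risks = `colnames<-`(s$cancer_risks[SURGERY_STRATA, ], CANCER_TYPES),
    costs = .builtin_costs,
    timeline = list(
      age_consent = 18,
      cancer_onset_age = onset,
      fu_step1_years = onset - 18,
      fu_step2_years = 80 - onset,
      exit_age = 80,
      cycle_years = 62,
      prophylactic_surgery_age = s$prophylactic_surgery_age
    )
  )
  class(p) <- "brca_scenario"
  validate_scenario(p)
}

#' Validate a scenario parameter set
#'
#' Checks ranges, stratum probability sums, timeline identities and internal
#' consistency. Risk-stratum rows whose printed probabilities sum to 1 within
#' 0.1% are renormalised to exactly 1 with a logged WARN; larger departures
#' are an error. A WARN (not an error) is emitted when the implied carrier
#' prevalence (eligibility x positivity + complement x not-eligible
#' prevalence) departs from the stated prevalence by more than 0.001.
#'
#' @param p A `brca_scenario` object (or bare list with the same fields).
#' @return The validated (possibly renormalised) `brca_scenario`, invisibly
#'   classed.
#' @export
validate_scenario <- function(p) {
  required <- c("scenario_label", "population_size", "prevalence_carriers",
                "clinical_eligibility_rate", "positivity_among_eligible",
                "prevalence_in_not_eligible", "surgery_mix", "cancer_risks",
                "costs", "timeline")
  missing <- setdiff(required, names(p))
  if (length(missing)) stopf("missing parameter field(s): %s", paste(missing, collapse = ", "))

  if (!is.numeric(p$population_size) || p$population_size <= 0)
    stopf("'population_size' must be a positive number")
  for (f in c("prevalence_carriers", "clinical_eligibility_rate",
              "positivity_among_eligible", "prevalence_in_not_eligible"))
    check_prob(p[[f]], f)

  mix <- p$surgery_mix
  if (!all(SURGERY_STRATA %in% names(mix)))
    stopf("'surgery_mix' must be named with: %s", paste(SURGERY_STRATA, collapse = ", "))
  mix <- mix[SURGERY_STRATA]
  if (any(mix < 0 | mix > 1)) stopf("'surgery_mix' entries must be in [0, 1]")
  if (abs(sum(mix) - 1) > 1e-9)
    stopf("surgery mix probabilities must sum to 1 (got %.10f)", sum(mix))
  p$surgery_mix <- mix

  cr <- p$cancer_risks
  if (!is.matrix(cr) || !all(SURGERY_STRATA %in% rownames(cr)) ||
      !all(CANCER_TYPES %in% colnames(cr)))
    stopf("'cancer_risks' must be a matrix with rows %s and columns %s",
          paste(SURGERY_STRATA, collapse = "/"), paste(CANCER_TYPES, collapse = "/"))
  cr <- cr[SURGERY_STRATA, CANCER_TYPES]
  if (any(cr < 0 | cr > 1)) stopf("'cancer_risks' entries must be in [0, 1]")
  for (k in SURGERY_STRATA) {
    s <- sum(cr[k, ])
    if (abs(s - 1) > 1e-9) {
      if (abs(s - 1) <= 1e-3) {
        brca_log("WARN", sprintf(
          "cancer-risk stratum '%s' sums to %.6f; renormalising to 1", k, s))
        cr[k, ] <- cr[k, ] / s
      } else {
        stopf("cancer-risk stratum '%s' probabilities sum to %.6f, not 1", k, s)
      }
    }
  }
  p$cancer_risks <- cr

  cost_missing <- setdiff(COST_FIELDS, names(p$costs))
  if (length(cost_missing)) stopf("missing cost field(s): %s", paste(cost_missing, collapse = ", "))
  for (f in COST_FIELDS) {
    v <- p$costs[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stopf("cost '%s' must be a single non-negative number", f)
  }

  tl <- p$timeline
  tl_fields <- c("age_consent", "cancer_onset_age", "fu_step1_years",
                 "fu_step2_years", "exit_age", "cycle_years", "prophylactic_surgery_age")
  tl_missing <- setdiff(tl_fields, names(tl))
  if (length(tl_missing)) stopf("missing timeline field(s): %s", paste(tl_missing, collapse = ", "))
  if (abs(tl$fu_step1_years - (tl$cancer_onset_age - tl$age_consent)) > 1e-9)
    stopf("timeline: fu_step1_years must equal cancer_onset_age - age_consent")
  if (abs(tl$fu_step2_years - (tl$exit_age - tl$cancer_onset_age)) > 1e-9)
    stopf("timeline: fu_step2_years must equal exit_age - cancer_onset_age")
  if (abs(tl$cycle_years - (tl$exit_age - tl$age_consent)) > 1e-9)
    stopf("timeline: cycle_years must equal exit_age - age_consent")

  implied <- p$clinical_eligibility_rate * p$positivity_among_eligible +
    (1 - p$clinical_eligibility_rate) * p$prevalence_in_not_eligible
  if (abs(implied - p$prevalence_carriers) > 0.001) {
    brca_log("WARN", sprintf(
      "implied carrier prevalence %.5f departs from stated prevalence %.5f by > 0.001",
      implied, p$prevalence_carriers))
  }

  class(p) <- "brca_scenario"
  p
}

#' Load scenario parameters from a YAML file
#'
#' Reads a flat, human-editable YAML configuration mirroring the published
#' parameter table (see the packaged `central.yaml`, `best.yaml`,
#' `worst.yaml` under `extdata`) and validates it.
#'
#' @param path Path to a YAML file.
#' @return A validated `brca_scenario`.
#' @seealso [write_parameters()] for the inverse; round-tripping is exact.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stopf("parameter file not found: %s", path)
  raw <- yaml::read_yaml(path)
  required <- c("scenario_label", "population_size", "prevalence_carriers",
                "clinical_eligibility_rate", "positivity_among_eligible",
                "prevalence_in_not_eligible", "surgery_mix", "cancer_risks",
                "costs", "timeline")
  missing <- setdiff(required, names(raw))
  if (length(missing)) stopf("missing parameter field(s): %s", paste(missing, collapse = ", "))
  cr <- raw$cancer_risks
  bad <- setdiff(SURGERY_STRATA, names(cr))
  if (length(bad)) stopf("cancer_risks: missing stratum/strata %s", paste(bad, collapse = ", "))
  mat <- t(vapply(SURGERY_STRATA, function(k) {
    row <- cr[[k]]
    miss <- setdiff(CANCER_TYPES, names(row))
    if (length(miss)) stopf("cancer_risks stratum '%s': missing %s", k, paste(miss, collapse = ", "))
    unlist(row[CANCER_TYPES])
  }, numeric(4)))
  colnames(mat) <- CANCER_TYPES
  p <- raw
  p$surgery_mix <- unlist(raw$surgery_mix)
  p$cancer_risks <- mat
  p$costs <- raw$costs
  class(p) <- "brca_scenario"
  validate_scenario(p)
}

#' Write scenario parameters to a YAML file
#'
#' @param p A `brca_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "brca_scenario"))
  out <- unclass(p)
  out$surgery_mix <- as.list(p$surgery_mix)
  out$cancer_risks <- lapply(setNames(SURGERY_STRATA, SURGERY_STRATA), function(k)
    as.list(setNames(p$cancer_risks[k, ], CANCER_TYPES)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Model configuration
#'
#' Defines which carrier-identification strategy to run. Model 1 is clinical
#' criteria / family history alone; model 2 adds the radiogenomic ultrasound
#' classifier at its current performance (49% sensitivity, 87% specificity);
#' model 3 uses the classifier at its projected improved performance (80%
#' sensitivity, 95% specificity). For models 2 and 3 the screening programme
#' runs by default in generations 1 and 2 and is withdrawn in generation 3,
#' where cascade testing of relatives carries detection.
#'
#' @param model_id 1, 2 or 3.
#' @param sensitivity,specificity Override the radiogenomic classifier
#'   performance (ignored for model 1). The alternative published figure of
#'   47% sensitivity for model 2 can be set here.
#' @param generations Number of generations to simulate (default 3).
#' @param screening_active_generations Generation indices in which the
#'   radiogenomic screen is offered; default `c(1, 2)` for models 2/3,
#'   `integer(0)` for model 1.
#' @param residual_rule How detection probabilities combine for carriers not
#'   flagged by cascade in generations >= 2 while screening is active:
#'   `"additive"` (sensitivity + clinical detection rate, the default, which
#'   reproduces the published generation-2 counts) or `"union"`
#'   (independent-overlap deduction).
#' @param residual_clinical_without_screening If `TRUE`, carriers not flagged
#'   by cascade can still be detected through clinical criteria after
#'   screening is withdrawn. Default `FALSE`: family-history criteria are
#'   subsumed by cascade testing once awareness has propagated, which
#'   reproduces the published generation-3 column.
#' @param cascade_for_model1 If `TRUE`, model 1 also accrues cascade
#'   awareness across generations (exploratory; default `FALSE`, matching the
#'   published single model-1 column).
#' @return A `brca_model_config` list.
#' @export
model_config <- function(model_id,
                         sensitivity = NULL,
                         specificity = NULL,
                         generations = 3,
                         screening_active_generations = NULL,
                         residual_rule = c("additive", "union"),
                         residual_clinical_without_screening = FALSE,
                         cascade_for_model1 = FALSE) {
  if (!model_id %in% 1:3) stopf("'model_id' must be 1, 2 or 3")
  if (!is.numeric(generations) || generations < 1) stopf("'generations' must be >= 1")
  residual_rule <- match.arg(residual_rule)
  screening <- NULL
  if (model_id == 1) {
    if (!is.null(sensitivity) || !is.null(specificity))
      stopf("model 1 has no screening test; do not supply sensitivity/specificity")
    if (is.null(screening_active_generations)) screening_active_generations <- integer(0)
    if (length(screening_active_generations))
      stopf("model 1 has no screening test; screening_active_generations must be empty")
  } else {
    defaults <- if (model_id == 2) c(0.49, 0.87) else c(0.80, 0.95)
    screening <- list(
      sensitivity = if (is.null(sensitivity)) defaults[1] else sensitivity,
      specificity = if (is.null(specificity)) defaults[2] else specificity
    )
    check_prob(screening$sensitivity, "sensitivity")
    check_prob(screening$specificity, "specificity")
    if (is.null(screening_active_generations)) screening_active_generations <- c(1L, 2L)
  }
  structure(list(
    model_id = as.integer(model_id),
    screening = screening,
    generations = as.integer(generations),
    screening_active_generations = as.integer(screening_active_generations),
    residual_rule = residual_rule,
    residual_clinical_without_screening = isTRUE(residual_clinical_without_screening),
    cascade_for_model1 = isTRUE(cascade_for_model1)
  ), class = "brca_model_config")
}

#' @export
print.brca_scenario <- function(x, ...) {
  cat(sprintf("BRCA1/2 screening scenario '%s'\n", x$scenario_label))
  cat(sprintf("  population: %s women (age %d-%d, %d-year cycle)\n",
              format(x$population_size, big.mark = ","),
              x$timeline$age_consent, x$timeline$exit_age, x$timeline$cycle_years))
  cat(sprintf("  carrier prevalence: %.2f%%; clinically eligible: %.2f%% (positivity %.0f%%)\n",
              100 * x$prevalence_carriers, 100 * x$clinical_eligibility_rate,
              100 * x$positivity_among_eligible))
  cat(sprintf("  cancer onset age: %d; surgery uptake (none/RRM/RRSO/both): %s\n",
              x$timeline$cancer_onset_age,
              paste(sprintf("%.1f%%", 100 * x$surgery_mix), collapse = "/")))
  invisible(x)
}

#' @export
print.brca_model_config <- function(x, ...) {
  cat(sprintf("Model %d", x$model_id))
  if (is.null(x$screening)) {
    cat(" (clinical criteria / family history only)\n")
  } else {
    cat(sprintf(" (radiogenomic screen: sens %.0f%%, spec %.0f%%; active in generations %s)\n",
                100 * x$screening$sensitivity, 100 * x$screening$specificity,
                paste(x$screening_active_generations, collapse = ",")))
  }
  cat(sprintf("  generations: %d; residual rule: %s\n", x$generations, x$residual_rule))
  invisible(x)
}
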