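#' Expected number of BRCA1/2 carriers in the cohort
#'
#' @param params A `brca_scenario`.
#' @return Expected carrier count `C = population_size * prevalence_carriers`,
#'   unrounded (central scenario: 274,000 x 0.0067 = 1,835.8).
#' @export
carriers_total <- function(params) {
  stopifnot(inherits(params, "brca_scenario"))
  params$population_size * params$prevalence_carriers
}

#' Probability that a carrier is detected through clinical criteria
#'
#' Clinical criteria / family history select a fraction of the population for
#' genetic testing, of whom 10% test positive. Dividing the resulting
#' positives by the total carrier count gives the per-carrier probability of
#' detection through the clinical route (central: 268.52 / 1,835.8 = 0.1463).
#'
#' @param params A `brca_scenario`.
#' @return Probability `r_clin` in [0, 1].
#' @export
clinical_detection_rate <- function(params) {
  C <- carriers_total(params)
  if (C == 0) stopf("carrier count is zero; clinical detection rate undefined")
  r <- params$population_size * params$clinical_eligibility_rate *
    params$positivity_among_eligible / C
  min(r, 1)
}

new_detection_result <- function(generation_index, eligible, by_screening,
                                 by_clinical, by_cascade, C) {
  detected <- by_screening + by_clinical + by_cascade
  structure(list(
    generation_index = as.integer(generation_index),
    eligible_for_testing = eligible,
    carriers_total = C,
    carriers_detected = detected,
    carriers_detected_by_screening = by_screening,
    carriers_detected_by_clinical = by_clinical,
    carriers_detected_by_cascade = by_cascade,
    carriers_undetected = C - detected
  ), class = "brca_detection")
}

#' First-generation carrier detection
#'
#' Model 1 detects carriers only through clinical criteria / family history.
#' Models 2 and 3 additionally screen the whole cohort with the radiogenomic
#' ultrasound classifier; carriers are detected if they screen positive, or
#' screen negative but meet clinical criteria (union rule), so the clinical
#' route contributes only the screen-negative clinically eligible carriers.
#'
#' The eligible-for-testing count for models 2/3 is the union of screen
#' positives and screen-negative clinically eligible women. It is
#' structurally derived and approximate: the published counts rest on
#' supplementary assumptions not in the main text.
#'
#' @param params A `brca_scenario`.
#' @param config A `brca_model_config`.
#' @return A `brca_detection` result with the detected count split by route.
#' @export
detect_generation1 <- function(params, config) {
  stopifnot(inherits(params, "brca_scenario"), inherits(config, "brca_model_config"))
  C <- carriers_total(params)
  N <- params$population_size
  e <- params$clinical_eligibility_rate
  r_clin <- if (C > 0) clinical_detection_rate(params) else 0
  screening_on <- !is.null(config$screening) && 1L %in% config$screening_active_generations

  if (!screening_on) {
    return(new_detection_result(1L, eligible = N * e,
                                by_screening = 0, by_clinical = r_clin * C,
                                by_cascade = 0, C = C))
  }
  sens <- config$screening$sensitivity
  spec <- config$screening$specificity
  by_screening <- C * sens
  by_clinical <- r_clin * C * (1 - sens)
  clin_elig_noncarrier <- N * e - r_clin * C
  eligible <- (C * sens + (N - C) * (1 - spec)) +
    clin_elig_noncarrier * spec + (r_clin * C) * (1 - sens)
  new_detection_result(1L, eligible, by_screening, by_clinical, 0, C)
}

#' Cascade-generation carrier detection
#'
#' In generations after the first, carriers whose relatives became aware in
#' the previous generation are flagged by family history and access genetic
#' testing through cascade testing; at cohort level this is the previous
#' generation's end-of-cycle awareness fraction applied to the carrier pool.
#' Residual carriers (from still-unaware families) can be detected by the
#' radiogenomic screen while it is active; detection probabilities for the
#' residual pool combine additively by default (see [model_config()]). Once
#' screening is withdrawn the residual pool, having by construction no
#' family-history flag, is undetected before cancer onset unless
#' `residual_clinical_without_screening` is set.
#'
#' @param params A `brca_scenario`.
#' @param config A `brca_model_config`.
#' @param prev_awareness_fraction Fraction of carriers aware at the end of
#'   the previous generation's cycle, in [0, 1].
#' @param screening_active Whether the radiogenomic screen runs in this
#'   generation.
#' @param generation_index Generation number (>= 2) recorded in the result.
#' @return A `brca_detection` result; total detected is capped at the carrier
#'   count.
#' @export
detect_cascade_generation <- function(params, config, prev_awareness_fraction,
                                      screening_active, generation_index = 2L) {
  stopifnot(inherits(params, "brca_scenario"), inherits(config, "brca_model_config"))
  check_prob(prev_awareness_fraction, "prev_awareness_fraction")
  C <- carriers_total(params)
  N <- params$population_size
  e <- params$clinical_eligibility_rate
  r_clin <- if (C > 0) clinical_detection_rate(params) else 0
  f <- prev_awareness_fraction

  by_cascade <- C * f
  R <- C * (1 - f)
  clin_elig_noncarrier <- N * e - r_clin * C

  if (screening_active) {
    if (is.null(config$screening))
      stopf("screening_active = TRUE but model %d has no screening test", config$model_id)
    sens <- config$screening$sensitivity
    spec <- config$screening$specificity
    p_res <- switch(config$residual_rule,
      additive = min(1, sens + r_clin),
      union = 1 - (1 - sens) * (1 - r_clin)
    )
    by_screening <- R * sens
    by_clinical <- R * (p_res - sens)
    eligible <- by_cascade + R * sens + (N - C) * (1 - spec) +
      clin_elig_noncarrier * spec + R * r_clin * (1 - sens)
  } else {
    p_res <- if (config$residual_clinical_without_screening) r_clin else 0
    by_screening <- 0
    by_clinical <- R * p_res
    eligible <- by_cascade + clin_elig_noncarrier + R * p_res
  }
  brca_log_once("eligible_approx", "WARN",
    "eligible-for-testing counts in cascade generations use the structural union ",
    "formula; published counts rest on supplementary assumptions and differ")

  res <- new_detection_result(generation_index, eligible, by_screening, by_clinical,
                              by_cascade, C)
  if (res$carriers_detected > C) {  # cap after the additive rule
    excess <- res$carriers_detected - C
    res$carriers_detected_by_clinical <- max(0, res$carriers_detected_by_clinical - excess)
    res$carriers_detected <- C
    res$carriers_undetected <- 0
  }
  res
}

#' Carriers aware of their status by the end of the cycle
#'
#' Carriers never detected before cancer onset learn their status at cancer
#' diagnosis, so end-of-cycle awareness adds the expected cancers among
#' undetected carriers to the detected count.
#'
#' @param detection A `brca_detection`.
#' @param cancers_unaware Expected cancer count among undetected carriers;
#'   must not exceed the undetected carrier count.
#' @return Expected count of carriers aware by cycle end.
#' @export
awareness_end_of_cycle <- function(detection, cancers_unaware) {
  stopifnot(inherits(detection, "brca_detection"))
  if (!is.numeric(cancers_unaware) || cancers_unaware < 0)
    stopf("'cancers_unaware' must be non-negative")
  if (cancers_unaware > detection$carriers_undetected + 1e-9)
    stopf("'cancers_unaware' (%.3f) exceeds undetected carriers (%.3f)",
          cancers_unaware, detection$carriers_undetected)
  detection$carriers_detected + cancers_unaware
}

#' @export
print.brca_detection <- function(x, ...) {
  cat(sprintf("Generation %d detection: %.1f of %.1f carriers (%.1f%%)\n",
              x$generation_index, x$carriers_detected, x$carriers_total,
              100 * x$carriers_detected / max(x$carriers_total, 1e-12)))
  cat(sprintf("  by screening %.1f | clinical %.1f | cascade %.1f; eligible for testing %.1f\n",
              x$carriers_detected_by_screening, x$carriers_detected_by_clinical,
              x$carriers_detected_by_cascade, x$eligible_for_testing))
  invisible(x)
}
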