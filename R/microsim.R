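#' Simulate an individual-level cohort
#'
#' Draws one realisation of the cohort that the deterministic engine models
#' in expectation: carrier status ~ Bernoulli(prevalence); clinical
#' eligibility with carrier-dependent probabilities chosen so the marginal
#' eligibility rate and the 10% positivity among the eligible are matched
#' exactly (P(eligible | carrier) is the clinical detection rate,
#' P(eligible | non-carrier) its complement-consistent rate); radiogenomic
#' screen results ~ Bernoulli(sensitivity) for carriers and
#' Bernoulli(1 - specificity) for non-carriers when screening is active;
#' detection by the generation-1 union rule (or the cascade/residual rules
#' for later generations, with `prev_awareness_fraction` as the per-carrier
#' probability of an aware relative); surgery choice ~ multinomial over the
#' uptake mix for detected carriers; cancer outcome ~ multinomial over the
#' carrier's surgery stratum risk row.
#'
#' @param params A `brca_scenario`.
#' @param config A `brca_model_config`.
#' @param seed Integer seed; required, there is no implicit global
#'   randomness.
#' @param generation_index Generation to simulate (default 1).
#' @param prev_awareness_fraction Carrier awareness fraction at the end of
#'   the previous generation (used when `generation_index >= 2`).
#' @return A `data.frame` with one row per woman: `is_carrier`,
#'   `clinically_eligible`, `screen_result` (NA when not screened), `tested`,
#'   `detected_before_cancer`, `surgery_stratum`, `cancer_type`,
#'   `aware_at_end`.
#' @export
simulate_cohort <- function(params, config, seed, generation_index = 1L,
                            prev_awareness_fraction = 0) {
  stopifnot(inherits(params, "brca_scenario"), inherits(config, "brca_model_config"))
  if (missing(seed) || is.null(seed)) stopf("'seed' is required for simulate_cohort()")
  set.seed(as.integer(seed))
  N <- as.integer(params$population_size)
  C <- carriers_total(params)
  r_clin <- if (C > 0) clinical_detection_rate(params) else 0
  # carrier-dependent eligibility rates implied by the marginal rates
  p_elig_noncarrier <- if (N - C > 0)
    max(0, (N * params$clinical_eligibility_rate - r_clin * C) / (N - C)) else 0

  is_carrier <- runif(N) < params$prevalence_carriers
  clinically_eligible <- runif(N) < ifelse(is_carrier, r_clin, p_elig_noncarrier)

  screening_active <- !is.null(config$screening) &&
    generation_index %in% config$screening_active_generations
  screen_result <- rep(NA, N)
  if (screening_active) {
    sens <- config$screening$sensitivity
    spec <- config$screening$specificity
    screen_result <- runif(N) < ifelse(is_carrier, sens, 1 - spec)
  }

  cascade_flag <- rep(FALSE, N)
  if (generation_index >= 2L) {
    check_prob(prev_awareness_fraction, "prev_awareness_fraction")
    cascade_flag <- is_carrier & (runif(N) < prev_awareness_fraction)
  }

  if (generation_index == 1L) {
    detected <- is_carrier &
      ((screening_active & screen_result %in% TRUE) | clinically_eligible)
    tested <- (screening_active & screen_result %in% TRUE) | clinically_eligible
  } else {
    # residual (non-cascade) carriers detected with the cohort engine's
    # residual probability, drawn directly (the additive rule is a single
    # probability, not an OR of independent flags)
    if (screening_active) {
      sens <- config$screening$sensitivity
      p_res <- switch(config$residual_rule,
        additive = min(1, sens + r_clin),
        union = 1 - (1 - sens) * (1 - r_clin))
    } else {
      p_res <- if (config$residual_clinical_without_screening) r_clin else 0
    }
    residual_detected <- is_carrier & !cascade_flag & (runif(N) < p_res)
    detected <- cascade_flag | residual_detected
    tested <- detected | (screening_active & screen_result %in% TRUE) | clinically_eligible
  }

  surgery_stratum <- rep("not_applicable", N)
  idx <- which(detected)
  if (length(idx)) {
    surgery_stratum[idx] <- sample(SURGERY_STRATA, length(idx), replace = TRUE,
                                   prob = params$surgery_mix[SURGERY_STRATA])
  }

  cancer_type <- rep("none", N)
  carrier_idx <- which(is_carrier)
  if (length(carrier_idx)) {
    stratum <- ifelse(detected[carrier_idx], surgery_stratum[carrier_idx], "none")
    for (k in SURGERY_STRATA) {
      sub <- carrier_idx[stratum == k]
      if (length(sub)) {
        draw <- sample(CANCER_TYPES, length(sub), replace = TRUE,
                       prob = params$cancer_risks[k, CANCER_TYPES])
        cancer_type[sub] <- ifelse(draw == "no_cancer", "none", draw)
      }
    }
  }

  aware_at_end <- detected | (is_carrier & cancer_type != "none")
  data.frame(
    id = seq_len(N),
    is_carrier = is_carrier,
    clinically_eligible = clinically_eligible,
    screen_result = screen_result,
    tested = tested,
    detected_before_cancer = detected,
    surgery_stratum = surgery_stratum,
    cancer_type = cancer_type,
    aware_at_end = aware_at_end,
    stringsAsFactors = FALSE
  )
}

summarize_cohort <- function(cohort) {
  carrier <- cohort$is_carrier
  detected <- cohort$detected_before_cancer
  cancer <- cohort$cancer_type != "none" & carrier
  c(
    carriers = sum(carrier),
    eligible_for_testing = sum(cohort$tested),
    carriers_detected = sum(detected),
    cancers_aware = sum(cancer & detected),
    cancers_unaware = sum(cancer & !detected),
    cancers_total = sum(cancer),
    aware_at_end = sum(cohort$aware_at_end & carrier)
  )
}

#' Validate the cohort engine against Monte Carlo replicates
#'
#' Runs [simulate_cohort()] `n_replicates` times (child seed for replicate
#' `i` is `seed + 7919 * i`) and compares, for each compartment, the
#' replicate mean against the deterministic cohort expectation. Because the
#' simulator draws from exactly the distributions whose expectations the
#' cohort engine computes, each cohort value should fall within 3 Monte
#' Carlo standard errors of the replicate mean.
#'
#' @param params A `brca_scenario`.
#' @param config A `brca_model_config`.
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Root seed.
#' @param generation_index Generation to validate (default 1).
#' @param prev_awareness_fraction Awareness carried into this generation.
#' @return A `brca_microsim_summary`: a `data.frame` with one row per
#'   compartment (`expected`, `mc_mean`, `mc_se`, `z`, `within_3se`), plus
#'   attributes `n_replicates`, `seed` and the per-replicate count matrix.
#' @export
validate_against_cohort <- function(params, config, n_replicates = 100, seed = 1,
                                    generation_index = 1L,
                                    prev_awareness_fraction = 0) {
  if (n_replicates < 2) stopf("'n_replicates' must be >= 2")
  reps <- t(vapply(seq_len(n_replicates), function(i) {
    summarize_cohort(simulate_cohort(params, config, seed = seed + 7919 * i,
                                     generation_index = generation_index,
                                     prev_awareness_fraction = prev_awareness_fraction))
  }, numeric(7)))

  screening_active <- !is.null(config$screening) &&
    generation_index %in% config$screening_active_generations
  detection <- if (generation_index == 1L) detect_generation1(params, config)
  else detect_cascade_generation(params, config, prev_awareness_fraction,
                                 screening_active, generation_index)
  outcome <- expected_cancers(detection, params)
  expected <- c(
    carriers = carriers_total(params),
    eligible_for_testing = detection$eligible_for_testing,
    carriers_detected = detection$carriers_detected,
    cancers_aware = outcome$cancers_aware,
    cancers_unaware = outcome$cancers_unaware,
    cancers_total = outcome$cancers_total,
    aware_at_end = awareness_end_of_cycle(detection, outcome$cancers_unaware)
  )

  mc_mean <- colMeans(reps)
  mc_se <- apply(reps, 2, stats::sd) / sqrt(n_replicates)
  z <- ifelse(mc_se > 0, (expected - mc_mean) / mc_se, 0)
  out <- data.frame(
    compartment = names(expected),
    expected = as.numeric(expected),
    mc_mean = as.numeric(mc_mean),
    mc_se = as.numeric(mc_se),
    z = as.numeric(z),
    within_3se = abs(z) <= 3,
    stringsAsFactors = FALSE
  )
  flagged <- out$compartment[!out$within_3se]
  if (length(flagged))
    brca_log("WARN", "compartment(s) outside 3 SE of the Monte Carlo mean: ",
             paste(flagged, collapse = ", "))
  structure(out, class = c("brca_microsim_summary", "data.frame"),
            n_replicates = n_replicates, seed = seed, replicates = reps)
}
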