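# Independent closed-form oracle for the central scenario, computed by plain
# arithmetic straight from the published parameter table (kept free of the
# package's own compartment code).
central_oracle <- local({
  N <- 274000
  C <- N * 0.0067                      # expected carriers
  clin_detected <- N * 0.0098 * 0.10   # clinically eligible women x 10% positivity
  r_clin <- clin_detected / C
  p_cancer_none <- 0.49 + 0.09 + 0.215
  stratum_totals <- c(
    none = 0.49 + 0.09 + 0.215,
    rrm_only = 0.0441 + 0.2856 + 0.0194,
    rrso_only = 0.3413 + 0.008 + 0.0042,
    both = 0.0349 + 0.0118 + 0.0004
  )
  mix <- c(none = 0.2385, rrm_only = 0.2115, rrso_only = 0.2915, both = 0.2585)
  p_cancer_aware <- sum(mix * stratum_totals)
  list(
    N = N, C = C, clin_detected = clin_detected, r_clin = r_clin,
    p_cancer_none = p_cancer_none, p_cancer_aware = p_cancer_aware,
    m2_screen = C * 0.49,
    m2_clinical = clin_detected * (1 - 0.49),
    m3_detected = C * 0.80 + clin_detected * (1 - 0.80),
    surgery_per_carrier = 0.2585 * (1436 + 1960) + 0.2915 * 1436 + 0.2115 * 1960,
    ovarian_bundle = 6791 + 2226 + 82344,
    breast_bundle = 3524.45 + 2226 + 6000
  )
})

quiet_scenario <- function(label = "central", ...) {
  suppressMessages(builtin_scenario(label, ...))
}

quiet_run <- function(label = "central", ...) {
  suppressMessages(run_scenario(label, ...))
}
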