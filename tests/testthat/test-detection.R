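test_that("expected carrier counts follow population x prevalence", {
  o <- central_oracle
  expect_equal(carriers_total(quiet_scenario("central")), o$C)        # 1,835.8
  expect_equal(carriers_total(quiet_scenario("best")), 274000 * 0.0059)  # 1,616.6
  p0 <- quiet_scenario("central"); p0$prevalence_carriers <- 0
  p0 <- suppressMessages(validate_scenario(p0))
  expect_equal(carriers_total(p0), 0)
  expect_error(clinical_detection_rate(p0), "zero")
})

test_that("clinical detection rate matches eligible x positivity / carriers", {
  o <- central_oracle
  p <- quiet_scenario("central")
  expect_equal(clinical_detection_rate(p), o$r_clin, tolerance = 1e-12)
  expect_equal(o$r_clin, 0.1463, tolerance = 1e-3)
  pz <- p; pz$positivity_among_eligible <- 0
  pz <- suppressMessages(validate_scenario(pz))
  expect_equal(clinical_detection_rate(pz), 0)
})

test_that("generation-1 detection reproduces the per-route decomposition", {
  o <- central_oracle
  p <- quiet_scenario("central")

  d1 <- detect_generation1(p, model_config(1))
  expect_equal(d1$carriers_detected, o$clin_detected)          # 268.52 -> 269
  expect_equal(d1$eligible_for_testing, o$N * 0.0098)          # 2,685.2
  expect_equal(d1$carriers_detected_by_screening, 0)

  d2 <- detect_generation1(p, model_config(2))
  expect_equal(d2$carriers_detected_by_screening, o$m2_screen)  # 899.5 -> 900
  expect_equal(d2$carriers_detected_by_clinical, o$m2_clinical) # 136.9
  expect_equal(d2$carriers_detected, o$m2_screen + o$m2_clinical) # 1,036.5

  d3 <- detect_generation1(p, model_config(3))
  expect_equal(d3$carriers_detected, o$m3_detected)             # 1,522.3

  # route components always add up to the total and undetected complements C
  for (d in list(d1, d2, d3)) {
    expect_equal(d$carriers_detected,
                 d$carriers_detected_by_screening + d$carriers_detected_by_clinical +
                   d$carriers_detected_by_cascade, tolerance = 1e-9)
    expect_equal(d$carriers_undetected, o$C - d$carriers_detected, tolerance = 1e-9)
  }
})

test_that("a perfect screen detects every carrier", {
  p <- quiet_scenario("central")
  d <- detect_generation1(p, model_config(2, sensitivity = 1, specificity = 1))
  expect_equal(d$carriers_detected, carriers_total(p), tolerance = 1e-9)
  expect_equal(d$carriers_undetected, 0, tolerance = 1e-9)
  # clinically eligible non-carriers still access testing through the
  # family-history route even when the screen never misfires
  clin_elig_noncarrier <- p$population_size * p$clinical_eligibility_rate -
    clinical_detection_rate(p) * carriers_total(p)
  expect_equal(d$eligible_for_testing, carriers_total(p) + clin_elig_noncarrier,
               tolerance = 1e-9)
})

test_that("cascade generations combine awareness carry-over with residual detection", {
  o <- central_oracle
  p <- quiet_scenario("central")
  cfg <- model_config(2)

  # generation-1 engine output feeds the oracle's own recursion
  detected1 <- o$m2_screen + o$m2_clinical
  unaware_cancers1 <- (o$C - detected1) * o$p_cancer_none
  f1 <- (detected1 + unaware_cancers1) / o$C

  d2 <- suppressMessages(
    detect_cascade_generation(p, cfg, f1, screening_active = TRUE, generation_index = 2L))
  expected2 <- o$C * f1 + o$C * (1 - f1) * (0.49 + o$r_clin)
  expect_equal(d2$carriers_detected, expected2, tolerance = 1e-9)   # 1,776.2
  expect_equal(round_half_away(d2$carriers_detected), 1776)

  # screening withdrawn: detection is carried by cascade alone
  unaware_cancers2 <- (o$C - expected2) * o$p_cancer_none
  f2 <- (expected2 + unaware_cancers2) / o$C
  d3 <- suppressMessages(
    detect_cascade_generation(p, cfg, f2, screening_active = FALSE, generation_index = 3L))
  expect_equal(d3$carriers_detected, o$C * f2, tolerance = 1e-9)
  expect_equal(round_half_away(d3$carriers_detected), 1824)

  # the published-rule alternative: residual clinical detection stays on
  cfg_alt <- model_config(2, residual_clinical_without_screening = TRUE)
  d3b <- suppressMessages(
    detect_cascade_generation(p, cfg_alt, f2, screening_active = FALSE))
  expect_equal(d3b$carriers_detected, o$C * f2 + o$C * (1 - f2) * o$r_clin,
               tolerance = 1e-9)

  # saturation: full awareness detects exactly C
  dsat <- suppressMessages(detect_cascade_generation(p, cfg, 1, screening_active = TRUE))
  expect_equal(dsat$carriers_detected, o$C, tolerance = 1e-12)
})

test_that("detection is monotone in sensitivity and awareness, and capped at C", {
  p <- quiet_scenario("central")
  C <- carriers_total(p)
  prev <- -Inf
  for (s in seq(0, 1, by = 0.1)) {
    d <- detect_generation1(p, model_config(2, sensitivity = s))
    expect_gte(d$carriers_detected, prev)
    expect_lte(d$carriers_detected, C + 1e-9)
    prev <- d$carriers_detected
  }
  cfg <- model_config(2)
  prev <- -Inf
  for (f in seq(0, 1, by = 0.1)) {
    d <- suppressMessages(detect_cascade_generation(p, cfg, f, screening_active = TRUE))
    expect_gte(d$carriers_detected, prev - 1e-12)
    expect_lte(d$carriers_detected, C + 1e-9)
    prev <- d$carriers_detected
  }
})

test_that("awareness accounting validates its inputs", {
  p <- quiet_scenario("central")
  d <- detect_generation1(p, model_config(2))
  expect_error(awareness_end_of_cycle(d, -1), "non-negative")
  expect_error(awareness_end_of_cycle(d, d$carriers_undetected + 5), "exceeds")
  expect_equal(awareness_end_of_cycle(d, 0), d$carriers_detected)
})
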