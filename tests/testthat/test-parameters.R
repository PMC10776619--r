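test_that("built-in scenarios are valid, deterministic and sum-consistent", {
  for (lab in c("central", "best", "worst")) {
    p1 <- quiet_scenario(lab)
    p2 <- quiet_scenario(lab)
    expect_identical(p1, p2)
    expect_s3_class(p1, "brca_scenario")
    expect_equal(sum(p1$surgery_mix), 1, tolerance = 1e-12)
    for (k in rownames(p1$cancer_risks))
      expect_equal(sum(p1$cancer_risks[k, ]), 1, tolerance = 1e-9)
    tl <- p1$timeline
    expect_equal(tl$fu_step1_years, tl$cancer_onset_age - tl$age_consent)
    expect_equal(tl$fu_step2_years, tl$exit_age - tl$cancer_onset_age)
    expect_equal(tl$cycle_years, tl$fu_step1_years + tl$fu_step2_years)
  }
  expect_equal(quiet_scenario("central")$prevalence_carriers, 0.0067)
  expect_equal(quiet_scenario("worst")$clinical_eligibility_rate, 0.0179)
  best <- quiet_scenario("best")
  expect_equal(best$timeline$cancer_onset_age, 60)
  expect_equal(best$timeline$fu_step2_years, 20)
})

test_that("unknown scenario labels raise an error naming the valid ones", {
  expect_error(builtin_scenario("median"), "central.*best.*worst")
})

test_that("the best-case no-surgery risk row is renormalised with a WARN", {
  expect_message(builtin_scenario("best"), "renormalising")
  best <- quiet_scenario("best")
  expect_equal(sum(best$cancer_risks["none", ]), 1, tolerance = 1e-12)
  # renormalisation preserves proportions of the printed values
  expect_equal(best$cancer_risks["none", "breast_only"], 0.4820 / 1.0002,
               tolerance = 1e-12)
})

test_that("YAML round-trip reproduces every scenario", {
  for (lab in c("central", "best", "worst")) {
    p <- quiet_scenario(lab)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_parameters(p, f)
    q <- suppressMessages(load_parameters(f))
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
})

test_that("packaged YAML fixtures equal the built-in scenarios", {
  for (lab in c("central", "best", "worst")) {
    f <- system.file("extdata", paste0(lab, ".yaml"), package = "brcascreen")
    expect_true(nzchar(f))
    expect_equal(unclass(suppressMessages(load_parameters(f))),
                 unclass(quiet_scenario(lab)), tolerance = 1e-12)
  }
})

test_that("validation rejects malformed parameter files with named errors", {
  p <- quiet_scenario("central")
  f <- withr::local_tempfile(fileext = ".yaml")

  bad <- p; bad$costs$parp_inhibitor <- NULL
  write_parameters(structure(bad, class = "brca_scenario"), f)
  expect_error(load_parameters(f), "parp_inhibitor")

  bad <- p; bad$surgery_mix[["none"]] <- 0.5
  write_parameters(structure(bad, class = "brca_scenario"), f)
  expect_error(load_parameters(f), "sum to 1")

  bad <- p; bad$prevalence_carriers <- 1.2
  write_parameters(structure(bad, class = "brca_scenario"), f)
  expect_error(load_parameters(f), "prevalence_carriers")

  bad <- p; bad$cancer_risks["none", ] <- c(0.6, 0.2, 0.15, 0.15)
  write_parameters(structure(bad, class = "brca_scenario"), f)
  expect_error(load_parameters(f), "none")

  expect_error(load_parameters(tempfile()), "not found")
})

test_that("the implied-prevalence consistency check WARNs without erroring", {
  p <- quiet_scenario("central")
  p$prevalence_carriers <- 0.01   # implied value is ~0.0067
  expect_message(validate_scenario(p), "implied carrier prevalence")
  # built-in columns are internally consistent: no WARN
  expect_no_message(validate_scenario(quiet_scenario("central")))
})

test_that("model configurations enforce screening presence per model", {
  m1 <- model_config(1)
  expect_null(m1$screening)
  expect_length(m1$screening_active_generations, 0)
  m2 <- model_config(2)
  expect_equal(m2$screening$sensitivity, 0.49)
  expect_equal(m2$screening$specificity, 0.87)
  m2alt <- model_config(2, sensitivity = 0.47)
  expect_equal(m2alt$screening$sensitivity, 0.47)
  m3 <- model_config(3)
  expect_equal(c(m3$screening$sensitivity, m3$screening$specificity), c(0.80, 0.95))
  expect_equal(m3$screening_active_generations, c(1L, 2L))
  expect_error(model_config(1, sensitivity = 0.5), "no screening")
  expect_error(model_config(4), "must be 1, 2 or 3")
  expect_error(model_config(2, generations = 0), ">= 1")
})
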