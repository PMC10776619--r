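test_that("unit cost operations match tariff arithmetic", {
  o <- central_oracle
  p <- quiet_scenario("central")
  costs <- p$costs

  expect_equal(testing_cost(2685.2, costs), 2685.2 * 1099.48)
  expect_equal(testing_cost(0, costs), 0)
  expect_error(testing_cost(-1, costs), "non-negative")

  expect_equal(surgery_cost(1, p$surgery_mix, costs), o$surgery_per_carrier) # 1,711.0
  expect_equal(o$surgery_per_carrier, 1711.0, tolerance = 1e-9)
  mix_none <- c(none = 1, rrm_only = 0, rrso_only = 0, both = 0)
  expect_equal(surgery_cost(100, mix_none, costs), 0)

  one_ov <- structure(list(breast_involved = 0, ovarian_involved = 1),
                      class = "brca_cancer_outcome")
  one_br <- structure(list(breast_involved = 1, ovarian_involved = 0),
                      class = "brca_cancer_outcome")
  expect_equal(treatment_cost(one_ov, costs), o$ovarian_bundle)   # 91,361
  expect_equal(treatment_cost(one_br, costs), o$breast_bundle)    # 11,750.45
  none <- structure(list(breast_involved = 0, ovarian_involved = 0),
                    class = "brca_cancer_outcome")
  expect_equal(treatment_cost(none, costs), 0)
  # a both-cancers patient appears in each involvement total once
  both <- structure(list(breast_involved = 1, ovarian_involved = 1),
                    class = "brca_cancer_outcome")
  expect_equal(treatment_cost(both, costs), o$ovarian_bundle + o$breast_bundle)
  # PARP restricted to a fraction of ovarian-involved cases
  expect_equal(treatment_cost(one_ov, costs, cost_rules(parp_fraction = 0.5)),
               6791 + 2226 + 0.5 * 82344)
})

test_that("follow-up schedules distinguish detected, late-diagnosed and standard women", {
  p1 <- quiet_scenario("central", population_size = 1)
  mk_det <- function(det) structure(list(carriers_detected = det,
                                         eligible_for_testing = 0),
                                    class = "brca_detection")
  mk_out <- function(unaware) structure(list(cancers_unaware = unaware),
                                        class = "brca_cancer_outcome")
  expect_equal(follow_up_cost(mk_det(0), mk_out(0), p1), 69.60 * 62)   # 4,315.20
  expect_equal(follow_up_cost(mk_det(1), mk_out(0), p1), 198.20 * 62)  # 12,288.40
  expect_equal(follow_up_cost(mk_det(0), mk_out(1), p1),
               69.60 * 27 + 198.20 * 35)                               # 8,816.20
})

test_that("total cost aggregates components and lands near the published level", {
  p <- quiet_scenario("central")
  d <- detect_generation1(p, model_config(1))
  cc <- expected_cancers(d, p)
  cb <- total_cost(d, cc, p, screening_active = FALSE)
  expect_equal(cb$total,
               cb$testing + cb$screening + cb$prophylactic_surgery +
                 cb$cancer_treatment + cb$follow_up, tolerance = 0.01)
  expect_equal(cb$per_year_per_person, cb$total / (62 * 274000), tolerance = 1e-9)
  # published model-1 level: 73.80 EUR/year/person; tolerance-based
  expect_lt(abs(cb$per_year_per_person - 73.80), 1.50)
  # dominant term: standard follow-up of never-identified women
  expect_gt(cb$follow_up / cb$total, 0.9)
  for (k in c("testing", "screening", "prophylactic_surgery", "cancer_treatment",
              "follow_up"))
    expect_gte(cb[[k]], 0)
})

test_that("turning the radiogenomic screen off recovers model-1 testing cost", {
  p <- quiet_scenario("central")
  d_m1 <- detect_generation1(p, model_config(1))
  d_off <- detect_generation1(p, model_config(2, sensitivity = 0, specificity = 1))
  c_m1 <- total_cost(d_m1, expected_cancers(d_m1, p), p)
  c_off <- total_cost(d_off, expected_cancers(d_off, p), p)
  expect_equal(c_off$testing, c_m1$testing, tolerance = 1e-9)
})

test_that("cost totals order as published across models and generations", {
  res <- quiet_run("central")
  tot <- function(m, g) res[[paste0("model", m)]][[g]]$cost$total
  expect_gt(tot(2, 1), tot(3, 1))
  expect_gt(tot(3, 1), tot(1, 1))
  expect_gt(tot(1, 1), tot(2, 3))   # cascade saves money once screening stops
  expect_gt(tot(1, 1), tot(3, 3))
})

test_that("cost is linear in population size and guards a zero population", {
  p1 <- quiet_scenario("central")
  p2 <- quiet_scenario("central", population_size = 548000)
  per <- function(p) {
    d <- detect_generation1(p, model_config(2))
    total_cost(d, expected_cancers(d, p), p, screening_active = TRUE)$total
  }
  expect_equal(per(p2) / per(p1), 2, tolerance = 1e-9)
  p0 <- quiet_scenario("central")
  p0$population_size <- 0
  d <- detect_generation1(quiet_scenario("central"), model_config(1))
  expect_error(total_cost(d, expected_cancers(d, quiet_scenario("central")), p0),
               "positive")
})
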