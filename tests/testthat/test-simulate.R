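# Synthetic cohort generator: determinism, marginals, calibration, nulls.

test_that("same config and seed give identical cohorts; different seeds differ", {
  cfg <- sim_config(n_patients = 300)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$followup_days, c$followup_days))
})

test_that("covariate marginals converge to the configured values", {
  cfg <- sim_config(n_patients = 100000)
  co <- generate_cohort(cfg, seed = 7)
  n <- nrow(co)
  # subtype mix: IPF fraction within 1 percentage point of 56/179
  expect_lt(abs(mean(co$diagnosis == "IPF") - 56 / 179), 0.01)
  expect_lt(abs(mean(co$diagnosis %in% c("CVD_IP", "iNSIP")) - 112 / 179), 0.01)
  # means/SDs within 3 Monte-Carlo standard errors (truncation shifts are
  # well inside these bands for the configured means)
  mc <- function(x, target, sd_target) {
    expect_lt(abs(mean(x) - target), 3 * sd_target / sqrt(n) + 0.15)
    expect_lt(abs(sd(x) - sd_target), 0.05 * sd_target)
  }
  mc(co$age, 73, 9)
  mc(co$fvc_pct_pred, 94.2, 18.8)
  mc(co$dlco_pct_pred, 92.9, 30.5)
  mc(co$monocyte_ratio, 8.6, 2.8)
  # male fraction is the subtype-probability mixture of the per-subtype rates
  male_target <- sum(c(56, 112, 6, 5) / 179 * c(0.88, 0.57, 0.67, 1.00))
  expect_lt(abs(mean(co$sex == "male") - male_target), 0.01)
  # follow-up means what the censoring calibration promised
  expect_lt(abs(mean(co$followup_days) - 679), 15)
})

test_that("null effect size makes the event rate independent of the score", {
  cfg <- sim_config(n_patients = 50000, log_hr_per_point = 0)
  co <- generate_cohort(cfg, seed = 21)
  sc <- score_cohort(co)
  hi <- sc$event[sc$ild_gapm_total >= median(sc$ild_gapm_total)]
  lo <- sc$event[sc$ild_gapm_total < median(sc$ild_gapm_total)]
  expect_lt(abs(mean(hi) - mean(lo)), 0.015)
})

test_that("baseline-hazard calibration recovers the closed form without dropout", {
  cfg <- sim_config(log_hr_per_point = 0, random_censor_rate = 0)
  h0 <- calibrate_baseline_hazard(cfg, 0.12)
  # with a null score effect and no dropout, P(event) = 1 - exp(-h0 * 1095)
  expect_equal(h0, -log(0.88) / 1095, tolerance = 0.05)
})

test_that("calibration is monotone in the target and rejects bad brackets", {
  cfg <- sim_config()
  h_lo <- calibrate_baseline_hazard(cfg, 0.05, n = 20000)
  h_hi <- calibrate_baseline_hazard(cfg, 0.30, n = 20000)
  expect_lt(h_lo, h_hi)
  expect_error(calibrate_baseline_hazard(cfg, 0.12, lower = 0.5, upper = 1),
               "bracket")
})

test_that("invalid configuration fields are named explicitly", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(subtype_probs = c(0.5, 0.5, 0.2, 0.1)),
               "subtype_probs")
  expect_error(sim_config(age_sd = -1), "age_sd")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(dlco_unmeasurable_prob = 1.5),
               "dlco_unmeasurable_prob")
})

test_that("unmeasurable DLco appears at the configured rate and scores 3", {
  co <- generate_cohort(sim_config(n_patients = 5000,
                                   dlco_unmeasurable_prob = 0.1), seed = 3)
  expect_lt(abs(mean(co$dlco_unmeasurable) - 0.1), 0.02)
  pts <- score_components(co)
  expect_true(all(pts$dlco_points[co$dlco_unmeasurable == 1] == 3L))
})

test_that("a Weibull shape below 1 keeps the generated cohort schema-valid", {
  co <- generate_cohort(sim_config(n_patients = 500, weibull_shape = 0.7),
                        seed = 9)
  expect_silent(validate_cohort(co))
  expect_true(all(co$followup_days <= 1095))
})

test_that("the ild_gap truth mode detaches the monocyte point from hazard", {
  co <- generate_cohort(sim_config(n_patients = 60000,
                                   truth_score = "ild_gap"), seed = 13)
  sc <- score_cohort(co)
  # conditional on the ILD-GAP total, the monocyte point carries no signal
  sub <- sc[sc$ild_gap_total == 2L, ]
  expect_lt(abs(mean(sub$event[sub$monocyte_points == 1]) -
                mean(sub$event[sub$monocyte_points == 0])), 0.02)
})
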