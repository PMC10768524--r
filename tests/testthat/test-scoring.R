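# Point assignment, totals, staging, HRCT global scores.

test_that("component points reproduce the published point table", {
  # Table-mean IPF patient: only male sex and age > 65 score
  expect_equal(unlist(score_components(make_patient())),
               c(diagnosis_points = 0L, sex_points = 1L, age_points = 2L,
                 fvc_points = 0L, dlco_points = 0L, monocyte_points = 0L))
  # all-lowest-bin patient with the -2 diagnosis adjustment
  low <- make_patient(diagnosis = "iNSIP", sex = "female", age = 58,
                      fvc_pct_pred = 80, dlco_pct_pred = 60,
                      monocyte_ratio = 8.5)
  expect_equal(unlist(score_components(low)),
               c(diagnosis_points = -2L, sex_points = 0L, age_points = 0L,
                 fvc_points = 0L, dlco_points = 0L, monocyte_points = 0L))
  # worst bins including the unmeasurable-DLco 3-point bin
  high <- make_patient(diagnosis = "UC_ILD", sex = "male", age = 66,
                       fvc_pct_pred = 49, dlco_pct_pred = NA,
                       dlco_unmeasurable = 1, monocyte_ratio = 8.6)
  expect_equal(unlist(score_components(high)),
               c(diagnosis_points = 0L, sex_points = 1L, age_points = 2L,
                 fvc_points = 2L, dlco_points = 3L, monocyte_points = 1L))
})

test_that("totals, extremes and the monocyte boundary behave as printed", {
  expect_identical(ild_gap_score(make_patient()), 3L)
  expect_identical(ild_gap_score(make_patient(diagnosis = "iNSIP",
                                              sex = "female", age = 58,
                                              fvc_pct_pred = 80,
                                              dlco_pct_pred = 60)), -2L)
  worst <- make_patient(diagnosis = "UC_ILD", sex = "male", age = 66,
                        fvc_pct_pred = 49, dlco_pct_pred = NA,
                        dlco_unmeasurable = 1, monocyte_ratio = 12)
  expect_identical(ild_gap_score(worst), 8L)
  expect_identical(ild_gapm_score(worst), 9L)
  # the cut itself stays in the low group; just above it adds the point
  at_cut <- make_patient(monocyte_ratio = 8.5)
  above <- make_patient(monocyte_ratio = 8.6)
  expect_identical(ild_gapm_score(at_cut), ild_gap_score(at_cut))
  expect_identical(ild_gapm_score(above), ild_gap_score(above) + 1L)
})

test_that("stage assignment follows the published cut-offs and rejects non-integers", {
  expect_identical(as.character(assign_stage(-2:9)),
                   c("I", "I", "I", "I", "II", "II", "III", "III",
                     "IV", "IV", "IV", "IV"))
  expect_error(assign_stage(2.5), "integer")
  expect_error(assign_stage(NA_real_), "integer")
})

test_that("score monotonicity: worsening any physiology never lowers a total", {
  base <- make_patient(age = 62, fvc_pct_pred = 70, dlco_pct_pred = 50,
                       monocyte_ratio = 7)
  for (field in c("fvc_pct_pred", "dlco_pct_pred")) {
    grid <- seq(100, 20, by = -5)
    tot <- vapply(grid, function(v) {
      p <- base; p[[field]] <- v; ild_gapm_score(p)
    }, integer(1L))
    expect_true(all(diff(tot) >= 0), label = paste("decreasing", field))
  }
  tot_age <- vapply(seq(40, 90, by = 2.5), function(a)
    ild_gapm_score(make_patient(age = a)), integer(1L))
  expect_true(all(diff(tot_age) >= 0))
  tot_mono <- vapply(seq(0, 20, by = 0.5), function(m)
    ild_gapm_score(make_patient(monocyte_ratio = m)), integer(1L))
  expect_true(all(diff(tot_mono) >= 0))
  # stages are monotone in the total
  expect_true(all(diff(as.integer(assign_stage(-2:9))) >= 0))
})

test_that("real-valued covariates at bin edges map to exactly one bin", {
  # age 60.5 sits between the printed integer bins; (60, 65] takes it
  expect_identical(score_components(make_patient(age = 60.5))$age_points, 1L)
  expect_identical(score_components(make_patient(fvc_pct_pred = 75))$fvc_points, 1L)
  expect_identical(score_components(make_patient(fvc_pct_pred = 49.9))$fvc_points, 2L)
  expect_identical(score_components(make_patient(dlco_pct_pred = 55))$dlco_points, 1L)
  expect_identical(score_components(make_patient(dlco_pct_pred = 35.5))$dlco_points, 1L)
  expect_identical(score_components(make_patient(dlco_pct_pred = 35))$dlco_points, 2L)
})

test_that("schema violations name the offending field; unmeasurable DLco does not error", {
  expect_error(score_components(make_patient(diagnosis = "NSIP")), "diagnosis")
  expect_error(score_components(make_patient(sex = "M")), "sex")
  expect_error(score_components(make_patient(age = NA_real_)), "age")
  expect_error(score_components(make_patient(fvc_pct_pred = -1)), "fvc_pct_pred")
  expect_error(score_components(make_patient(monocyte_ratio = NA_real_)),
               "monocyte_ratio")
  # silently missing DLco is an error; the explicit flag is not
  expect_error(score_components(make_patient(dlco_pct_pred = NA)),
               "dlco_pct_pred")
  expect_silent(score_components(make_patient(dlco_pct_pred = NA,
                                              dlco_unmeasurable = 1)))
})

test_that("HRCT global score sums six zone grades and validates input", {
  expect_identical(hrct_global_score(rep(0, 6)), 0L)
  expect_identical(hrct_global_score(rep(4, 6)), 24L)
  expect_identical(hrct_global_score(c(1, 2, 0, 1, 0, 1)), 5L)
  expect_identical(hrct_global_score(rbind(rep(0, 6), rep(4, 6))), c(0L, 24L))
  expect_error(hrct_global_score(rep(1, 5)), "6 zones")
  expect_error(hrct_global_score(c(1, 2, 3, 4, 5, 0)), "0..4")
})

test_that("extent-to-grade uses quartile bins with configurable edges", {
  expect_identical(grade_from_extent(c(0, 100, 30, 25, 25.01, 75, 76)),
                   c(0L, 4L, 2L, 1L, 2L, 3L, 4L))
  expect_error(grade_from_extent(101), "\\[0, 100\\]")
  # custom (coarser) dialect
  expect_identical(grade_from_extent(30, thresholds = c(0, 10, 40, 70)), 2L)
})

test_that("score_cohort appends components, totals and stages consistently", {
  sc <- score_cohort(make_toy_cohort())
  expect_identical(sc$ild_gap_total,
                   as.integer(sc$diagnosis_points + sc$sex_points +
                              sc$age_points + sc$fvc_points + sc$dlco_points))
  expect_identical(sc$ild_gapm_total,
                   as.integer(sc$ild_gap_total + sc$monocyte_points))
  expect_identical(sc$ild_gap_stage, assign_stage(sc$ild_gap_total))
  expect_identical(sc$ild_gapm_stage, assign_stage(sc$ild_gapm_total))
  # median-split mode uses this cohort's median and records it
  med <- score_cohort(make_toy_cohort(), monocyte_cut = "median")
  expect_equal(attr(med, "monocyte_cut"),
               median(make_toy_cohort()$monocyte_ratio))
})
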