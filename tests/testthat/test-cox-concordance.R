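# Harrell's C and the univariate Cox partial-likelihood fit.

test_that("C-index hits the degenerate anchors", {
  # perfect ranking, all events
  time <- c(1, 2, 3, 4, 5)
  expect_equal(harrell_c(time, rep(1, 5), c(5, 4, 3, 2, 1)), 1)
  # constant score: every comparable pair is a tie
  expect_equal(harrell_c(time, rep(1, 5), rep(2, 5)), 0.5)
  # anti-perfect ranking
  expect_equal(harrell_c(time, rep(1, 5), 1:5), 0)
  expect_error(harrell_c(5, 0, 1), "no comparable pairs")
})

test_that("C-index equals exhaustive pair enumeration on censored samples", {
  for (seed in c(2, 3)) {
    s <- make_surv_sample(n = 30, seed = seed)
    sc <- round(s$score, 1)  # induce score ties
    expect_equal(harrell_c(s$time, s$event, sc),
                 brute_force_c(s$time, s$event, sc))
  }
})

test_that("C-index agrees with the survival package", {
  skip_if_not_installed("survival")
  s <- make_surv_sample(n = 80, seed = 6)
  cc <- survival::concordance(survival::Surv(s$time, s$event) ~ s$score,
                              reverse = TRUE)
  expect_equal(harrell_c(s$time, s$event, s$score),
               unname(cc$concordance), tolerance = 1e-12)
})

test_that("bootstrap C-index CI is seed-reproducible and contains the estimate", {
  s <- make_surv_sample(n = 60, seed = 8)
  a <- harrell_c_ci(s$time, s$event, s$score, B = 200, seed = 5)
  b <- harrell_c_ci(s$time, s$event, s$score, B = 200, seed = 5)
  expect_identical(a, b)
  expect_lt(a$ci_lower, a$cindex)
  expect_gt(a$ci_upper, a$cindex)
})

test_that("Cox fit maximises the partial likelihood (grid-search oracle)", {
  s <- make_surv_sample(n = 20, seed = 9, round_times = FALSE)
  # unique times in this sample, so Breslow and Efron coincide
  stopifnot(!anyDuplicated(s$time))
  fit <- cox_fit(s$time, s$event, s$score)
  coarse <- seq(-4, 4, by = 0.01)
  ll <- vapply(coarse, naive_cox_loglik, numeric(1L),
               time = s$time, event = s$event, x = s$score)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, naive_cox_loglik, numeric(1L),
                time = s$time, event = s$event, x = s$score)
  expect_equal(fit$coef, fine[which.max(llf)], tolerance = 2e-4)
  expect_equal(fit$loglik, max(llf), tolerance = 1e-8)
  # AIC identity for the single-parameter fit
  expect_equal(fit$aic, -2 * fit$loglik + 2)
})

test_that("Cox fit matches coxph for both tie conventions", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 120
  time <- round(rexp(n, 0.01)) + 1   # heavy ties
  x <- sample(0:5, n, replace = TRUE)
  event <- rbinom(n, 1, plogis(0.3 * x - 1))
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(time, event, x, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
    expect_equal(fit$aic, unname(stats::AIC(ref)), tolerance = 1e-6)
  }
})

test_that("null predictor recovers HR near 1 and the CI covers it", {
  set.seed(15)
  n <- 2000
  time <- rexp(n, 0.002)
  event <- rbinom(n, 1, 0.7)
  x <- rnorm(n)  # independent of outcome
  fit <- cox_fit(time, event, x)
  expect_lt(fit$ci_lower, 1)
  expect_gt(fit$ci_upper, 1)
  expect_lt(abs(fit$coef), 3 * fit$se)
})

test_that("degenerate Cox inputs raise the contracted errors", {
  s <- make_surv_sample(n = 20, seed = 10)
  expect_error(cox_fit(s$time, s$event, rep(1, 20)), "constant")
  expect_error(cox_fit(s$time, rep(0, 20), s$score), "at least one event")
  # perfectly separating predictor: monotone likelihood must be flagged
  time <- 1:20
  event <- rep(1, 20)
  x <- 20:1  # higher score exactly means earlier failure
  expect_error(cox_fit(time, event, x), "converge")
})

test_that("null log partial likelihood matches its direct computation", {
  s <- make_surv_sample(n = 25, seed = 12, round_times = FALSE)
  stopifnot(!anyDuplicated(s$time))
  fit <- cox_fit(s$time, s$event, s$score)
  expect_equal(fit$loglik_null,
               naive_cox_loglik(0, s$time, s$event, s$score), tolerance = 1e-10)
})
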