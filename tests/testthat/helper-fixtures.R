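# In-code fixtures shared across the suite.

# a record with every covariate at a benign default; override fields by name
make_patient <- function(...) {
  rec <- data.frame(patient_id = "P1", diagnosis = "IPF", sex = "male",
                    age = 73, fvc_pct_pred = 93, dlco_pct_pred = 81,
                    dlco_unmeasurable = 0, monocyte_ratio = 8.3,
                    monocyte_count = 550, ccis = 2, honeycomb_score = 1,
                    ggo_score = 5, followup_days = 700, event = 0,
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# small deterministic cohort exercising every scoring bin and both outcomes
make_toy_cohort <- function() {
  rbind(
    make_patient(patient_id = "P1", diagnosis = "IPF", sex = "male", age = 73,
                 fvc_pct_pred = 93, dlco_pct_pred = 81, monocyte_ratio = 8.3,
                 followup_days = 420, event = 1),
    make_patient(patient_id = "P2", diagnosis = "iNSIP", sex = "female",
                 age = 58, fvc_pct_pred = 80, dlco_pct_pred = 60,
                 monocyte_ratio = 8.5, followup_days = 1095, event = 0),
    make_patient(patient_id = "P3", diagnosis = "UC_ILD", sex = "male",
                 age = 66, fvc_pct_pred = 49, dlco_pct_pred = NA,
                 dlco_unmeasurable = 1, monocyte_ratio = 8.6,
                 followup_days = 150, event = 1),
    make_patient(patient_id = "P4", diagnosis = "CVD_IP", sex = "female",
                 age = 64, fvc_pct_pred = 60, dlco_pct_pred = 40,
                 monocyte_ratio = 12, followup_days = 900, event = 0),
    make_patient(patient_id = "P5", diagnosis = "CHP", sex = "male", age = 60,
                 fvc_pct_pred = 50, dlco_pct_pred = 35, monocyte_ratio = 4,
                 followup_days = 1095, event = 0))
}

# independent naive Kaplan-Meier: explicit subject-by-subject risk counting
naive_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    n_at_risk <- 0; d <- 0
    for (i in seq_along(time)) {
      if (time[i] >= ts[k]) n_at_risk <- n_at_risk + 1
      if (time[i] == ts[k] && event[i] == 1) d <- d + 1
    }
    s <- s * (1 - d / n_at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# independent O(n^2) concordance by exhaustive pair enumeration
brute_force_c <- function(time, event, score) {
  conc <- comp <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (event[i] == 1 && time[i] < time[j]) ||
      (event[i] == 1 && event[j] == 0 && time[i] == time[j])
    if (!comparable) next
    comp <- comp + 1
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / comp
}

# independent naive Breslow log partial likelihood (no tied event times in
# the toys it is used on)
naive_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# a censored sample of moderate size with a real score effect;
# round_times = FALSE keeps all times distinct (tie-free toys)
make_surv_sample <- function(n = 60, seed = 11, rate = 0.002, effect = 0.8,
                             round_times = TRUE) {
  set.seed(seed)
  score <- rnorm(n)
  t_ev <- rexp(n, rate * exp(effect * score))
  t_cn <- rexp(n, rate / 2)
  time <- pmin(t_ev, t_cn)
  if (round_times) time <- round(time) + 1
  list(time = time, event = as.integer(t_ev <= t_cn), score = score)
}
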