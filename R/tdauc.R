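# Cumulative/dynamic time-dependent ROC AUC at a fixed horizon with
# inverse-probability-of-censoring weights, bootstrap normal-approximation CI.

# point estimate of the IPCW cumulative/dynamic AUC at `horizon`
ipcw_auc_point <- function(time, event, score, horizon, ids = NULL) {
  is_case <- time <= horizon & event == 1
  # controls are subjects known event-free through the horizon, including
  # those administratively censored exactly at it
  is_ctrl <- time > horizon | (time == horizon & event == 0)
  if (!any(is_case)) stop("no cases (events inside the horizon)", call. = FALSE)
  if (!any(is_ctrl)) stop("no controls (follow-up beyond the horizon)",
                          call. = FALSE)
  # KM estimate of the censoring survival function G (events are censorings
  # of the censoring process and vice versa); the control weight uses the
  # left limit G(horizon-) so an administrative-censoring atom at the
  # horizon does not deflate its own weight
  G <- km_one_group(time, 1 - event)
  g_case <- km_step_eval(G, time[is_case], left = TRUE)  # G(T-)
  g_ctrl <- km_step_eval(G, horizon, left = TRUE)        # G(horizon-)
  if (any(g_case <= 0) || g_ctrl <= 0) {
    bad <- if (g_ctrl <= 0) "controls at the horizon" else {
      lab <- if (is.null(ids)) which(is_case)[g_case <= 0] else
        ids[is_case][g_case <= 0]
      paste("subject(s)", paste(utils::head(lab, 5L), collapse = ", "))
    }
    stop("degenerate censoring distribution: IPCW weight undefined for ",
         bad, call. = FALSE)
  }
  w_case <- 1 / g_case
  w_ctrl <- rep(1 / g_ctrl, sum(is_ctrl))
  s_case <- score[is_case]
  s_ctrl <- score[is_ctrl]
  num <- 0
  for (i in seq_along(s_case)) {
    num <- num + w_case[i] *
      sum(w_ctrl * ((s_case[i] > s_ctrl) + 0.5 * (s_case[i] == s_ctrl)))
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Time-dependent ROC AUC with IPCW and bootstrap CI
#'
#' Cumulative/dynamic AUC at a fixed horizon: cases are subjects with an
#' observed event at or before the horizon, controls are subjects known
#' event-free through it (follow-up beyond the horizon, or censored exactly
#' at it without an event, as under administrative censoring at the
#' horizon). Each case is weighted by the inverse of the Kaplan-Meier
#' censoring survival just before its event time and each control by the
#' inverse censoring survival just before the horizon, which corrects the
#' case/control mix for censoring. The confidence interval is a normal
#' approximation, estimate +/- z * SE, with the SE taken from `B` bootstrap
#' resamples of subjects.
#'
#' @param time Positive follow-up times (days).
#' @param event 0/1 event indicators.
#' @param score Numeric risk score (higher = higher predicted risk).
#' @param horizon Evaluation horizon in days (default 1095, i.e. 3 years).
#' @param B Number of bootstrap resamples (default 2000); `B = 0` skips the
#'   interval.
#' @param seed Seed for the bootstrap stream.
#' @param conf_level Confidence level (default 0.95).
#' @param ids Optional subject labels used in error messages.
#' @return List of class `td_auc`: `auc`, `se`, `ci_lower`, `ci_upper`,
#'   `horizon`, `B`, `n_case`, `n_ctrl`.
#' @export
td_auc_ipcw <- function(time, event, score, horizon = 1095, B = 2000,
                        seed = 1L, conf_level = 0.95, ids = NULL) {
  check_survival_sample(time, event, predictor = score)
  stopifnot(horizon > 0)
  est <- ipcw_auc_point(time, event, score, horizon, ids = ids)
  se <- ci_lower <- ci_upper <- NA_real_
  n_used <- 0L
  if (B > 0) {
    n <- length(time)
    boots <- withr_seed(as.integer(seed), {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(ipcw_auc_point(time[idx], event[idx], score[idx], horizon),
                 error = function(e) NA_real_)
      }, numeric(1L))
    })
    se <- stats::sd(boots, na.rm = TRUE)
    n_used <- sum(!is.na(boots))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_lower <- est - z * se
    ci_upper <- est + z * se
  }
  res <- list(auc = est, se = se, ci_lower = ci_lower, ci_upper = ci_upper,
              horizon = horizon, B = B, n_boot_used = n_used,
              n_case = sum(time <= horizon & event == 1),
              n_ctrl = sum(time > horizon | (time == horizon & event == 0)))
  class(res) <- "td_auc"
  res
}

#' @export
print.td_auc <- function(x, ...) {
  cat(sprintf("IPCW time-dependent AUC at %g days: %.4f", x$horizon, x$auc))
  if (!is.na(x$se)) {
    cat(sprintf(" (95%% CI %.4f-%.4f, bootstrap B = %d)", x$ci_lower,
                x$ci_upper, x$B))
  }
  cat(sprintf("\n  cases = %d, controls = %d\n", x$n_case, x$n_ctrl))
  invisible(x)
}
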