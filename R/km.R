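# Kaplan-Meier product-limit estimation and the k-group log-rank test.

check_survival_sample <- function(time, event, predictor = NULL, group = NULL) {
  if (!is.numeric(time) || anyNA(time) || any(time <= 0)) {
    stop("`time` must be positive follow-up times", call. = FALSE)
  }
  if (length(event) != length(time) || anyNA(event) || !all(event %in% c(0, 1))) {
    stop("`event` must be a 0/1 vector the same length as `time`", call. = FALSE)
  }
  if (!is.null(predictor) &&
      (length(predictor) != length(time) || anyNA(predictor) ||
         !is.numeric(predictor))) {
    stop("`predictor` must be a numeric vector the same length as `time`",
         call. = FALSE)
  }
  if (!is.null(group) && length(group) != length(time)) {
    stop("`group` must have the same length as `time`", call. = FALSE)
  }
  invisible(TRUE)
}

km_one_group <- function(time, event) {
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1L))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), integer(1L))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), integer(1L))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function per group. Tied event times decrement
#' the curve simultaneously; subjects censored at an event time are counted
#' as still at risk at that time.
#'
#' @param time Positive follow-up times (days).
#' @param event 0/1 event indicators.
#' @param group Optional grouping vector; `NULL` fits a single curve.
#' @return A data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (one row per distinct observed
#'   time per group; `surv` starts below 1 only after the first event).
#' @export
#' @examples
#' km_estimate(c(2, 4, 5), c(1, 1, 1))
km_estimate <- function(time, event, group = NULL) {
  check_survival_sample(time, event, group = group)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  out <- do.call(rbind, lapply(split(seq_along(time), group), function(idx) {
    if (!length(idx)) stop("empty group", call. = FALSE)
    cbind(group = group[idx[1L]], km_one_group(time[idx], event[idx]))
  }))
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

# step-function evaluation of a single-group KM curve at arbitrary times;
# left = TRUE gives the left limit S(t-)
km_step_eval <- function(curve, t, left = FALSE) {
  ct <- curve$time
  cs <- curve$surv
  vapply(t, function(x) {
    idx <- if (left) sum(ct < x) else sum(ct <= x)
    if (idx == 0L) 1 else cs[idx]
  }, numeric(1L))
}

#' k-group log-rank test
#'
#' Observed-minus-expected log-rank statistic with the hypergeometric
#' variance, compared to a chi-square distribution on k - 1 degrees of
#' freedom.
#'
#' @inheritParams km_estimate
#' @param group Grouping vector with at least two non-empty levels.
#' @return List of class `logrank_test` with `statistic`, `df`, `p_value`,
#'   and the per-group `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  check_survival_sample(time, event, group = group)
  group <- factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (sum(event) == 0) stop("log-rank test undefined: no events", call. = FALSE)
  k <- nlevels(group)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & group == levels(group)[j]),
                 numeric(1L))
    dead <- time == t & event == 1
    d <- sum(dead)
    dj <- vapply(seq_len(k), function(j) sum(dead & group == levels(group)[j]),
                 numeric(1L))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      vc <- d * (n - d) / (n - 1) * (diag(nj * n, k) - outer(nj, nj)) / n^2
      V <- V + vc
    }
  }
  # drop one group; invert the reduced variance (pseudoinverse guards
  # against degenerate strata)
  u <- (O - E)[-k]
  Vr <- V[-k, -k, drop = FALSE]
  stat <- drop(u %*% pinv_sym(Vr) %*% u)
  df <- k - 1L
  res <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              observed = stats::setNames(O, levels(group)),
              expected = stats::setNames(E, levels(group)),
              n = length(time), n_events = sum(event))
  class(res) <- "logrank_test"
  res
}

# Moore-Penrose pseudoinverse of a small symmetric matrix
pinv_sym <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = x$expected)
  print(round(tab, 2))
  invisible(x)
}
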