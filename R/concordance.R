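# Harrell's concordance index for censored data.

#' Harrell's C-index
#'
#' Fraction of comparable subject pairs in which the higher-risk score
#' belongs to the subject who fails earlier. A pair is comparable when the
#' shorter follow-up ends in an event (including a pair tied in time in
#' which exactly one subject has the event); tied scores count 1/2.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param score Numeric risk score (higher = higher predicted risk).
#' @return C-index in \[0, 1\].
#' @export
harrell_c <- function(time, event, score) {
  check_survival_sample(time, event, predictor = score)
  conc <- 0
  comp <- 0
  for (i in which(event == 1)) {
    later <- (time > time[i]) | (time == time[i] & event == 0)
    later[i] <- FALSE
    m <- sum(later)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' C-index with a bootstrap confidence interval
#'
#' Resamples subjects with replacement `B` times and forms a normal
#' approximation interval, estimate +/- z * bootstrap SE.
#'
#' @inheritParams harrell_c
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Seed for the resampling stream.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `cindex`, `se`, `ci_lower`, `ci_upper`, `B`.
#' @export
harrell_c_ci <- function(time, event, score, B = 2000, seed = 1L,
                         conf_level = 0.95) {
  est <- harrell_c(time, event, score)
  n <- length(time)
  boots <- withr_seed(as.integer(seed), {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(harrell_c(time[idx], event[idx], score[idx]),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  se <- stats::sd(boots, na.rm = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(cindex = est, se = se, ci_lower = est - z * se, ci_upper = est + z * se,
       B = B, n_boot_used = sum(!is.na(boots)))
}
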