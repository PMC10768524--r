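# End-to-end cohort analysis: univariate Cox screens, stratified
# Kaplan-Meier comparisons, and the paired ILD-GAP vs ILD-GAPM evaluation.

.default_predictors <- c("age", "sex", "ccis", "monocyte_ratio",
                         "honeycomb_score", "ggo_score", "ild_gap_total",
                         "fvc_pct_pred", "dlco_pct_pred")

#' Analysis plan
#'
#' Bundles the knobs of the full analysis: the monocyte cut (fixed model
#' constant 8.5 or the cohort median), the honeycomb dichotomy (present
#' when the global honeycomb score exceeds 0), the %DLco subgroup threshold
#' (default 90% predicted), the evaluation horizon, the bootstrap size and
#' seed, the univariate predictor list, and whether the model-comparison
#' AIC uses the score as a continuous covariate (default) or the stage as
#' an ordinal 1-4 covariate.
#'
#' @param monocyte_cut Numeric cut-point or `"median"`.
#' @param honeycomb_cut Honeycomb scores strictly above this count as
#'   "honeycomb present" (default 0).
#' @param dlco_subgroup_threshold Subjects with %DLco at or below this enter
#'   the low-DLco subgroup (default 90).
#' @param horizon_days Evaluation horizon (default 1095).
#' @param bootstrap_B Bootstrap resamples for AUC / C-index CIs.
#' @param seed Seed for every bootstrap stream in the plan.
#' @param predictors Univariate screen predictor columns.
#' @param aic_mode `"continuous"` or `"stage"`.
#' @param alpha Two-sided significance threshold (default 0.05).
#' @return List of class `analysis_plan`.
#' @export
analysis_plan <- function(monocyte_cut = 8.5, honeycomb_cut = 0,
                          dlco_subgroup_threshold = 90, horizon_days = 1095,
                          bootstrap_B = 2000, seed = 1L,
                          predictors = .default_predictors,
                          aic_mode = c("continuous", "stage"),
                          alpha = 0.05) {
  aic_mode <- match.arg(aic_mode)
  if (!identical(monocyte_cut, "median")) stopifnot(is.numeric(monocyte_cut))
  stopifnot(dlco_subgroup_threshold > 0, horizon_days > 0, bootstrap_B >= 0,
            length(predictors) >= 1L, alpha > 0, alpha < 1)
  plan <- list(monocyte_cut = monocyte_cut, honeycomb_cut = honeycomb_cut,
               dlco_subgroup_threshold = dlco_subgroup_threshold,
               horizon_days = horizon_days, bootstrap_B = bootstrap_B,
               seed = as.integer(seed), predictors = predictors,
               aic_mode = aic_mode, alpha = alpha)
  class(plan) <- "analysis_plan"
  plan
}

# ensure score columns are present
ensure_scored <- function(cohort, plan) {
  if (!all(c("ild_gap_total", "ild_gapm_total") %in% names(cohort))) {
    cohort <- score_cohort(cohort, monocyte_cut = plan$monocyte_cut)
  }
  cohort
}

# subject filter for a named analysis population
population_rows <- function(cohort, population, plan) {
  switch(population,
         all = rep(TRUE, nrow(cohort)),
         IPF = cohort$diagnosis == "IPF",
         non_IPF = cohort$diagnosis != "IPF",
         low_dlco = !is.na(cohort$dlco_pct_pred) &
           cohort$dlco_pct_pred <= plan$dlco_subgroup_threshold,
         stop("unknown population: ", population, call. = FALSE))
}

#' Univariate Cox screen by IPF / non-IPF stratum
#'
#' Fits one univariate Cox model per predictor within the IPF and non-IPF
#' strata and flags predictors significant at the plan's alpha. Sex is
#' coded male = 1. Rows with an unmeasurable DLco are excluded from the
#' DLco fit only. A stratum with no events is skipped with a warning, as is
#' a constant or absent predictor column.
#'
#' @param cohort Cohort data frame (scored or raw).
#' @param plan An [analysis_plan()].
#' @return Data frame with one row per (stratum, predictor): `n`,
#'   `n_events`, `hr`, `ci_lower`, `ci_upper`, `p_value`, `significant`.
#' @export
run_univariate_screen <- function(cohort, plan = analysis_plan()) {
  validate_cohort(cohort)
  cohort <- ensure_scored(cohort, plan)
  strata <- list(IPF = cohort$diagnosis == "IPF",
                 non_IPF = cohort$diagnosis != "IPF")
  rows <- list()
  for (s in names(strata)) {
    sub <- cohort[strata[[s]], , drop = FALSE]
    if (!nrow(sub) || sum(sub$event) == 0) {
      warning("stratum ", s, " skipped: no events", call. = FALSE)
      next
    }
    for (p in plan$predictors) {
      if (!p %in% names(sub)) {
        warning("predictor ", p, " absent from cohort; skipped", call. = FALSE)
        next
      }
      x <- sub[[p]]
      keep <- rep(TRUE, nrow(sub))
      if (p == "sex") x <- as.numeric(x == "male")
      if (is.factor(x)) x <- as.numeric(x)
      keep <- keep & !is.na(x)
      x <- as.numeric(x)
      fit <- tryCatch(
        cox_fit(sub$followup_days[keep], sub$event[keep], x[keep]),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("predictor ", p, " in stratum ", s, " skipped: ",
                conditionMessage(fit), call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, predictor = p, n = sum(keep),
        n_events = sum(sub$event[keep]),
        hr = fit$hr, ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
        p_value = fit$p_value, significant = fit$p_value < plan$alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified Kaplan-Meier comparison
#'
#' Builds the grouping requested by `stratifier` (monocyte high/low at the
#' plan's cut, honeycomb present/absent, or the stage of either model),
#' restricts to the requested analysis population, drops empty strata with
#' a message, and returns the per-group Kaplan-Meier curves together with
#' the log-rank comparison.
#'
#' @param cohort Cohort data frame.
#' @param plan An [analysis_plan()].
#' @param stratifier One of `"monocyte"`, `"honeycomb"`, `"ild_gap_stage"`,
#'   `"ild_gapm_stage"`.
#' @param population One of `"all"`, `"IPF"`, `"non_IPF"`, `"low_dlco"`.
#' @return List with `curves` (a `km_curve` data frame), `logrank`,
#'   `stratifier`, `population`, `n`, `n_events`.
#' @export
run_stratified_km <- function(cohort, plan = analysis_plan(),
                              stratifier = c("monocyte", "honeycomb",
                                             "ild_gap_stage", "ild_gapm_stage"),
                              population = c("all", "IPF", "non_IPF",
                                             "low_dlco")) {
  stratifier <- match.arg(stratifier)
  population <- match.arg(population)
  validate_cohort(cohort)
  cohort <- ensure_scored(cohort, plan)
  sub <- cohort[population_rows(cohort, population, plan), , drop = FALSE]
  grp <- switch(stratifier,
    monocyte = {
      cut <- attr(sub, "monocyte_cut")
      cut <- if (is.null(cut)) {
        if (identical(plan$monocyte_cut, "median")) {
          stats::median(sub$monocyte_ratio)
        } else plan$monocyte_cut
      } else cut
      ifelse(sub$monocyte_ratio > cut, "high", "low")
    },
    honeycomb = {
      if (!"honeycomb_score" %in% names(sub) || anyNA(sub$honeycomb_score)) {
        stop("honeycomb_score column required for honeycomb stratification",
             call. = FALSE)
      }
      ifelse(sub$honeycomb_score > plan$honeycomb_cut, "present", "absent")
    },
    ild_gap_stage = as.character(sub$ild_gap_stage),
    ild_gapm_stage = as.character(sub$ild_gapm_stage))
  keep_levels <- names(which(table(grp) > 0))
  dropped <- setdiff(unique(grp), keep_levels)
  if (length(dropped)) {
    message("dropping empty strata: ", paste(dropped, collapse = ", "))
  }
  if (length(keep_levels) < 2L) {
    stop("fewer than 2 non-empty strata for ", stratifier, " in population ",
         population, call. = FALSE)
  }
  curves <- km_estimate(sub$followup_days, sub$event, grp)
  lr <- logrank_test(sub$followup_days, sub$event, grp)
  list(curves = curves, logrank = lr, stratifier = stratifier,
       population = population, n = nrow(sub), n_events = sum(sub$event))
}

#' Paired comparison of the ILD-GAP and ILD-GAPM models
#'
#' Evaluates both scores on the identical subject set with the identical
#' bootstrap resamples (same seed for each model's resampling stream, so
#' the comparison is paired): IPCW time-dependent AUC at the plan horizon,
#' Harrell's C-index (both with bootstrap normal-approximation CIs), and
#' the AIC of a univariate Cox fit of the score (continuous by default,
#' ordinal stage when `plan$aic_mode == "stage"`).
#'
#' @param cohort Cohort data frame.
#' @param plan An [analysis_plan()].
#' @return Data frame of class `model_comparison` with rows `ild_gap` and
#'   `ild_gapm` and columns `auc`, `auc_lower`, `auc_upper`, `cindex`,
#'   `cindex_lower`, `cindex_upper`, `aic`; the `winner` attribute names
#'   the better model per metric (higher AUC/C, lower AIC).
#' @export
compare_models <- function(cohort, plan = analysis_plan()) {
  validate_cohort(cohort)
  cohort <- ensure_scored(cohort, plan)
  scores <- list(ild_gap = cohort$ild_gap_total,
                 ild_gapm = cohort$ild_gapm_total)
  stages <- list(ild_gap = as.numeric(cohort$ild_gap_stage),
                 ild_gapm = as.numeric(cohort$ild_gapm_stage))
  rows <- lapply(names(scores), function(m) {
    sc <- scores[[m]]
    auc <- td_auc_ipcw(cohort$followup_days, cohort$event, sc,
                       horizon = plan$horizon_days, B = plan$bootstrap_B,
                       seed = plan$seed)
    cc <- harrell_c_ci(cohort$followup_days, cohort$event, sc,
                       B = plan$bootstrap_B, seed = plan$seed)
    aic_x <- if (plan$aic_mode == "stage") stages[[m]] else sc
    aic <- cox_fit(cohort$followup_days, cohort$event, aic_x)$aic
    data.frame(model = m, auc = auc$auc, auc_lower = auc$ci_lower,
               auc_upper = auc$ci_upper, cindex = cc$cindex,
               cindex_lower = cc$ci_lower, cindex_upper = cc$ci_upper,
               aic = aic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$model
  attr(out, "winner") <- list(
    auc = out$model[which.max(out$auc)],
    cindex = out$model[which.max(out$cindex)],
    aic = out$model[which.min(out$aic)])
  attr(out, "plan") <- plan
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (paired bootstrap):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  w <- attr(x, "winner")
  cat(sprintf("winner: AUC %s, C-index %s, AIC %s\n", w$auc, w$cindex, w$aic))
  invisible(x)
}

#' Descriptive between-group comparison test
#'
#' Generic helper for descriptive cohort tables: a chi-square test for a
#' categorical variable against the grouping, a Wilcoxon rank-sum test for
#' a numeric variable over two groups, and its k-group generalisation
#' (Kruskal-Wallis) otherwise.
#'
#' @param values Vector to compare (numeric or categorical).
#' @param group Grouping vector.
#' @return List with `method`, `statistic`, `p_value`.
#' @export
group_comparison_test <- function(values, group) {
  group <- factor(group)
  if (is.numeric(values)) {
    if (nlevels(group) == 2L) {
      ht <- stats::wilcox.test(values ~ group, exact = FALSE)
    } else {
      ht <- stats::kruskal.test(values, group)
    }
  } else {
    ht <- stats::chisq.test(table(values, group))
  }
  list(method = ht$method, statistic = unname(ht$statistic),
       p_value = ht$p.value)
}

#' Run the full analysis and write its artefacts
#'
#' Scores the cohort under both models, runs the univariate screen, the
#' stratified Kaplan-Meier comparisons (monocyte and honeycomb in the all /
#' IPF / non-IPF populations; stage of each model in the full cohort and
#' the low-DLco subgroup), and the paired model comparison, writing each
#' artefact under `outdir`: `scored_cohort.csv`, `univariate_screen.csv`,
#' `model_comparison.json` / `.csv`, one `km_<stratifier>_<population>.csv`
#' per comparison, and `run_log.txt` with the seed and plan. Outputs are
#' regenerable bit-identically from (cohort, plan, seed).
#'
#' @param cohort Cohort data frame.
#' @param plan An [analysis_plan()].
#' @param outdir Output directory (created if absent).
#' @return Named list of everything computed, invisibly.
#' @export
run_report <- function(cohort, plan = analysis_plan(), outdir) {
  validate_cohort(cohort)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  scored <- score_cohort(cohort, monocyte_cut = plan$monocyte_cut)
  write_cohort(scored, file.path(outdir, "scored_cohort.csv"))

  screen <- run_univariate_screen(scored, plan)
  utils::write.csv(screen, file.path(outdir, "univariate_screen.csv"),
                   row.names = FALSE)

  km_specs <- list(c("monocyte", "all"), c("monocyte", "IPF"),
                   c("monocyte", "non_IPF"),
                   c("honeycomb", "all"), c("honeycomb", "IPF"),
                   c("honeycomb", "non_IPF"),
                   c("ild_gap_stage", "all"), c("ild_gapm_stage", "all"),
                   c("ild_gap_stage", "low_dlco"),
                   c("ild_gapm_stage", "low_dlco"))
  km_results <- list()
  for (spec in km_specs) {
    res <- tryCatch(
      run_stratified_km(scored, plan, stratifier = spec[1L],
                        population = spec[2L]),
      error = function(e) e)
    key <- paste(spec, collapse = "_")
    if (inherits(res, "error")) {
      warning("KM comparison ", key, " skipped: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    km_results[[key]] <- res
    curves <- res$curves
    curves$logrank_p <- res$logrank$p_value
    utils::write.csv(curves, file.path(outdir, sprintf("km_%s.csv", key)),
                     row.names = FALSE)
  }

  comparison <- compare_models(scored, plan)
  utils::write.csv(as.data.frame(comparison),
                   file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  write_metrics(list(seed = plan$seed, horizon_days = plan$horizon_days,
                     bootstrap_B = plan$bootstrap_B,
                     models = lapply(split(as.data.frame(comparison),
                                           comparison$model), as.list),
                     winner = attr(comparison, "winner")),
                file.path(outdir, "model_comparison.json"))

  log_lines <- c("ildgapm run log",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("ildgapm"))),
                 sprintf("seed: %d", plan$seed),
                 sprintf("plan: %s",
                         paste(names(unclass(plan)),
                               vapply(unclass(plan), function(v)
                                 paste(format(v), collapse = ","), ""),
                               sep = "=", collapse = "; ")))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))

  invisible(list(scored = scored, screen = screen, km = km_results,
                 comparison = comparison))
}
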