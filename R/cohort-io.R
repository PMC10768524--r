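# Cohort CSV reading/writing with schema validation, plan files, metrics JSON.

# canonical column order for cohort files
.cohort_columns <- c("patient_id", "diagnosis", "sex", "age", "fvc_pct_pred",
                     "dlco_pct_pred", "dlco_unmeasurable", "monocyte_ratio",
                     "monocyte_count", "ccis", "honeycomb_score", "ggo_score",
                     "followup_days", "event")

#' Validate a cohort table
#'
#' Checks the cohort schema: required columns, controlled vocabularies for
#' diagnosis and sex, numeric ranges, a strictly 0/1 event indicator, and
#' non-negative follow-up. All row-level problems are collected and reported
#' together (all-or-nothing), with row numbers.
#'
#' @param cohort Data frame to validate.
#' @param require_outcome If `TRUE` (default) `followup_days` and `event`
#'   are required; covariate-only tables may pass `FALSE`.
#' @return The validated data frame, invisibly.
#' @export
validate_cohort <- function(cohort, require_outcome = TRUE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  errs <- character()
  need <- c("diagnosis", "sex", "age", "fvc_pct_pred", "monocyte_ratio")
  if (require_outcome) need <- c(need, "followup_days", "event")
  miss <- setdiff(need, names(cohort))
  has_dlco <- "dlco_pct_pred" %in% names(cohort)
  has_flag <- "dlco_unmeasurable" %in% names(cohort)
  if (!has_dlco && !has_flag) {
    miss <- c(miss, "dlco_pct_pred (or dlco_unmeasurable)")
  }
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  rows <- function(bad) paste(utils::head(which(bad), 10L), collapse = ", ")
  add <- function(bad, msg) {
    if (any(bad)) errs <<- c(errs, sprintf("%s [row(s) %s]", msg, rows(bad)))
  }

  add(is.na(cohort$diagnosis) | !cohort$diagnosis %in% ild_diagnoses(),
      sprintf("diagnosis not one of {%s}", paste(ild_diagnoses(), collapse = ", ")))
  add(is.na(cohort$sex) | !cohort$sex %in% ild_sexes(),
      sprintf("sex not one of {%s}", paste(ild_sexes(), collapse = ", ")))
  add(!is.finite(cohort$age) | cohort$age < 0, "age must be a non-negative number")
  add(!is.finite(cohort$fvc_pct_pred) | cohort$fvc_pct_pred <= 0,
      "fvc_pct_pred must be positive")
  add(!is.finite(cohort$monocyte_ratio) | cohort$monocyte_ratio < 0,
      "monocyte_ratio must be non-negative")

  unm <- if (has_flag) {
    flag <- cohort$dlco_unmeasurable
    add(is.na(flag) | !flag %in% c(0, 1), "dlco_unmeasurable must be 0/1")
    !is.na(flag) & flag == 1
  } else rep(FALSE, nrow(cohort))
  if (has_dlco) {
    add(!unm & (!is.finite(cohort$dlco_pct_pred) | cohort$dlco_pct_pred <= 0),
        "dlco_pct_pred must be positive unless flagged unmeasurable")
  } else {
    add(!unm, "dlco_pct_pred absent and dlco_unmeasurable not set")
  }

  if (require_outcome) {
    add(!is.finite(cohort$followup_days) | cohort$followup_days < 0,
        "followup_days must be non-negative")
    ev <- cohort$event
    add(is.na(ev) | !(is.numeric(ev) | is.integer(ev)) | !ev %in% c(0, 1),
        "event must be 0 or 1")
  }
  if (length(errs)) {
    stop("invalid cohort:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a comma-delimited, header-rowed cohort file (UTF-8, decimal point,
#' empty cells for missing optional values) and validates it against the
#' cohort schema. Leading `#` comment lines written by [write_cohort()]
#' carry provenance (e.g. a simulation seed) and are re-attached as the
#' `provenance` attribute.
#'
#' @param path Path to the CSV file.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  prov <- sub("^#\\s*", "", grep("^#", head_lines, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_cohort(df)
  if (length(prov)) {
    prov_list <- list()
    seed_line <- grep("^seed:", prov, value = TRUE)
    if (length(seed_line)) {
      prov_list$seed <- as.integer(sub("^seed:\\s*", "", seed_line[[1L]]))
    }
    prov_list$header <- prov
    attr(df, "provenance") <- prov_list
  }
  df
}

#' Write a cohort CSV
#'
#' Writes the canonical comma-delimited cohort format. Provenance (schema
#' version and, when present, the simulation seed) is written as leading
#' `#` comment lines so that `read_cohort(write_cohort(x))` round-trips.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  header <- "# ildgapm cohort schema v1"
  prov <- attr(cohort, "provenance")
  if (!is.null(prov$seed)) header <- c(header, sprintf("# seed: %d", prov$seed))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a metrics JSON file
#'
#' Serialises an evaluation result (model comparison, univariate screen,
#' Kaplan-Meier curves ...) to schema-versioned JSON. The seed used for any
#' bootstrap is expected inside `metrics` and is preserved verbatim.
#'
#' @param metrics Named list (or coercible object) of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  payload <- c(list(schema_version = "ildgapm-metrics-1"), as.list(metrics))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an analysis plan from YAML or JSON
#'
#' A plan file is a flat key-value document whose keys mirror the arguments
#' of [analysis_plan()]; unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` plan file.
#' @return An `analysis_plan` object.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(analysis_plan)))
  if (length(unknown)) {
    stop("unknown plan key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_plan, vals)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Flat key-value document mirroring the arguments of [sim_config()].
#'
#' @param path Path to the config file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}
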