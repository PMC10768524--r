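# ILD-GAP / ILD-GAPM point tables, stage assignment, HRCT global scores.

#' Controlled vocabularies
#'
#' Admissible values for the categorical cohort fields.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ild_diagnoses <- function() c("IPF", "UC_ILD", "CVD_IP", "iNSIP", "CHP")

#' @rdname vocabularies
#' @export
ild_sexes <- function() c("male", "female")

#' @rdname vocabularies
#' @export
ild_stages <- function() c("I", "II", "III", "IV")

# diagnosis subtypes that take the -2 adjustment relative to the GAP score
.adjusted_diagnoses <- c("CVD_IP", "iNSIP", "CHP")

#' Per-component ILD-GAP / ILD-GAPM points
#'
#' Assigns the component points of the ILD-GAP model (diagnosis adjustment,
#' sex, age, %FVC, %DLco) and the monocyte-ratio point of the ILD-GAPM
#' extension for every row of a cohort table.
#'
#' Point assignment: diagnosis IPF or unclassifiable ILD scores 0, the
#' remaining subtypes (CVD-IP, iNSIP, CHP) score -2; female 0, male 1;
#' age <= 60 scores 0, (60, 65] scores 1, > 65 scores 2; %FVC > 75 scores 0,
#' [50, 75] scores 1, < 50 scores 2; %DLco > 55 scores 0, (35, 55] scores 1,
#' <= 35 scores 2, and a DLco measurement that could not be performed scores
#' 3; monocyte ratio above `monocyte_cut` (default 8.5%) scores 1, otherwise
#' 0. Interval edges are chosen so any real-valued covariate maps to exactly
#' one bin while integer inputs reproduce the printed table.
#'
#' @param cohort Data frame with at least `diagnosis`, `sex`, `age`,
#'   `fvc_pct_pred`, `dlco_pct_pred` (may be `NA` only where
#'   `dlco_unmeasurable` is 1) and `monocyte_ratio`.
#' @param monocyte_cut Monocyte-ratio cut-point in percent; values strictly
#'   above it receive the monocyte point. The model constant is 8.5 (the
#'   development cohort's median); pass a cohort median explicitly for
#'   sensitivity analyses.
#' @return Data frame with integer columns `diagnosis_points`, `sex_points`,
#'   `age_points`, `fvc_points`, `dlco_points`, `monocyte_points`.
#' @seealso [ild_gap_score()], [ild_gapm_score()], [score_cohort()]
#' @export
#' @examples
#' pt <- data.frame(diagnosis = "IPF", sex = "male", age = 73,
#'                  fvc_pct_pred = 93, dlco_pct_pred = 81,
#'                  monocyte_ratio = 8.3)
#' score_components(pt)
score_components <- function(cohort, monocyte_cut = 8.5) {
  check_scoring_fields(cohort)
  stopifnot(is.numeric(monocyte_cut), length(monocyte_cut) == 1L)
  n <- nrow(cohort)

  diagnosis_points <- ifelse(cohort$diagnosis %in% .adjusted_diagnoses, -2L, 0L)
  sex_points <- ifelse(cohort$sex == "male", 1L, 0L)
  age_points <- ifelse(cohort$age <= 60, 0L, ifelse(cohort$age <= 65, 1L, 2L))
  fvc_points <- ifelse(cohort$fvc_pct_pred > 75, 0L,
                ifelse(cohort$fvc_pct_pred >= 50, 1L, 2L))

  unm <- cohort_dlco_unmeasurable(cohort)
  dlco_points <- integer(n)
  dlco_points[unm] <- 3L
  d <- cohort$dlco_pct_pred[!unm]
  dlco_points[!unm] <- ifelse(d > 55, 0L, ifelse(d > 35, 1L, 2L))

  monocyte_points <- ifelse(cohort$monocyte_ratio > monocyte_cut, 1L, 0L)

  data.frame(diagnosis_points = as.integer(diagnosis_points),
             sex_points = as.integer(sex_points),
             age_points = as.integer(age_points),
             fvc_points = as.integer(fvc_points),
             dlco_points = as.integer(dlco_points),
             monocyte_points = as.integer(monocyte_points))
}

#' Total ILD-GAP score
#'
#' Sum of the diagnosis, sex, age, %FVC and %DLco points; range -2 to 8.
#'
#' @inheritParams score_components
#' @return Integer vector of total scores.
#' @export
ild_gap_score <- function(cohort) {
  pts <- score_components(cohort)
  as.integer(pts$diagnosis_points + pts$sex_points + pts$age_points +
             pts$fvc_points + pts$dlco_points)
}

#' Total ILD-GAPM score
#'
#' The ILD-GAP total plus one point when the blood monocyte ratio exceeds
#' `monocyte_cut`; range -2 to 9.
#'
#' @inheritParams score_components
#' @return Integer vector of total scores.
#' @export
ild_gapm_score <- function(cohort, monocyte_cut = 8.5) {
  pts <- score_components(cohort, monocyte_cut = monocyte_cut)
  as.integer(pts$diagnosis_points + pts$sex_points + pts$age_points +
             pts$fvc_points + pts$dlco_points + pts$monocyte_points)
}

#' Stage from a total score
#'
#' Maps an integer total score (either model) to a disease stage:
#' stage I for totals of at most 1 point, stage II for 2-3 points, stage III
#' for 4-5 points, stage IV above 5 points. The same cut-offs apply to
#' ILD-GAP and ILD-GAPM totals.
#'
#' @param total Integer vector of total scores (negative totals are valid
#'   and stage as I).
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' assign_stage(-2:9)
assign_stage <- function(total) {
  if (!is.numeric(total) || anyNA(total) || any(total != round(total))) {
    stop("`total` must be a vector of integer scores", call. = FALSE)
  }
  lab <- ifelse(total <= 1, "I",
         ifelse(total <= 3, "II",
         ifelse(total <= 5, "III", "IV")))
  factor(lab, levels = ild_stages())
}

#' Score a cohort under both models
#'
#' Appends the component points, ILD-GAP and ILD-GAPM totals, and the stage
#' labels of both models to a cohort table.
#'
#' @inheritParams score_components
#' @param monocyte_cut Either a numeric cut-point (default 8.5, the model
#'   constant) or the string `"median"` to split at this cohort's median
#'   monocyte ratio (sensitivity-analysis mode).
#' @return The input data frame with columns `diagnosis_points` ...
#'   `monocyte_points`, `ild_gap_total`, `ild_gapm_total`, `ild_gap_stage`,
#'   `ild_gapm_stage` appended. The cut-point actually used is recorded in
#'   the `monocyte_cut` attribute.
#' @export
score_cohort <- function(cohort, monocyte_cut = 8.5) {
  if (identical(monocyte_cut, "median")) {
    monocyte_cut <- stats::median(cohort$monocyte_ratio)
  }
  pts <- score_components(cohort, monocyte_cut = monocyte_cut)
  gap <- as.integer(pts$diagnosis_points + pts$sex_points + pts$age_points +
                    pts$fvc_points + pts$dlco_points)
  gapm <- as.integer(gap + pts$monocyte_points)
  out <- cbind(cohort, pts)
  out$ild_gap_total <- gap
  out$ild_gapm_total <- gapm
  out$ild_gap_stage <- assign_stage(gap)
  out$ild_gapm_stage <- assign_stage(gapm)
  attr(out, "monocyte_cut") <- monocyte_cut
  attr(out, "provenance") <- attr(cohort, "provenance")  # keep seed et al.
  out
}

#' HRCT six-zone global score
#'
#' Sums semiquantitative extent grades over the six lung zones (three per
#' lung) for one abnormality (ground-glass opacity or honeycombing); the
#' global score ranges 0-24. Each abnormality is scored separately.
#'
#' @param grades Either an integer vector of length 6 (one subject) or a
#'   6-column matrix / data frame (one row per subject), grades in 0-4.
#' @return Integer global score(s).
#' @export
#' @examples
#' hrct_global_score(c(1, 2, 0, 1, 0, 1))
hrct_global_score <- function(grades) {
  if (is.data.frame(grades)) grades <- as.matrix(grades)
  if (is.matrix(grades)) {
    if (ncol(grades) != 6L) {
      stop("HRCT grades must cover exactly 6 zones", call. = FALSE)
    }
    apply(grades, 1L, function(g) hrct_global_score(as.numeric(g)))
  } else {
    if (length(grades) != 6L) {
      stop("HRCT grades must cover exactly 6 zones", call. = FALSE)
    }
    if (anyNA(grades) || !is.numeric(grades) || any(grades != round(grades)) ||
        any(grades < 0) || any(grades > 4)) {
      stop("each HRCT zone grade must be an integer in 0..4", call. = FALSE)
    }
    as.integer(sum(grades))
  }
}

#' Extent percentage to zone grade
#'
#' Converts a per-zone disease-extent percentage into a semiquantitative
#' grade 0-4. The default binning is by extent quartile: 0% maps to 0 and
#' the intervals (0,25], (25,50], (50,75], (75,100] map to grades 1-4. The
#' thresholds are exposed because published six-zone schemes vary in their
#' bin edges.
#'
#' @param percent_extent Numeric vector of extents in \[0, 100\].
#' @param thresholds Increasing vector of four lower bin edges; a grade of
#'   g is assigned when the extent is strictly above `thresholds[g]` (and
#'   not above the next edge).
#' @return Integer vector of grades 0-4.
#' @export
grade_from_extent <- function(percent_extent, thresholds = c(0, 25, 50, 75)) {
  if (!is.numeric(percent_extent) || anyNA(percent_extent) ||
      any(percent_extent < 0) || any(percent_extent > 100)) {
    stop("`percent_extent` must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(length(thresholds) == 4L, !is.unsorted(thresholds, strictly = TRUE))
  grade <- rowSums(outer(percent_extent, thresholds, ">"))
  as.integer(grade)
}

# ---- field validation -------------------------------------------------------

# logical vector: which rows have DLco flagged unmeasurable
cohort_dlco_unmeasurable <- function(cohort) {
  if ("dlco_unmeasurable" %in% names(cohort)) {
    flag <- cohort$dlco_unmeasurable
    if (anyNA(flag) || !all(flag %in% c(0, 1))) {
      stop("`dlco_unmeasurable` must be 0/1", call. = FALSE)
    }
    as.logical(flag)
  } else {
    rep(FALSE, nrow(cohort))
  }
}

check_scoring_fields <- function(cohort) {
  if (!is.data.frame(cohort)) stop("`cohort` must be a data frame", call. = FALSE)
  required <- c("diagnosis", "sex", "age", "fvc_pct_pred", "monocyte_ratio")
  missing_cols <- setdiff(c(required, "dlco_pct_pred"), names(cohort))
  # DLco may be supplied as an all-unmeasurable flag column instead
  if ("dlco_pct_pred" %in% missing_cols && "dlco_unmeasurable" %in% names(cohort) &&
      all(cohort$dlco_unmeasurable %in% 1)) {
    cohort$dlco_pct_pred <- NA_real_
    missing_cols <- setdiff(missing_cols, "dlco_pct_pred")
  }
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_field <- function(field, ok) {
    if (any(!ok)) {
      stop(sprintf("invalid `%s` in row(s) %s", field,
                   paste(utils::head(which(!ok), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_field("diagnosis", !is.na(cohort$diagnosis) &
              cohort$diagnosis %in% ild_diagnoses())
  bad_field("sex", !is.na(cohort$sex) & cohort$sex %in% ild_sexes())
  bad_field("age", is.numeric(cohort$age) & !is.na(cohort$age) & cohort$age >= 0)
  bad_field("fvc_pct_pred", is.numeric(cohort$fvc_pct_pred) &
              !is.na(cohort$fvc_pct_pred) & cohort$fvc_pct_pred > 0)
  bad_field("monocyte_ratio", is.numeric(cohort$monocyte_ratio) &
              !is.na(cohort$monocyte_ratio) & cohort$monocyte_ratio >= 0)
  unm <- cohort_dlco_unmeasurable(cohort)
  # a silently absent DLco is a schema error; only the explicit flag maps to
  # the "cannot perform" 3-point bin
  bad_field("dlco_pct_pred", unm |
              (!is.na(cohort$dlco_pct_pred) & is.numeric(cohort$dlco_pct_pred) &
                 cohort$dlco_pct_pred > 0))
  invisible(TRUE)
}
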