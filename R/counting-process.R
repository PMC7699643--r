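# Counting-process records: one row per subject-interval at risk, with the
# cumulative-average exposure at interval start and biennially updated
# covariates.  This is the single input format of the EWAS engine.

#' Assemble the counting-process table
#'
#' Splits each subject's follow-up into `(start, stop]` rows on the
#' interval grid, truncated at event, censoring, or administrative end.
#' Exposure columns carry the cumulative-average value at the panel
#' interval covering the row start; `age` is updated continuously on the
#' grid and `calories` (when `energy_kcal` is in the panel) is the
#' time-updated cumulative-average energy intake.  Other covariates enter
#' at their baseline values.  The event indicator is 1 only on a case's
#' final row; intermediate non-case diagnoses have already frozen the
#' panel's dietary values and do not end follow-up.
#'
#' @param subjects Subject tibble (retained set) with `entry_time`,
#'   `exit_time`, `event_indicator` and baseline covariates.
#' @param exposure_panel Output of [build_exposure_panel()].
#' @param interval_length Years per row before truncation.
#' @param panel_interval_starts Start times of the panel's intervals;
#'   defaults to a grid of `interval_length` starting at 0, matching the
#'   panel's `interval_index` range.
#' @param covariates Covariate columns to carry; defaults to every
#'   adjustment covariate present in `subjects` plus `age` and `calories`.
#' @return A `counting_process` tibble (`subject_id`, `start`, `stop`,
#'   `event`, covariates, one column per exposure), with attributes
#'   `exposure_cols`, `exposure_types`, `covariate_cols`, and
#'   `reference_levels` for the categorical codings.
#' @export
build_counting_process <- function(subjects, exposure_panel,
                                   interval_length = 2,
                                   panel_interval_starts = NULL,
                                   covariates = NULL) {
  if (any(subjects$exit_time <= subjects$entry_time)) {
    abort("event or censoring before entry")
  }
  if (any(subjects$entry_time < 0)) abort("negative entry time")

  n_panel_int <- max(exposure_panel$interval_index)
  panel_interval_starts <- panel_interval_starts %||%
    ((seq_len(n_panel_int) - 1) * interval_length)

  base_covs <- c(
    "bmi", "activity", "smoking", "ethnicity", "multivitamin",
    "vitamin_e_supp", "pm_hormones", "aspirin", "high_bp", "high_chol",
    "famhx_mi", "famhx_bp"
  )
  covariates <- covariates %||%
    c("age", intersect(base_covs, names(subjects)), "calories")

  # one row per subject-interval, truncated at exit
  k <- ceiling(subjects$exit_time / interval_length)
  rows <- tibble(
    subject_id = rep(subjects$subject_id, k),
    exit_time = rep(subjects$exit_time, k),
    event_indicator = rep(subjects$event_indicator, k),
    idx = sequence(k)
  ) %>%
    mutate(
      start = (idx - 1) * interval_length,
      stop = pmin(idx * interval_length, exit_time),
      event = as.integer(event_indicator == 1 & stop == exit_time),
      interval_index = findInterval(start, panel_interval_starts)
    )
  if (any(rows$stop <= rows$start)) abort("overlapping or empty interval")

  # exposures wide
  wide <- exposure_panel %>%
    tidyr::pivot_wider(
      id_cols = c(subject_id, interval_index),
      names_from = exposure_id, values_from = value
    )
  exposure_cols <- setdiff(names(wide), c("subject_id", "interval_index"))
  types <- exposure_panel %>% distinct(exposure_id, type)

  out <- rows %>%
    left_join(wide, by = c("subject_id", "interval_index")) %>%
    left_join(
      subjects %>%
        select(subject_id, any_of(c("age", base_covs))),
      by = "subject_id"
    )
  if ("age" %in% covariates) out <- out %>% mutate(age = age + start)
  if ("calories" %in% covariates) {
    if (!"energy_kcal" %in% exposure_cols) {
      covariates <- setdiff(covariates, "calories")
    } else {
      out <- out %>% mutate(calories = .data$energy_kcal)
    }
  }

  out <- out %>%
    select(
      subject_id, start, stop, event,
      all_of(intersect(covariates, names(out))),
      all_of(exposure_cols)
    )

  ref_levels <- list()
  if ("smoking" %in% names(out)) ref_levels$smoking <- "never"
  if ("ethnicity" %in% names(out)) ref_levels$ethnicity <- "white"

  structure(
    out,
    exposure_cols = exposure_cols,
    exposure_types = setNames(types$type, types$exposure_id),
    covariate_cols = intersect(covariates, names(out)),
    reference_levels = ref_levels,
    class = c("counting_process", class(out))
  )
}

#' Total person-time and event count of a counting-process table
#'
#' @param table A `counting_process` tibble.
#' @return A one-row tibble with `person_years`, `n_events`, `n_subjects`.
#' @export
person_time <- function(table) {
  tibble(
    person_years = sum(table$stop - table$start),
    n_events = sum(table$event),
    n_subjects = dplyr::n_distinct(table$subject_id)
  )
}

# numeric design matrix for the adjustment covariates, dummy-coding
# categoricals against their recorded reference levels
covariate_design <- function(table, covariates = NULL) {
  covariates <- covariates %||% attr(table, "covariate_cols")
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow(table), 0))
  }
  refs <- attr(table, "reference_levels") %||% list()
  df <- as.data.frame(table[, covariates, drop = FALSE])
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      f <- factor(df[[nm]])
      if (!is.null(refs[[nm]]) && refs[[nm]] %in% levels(f)) {
        f <- stats::relevel(f, refs[[nm]])
      }
      df[[nm]] <- f
    }
  }
  mf <- stats::model.frame(~., data = df, na.action = stats::na.pass)
  mm <- stats::model.matrix(~., data = mf)
  mm[, -1, drop = FALSE] # drop intercept (rows with NA are kept as NA)
}
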