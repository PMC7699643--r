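# FFQ frequency responses -> servings/day -> nutrient intakes ->
# cumulative-average time-varying exposures, plus the baseline exclusions.

#' Default frequency-to-servings conversion table
#'
#' Midpoint servings/day for the nine ordinal FFQ frequency categories,
#' from "almost never" (0) to "six or more times per day" (8).  The two
#' anchors are fixed by the instrument ("almost never" = 0, "once per
#' day" = 1); intermediate categories use the standard FFQ midpoint
#' convention.  Override by passing an edited copy (or one read from YAML
#' with [read_servings_map()]) wherever a `servings_map` argument exists.
#'
#' @return Named numeric vector of length 9, category labels as names.
#' @export
ffq_servings_map <- function() {
  c(
    "almost never" = 0,
    "1-3 per month" = 0.066,
    "1 per week" = 0.143,
    "2-4 per week" = 0.43,
    "5-6 per week" = 0.79,
    "1 per day" = 1,
    "2-3 per day" = 2.5,
    "4-5 per day" = 4.5,
    "6+ per day" = 6
  )
}

#' Read / write a frequency-to-servings mapping as YAML
#' @param path File path.
#' @return A named numeric vector of length 9.
#' @export
read_servings_map <- function(path) {
  m <- unlist(yaml::read_yaml(path))
  if (length(m) != 9) abort("servings map must have 9 categories")
  if (any(diff(m) < 0)) abort("servings map must be monotone nondecreasing")
  m
}

#' @param map Named numeric vector of length 9.
#' @rdname read_servings_map
#' @export
write_servings_map <- function(map, path) {
  yaml::write_yaml(as.list(map), path)
  invisible(path)
}

#' Convert FFQ frequency categories to servings per day
#'
#' @param category Integer vector of frequency categories in `0:8`
#'   (`NA` allowed, mapped to `NA`).
#' @param servings_map Conversion table, see [ffq_servings_map()].
#' @return Numeric vector of servings/day.
#' @examples
#' servings_per_day(c(0, 5, 8, NA))
#' @export
servings_per_day <- function(category, servings_map = ffq_servings_map()) {
  ok <- is.na(category) | (category %in% 0:8)
  if (!all(ok)) {
    abort(paste0(
      "frequency category outside 0..8: ",
      paste(unique(category[!ok]), collapse = ", ")
    ))
  }
  unname(servings_map[category + 1L])
}

#' Derive nutrient intakes from food servings
#'
#' Daily nutrient intake is the servings-weighted sum of the nutrient
#' content of all foods: `intake_i = sum_k servings_k * a[i, k]`.
#'
#' @param servings Tibble with columns `subject_id`, `cycle_index`,
#'   `food_id`, `servings`.
#' @param composition Long-form composition table
#'   (`nutrient_id`, `food_id`, `amount`).
#' @return Tibble `subject_id`, `cycle_index`, `nutrient_id`, `value`
#'   (composition units/day), one row per subject-wave-nutrient.
#' @export
nutrient_intakes <- function(servings, composition) {
  unknown <- setdiff(servings$food_id, composition$food_id)
  if (length(unknown)) {
    abort(paste0("unknown food(s): ", paste(unknown, collapse = ", ")))
  }
  foods <- sort(unique(servings$food_id))
  comp_m <- composition_matrix(
    composition %>% filter(food_id %in% foods), foods
  )
  wide <- servings %>%
    tidyr::pivot_wider(
      id_cols = c(subject_id, cycle_index),
      names_from = food_id, values_from = servings, values_fill = 0
    )
  sm <- as.matrix(wide[, foods, drop = FALSE])
  intakes <- sm %*% t(comp_m)
  out <- as_tibble(intakes)
  out$subject_id <- wide$subject_id
  out$cycle_index <- wide$cycle_index
  out %>%
    tidyr::pivot_longer(
      cols = all_of(rownames(comp_m)),
      names_to = "nutrient_id", values_to = "value"
    ) %>%
    select(subject_id, cycle_index, nutrient_id, value) %>%
    arrange(subject_id, cycle_index, nutrient_id)
}

#' Apply the baseline exclusion criteria
#'
#' Excludes subjects with a history of disease at baseline (CVD, diabetes,
#' or cancer), missing demographic data, implausible reported energy intake
#' (strictly below 600 or strictly above 3500 kcal/day at the baseline
#' wave), or more than `max_blanks` unanswered FFQ items at baseline.
#' Item-level missing responses within a returned questionnaire count as
#' blanks for the blank rule but as zero intake for the energy computation.
#'
#' @param subjects Subject tibble (see [generate_cohort()]).
#' @param ffq FFQ response panel
#'   (`subject_id`, `cycle_index`, `food_id`, `frequency_category`).
#' @param composition Composition table containing the `energy_kcal` row.
#' @param energy_range Retained range of baseline energy, inclusive.
#' @param max_blanks Retain subjects with at most this many blank items.
#' @param servings_map See [ffq_servings_map()].
#' @return List with `retained` (subject tibble) and `log` (tibble
#'   `subject_id`, `reason`); each excluded subject appears once, under the
#'   first matching rule in the order baseline disease, missing
#'   demographics, blanks, low energy, high energy.
#' @export
apply_exclusions <- function(subjects, ffq, composition,
                             energy_range = c(600, 3500), max_blanks = 70,
                             servings_map = ffq_servings_map()) {
  baseline_cycle <- min(ffq$cycle_index)
  base <- ffq %>% filter(cycle_index == baseline_cycle)

  blanks <- base %>%
    group_by(subject_id) %>%
    summarise(n_blank = sum(is.na(frequency_category)), .groups = "drop")

  energy <- base %>%
    mutate(servings = dplyr::coalesce(
      servings_per_day(frequency_category, servings_map), 0
    )) %>%
    nutrient_intakes(composition %>% filter(nutrient_id == "energy_kcal")) %>%
    select(subject_id, energy = value)

  demog <- c("age", "bmi", "activity", "smoking", "ethnicity")
  flags <- subjects %>%
    left_join(blanks, by = "subject_id") %>%
    left_join(energy, by = "subject_id") %>%
    mutate(
      r_disease = baseline_cvd == 1 | baseline_diabetes == 1 |
        baseline_cancer == 1,
      r_demog = !complete.cases(
        dplyr::pick(any_of(demog))
      ),
      r_low = !is.na(energy) & energy < energy_range[1],
      r_high = !is.na(energy) & energy > energy_range[2],
      r_blank = !is.na(n_blank) & n_blank > max_blanks,
      # blanks take precedence over energy: an FFQ that is mostly blank
      # yields a meaningless energy total
      reason = dplyr::case_when(
        r_disease ~ "baseline_disease",
        r_demog ~ "missing_demographics",
        r_blank ~ "many_blanks",
        r_low ~ "low_energy",
        r_high ~ "high_energy",
        TRUE ~ NA_character_
      )
    )

  log <- flags %>%
    filter(!is.na(reason)) %>%
    select(subject_id, reason)
  retained <- subjects %>% anti_join(log, by = "subject_id")
  if (nrow(retained) == 0) warn("all subjects excluded")
  list(retained = retained, log = log)
}

#' Cumulative-average exposure series on the follow-up interval grid
#'
#' The exposure carried into a follow-up interval is the mean of all wave
#' values observed at or before the interval start; missing waves are
#' skipped.  After `freeze_time` (an intermediate diagnosis that stops
#' dietary updates) later waves are ignored, so the series holds at the
#' last pre-freeze average.
#'
#' @param wave_values Numeric vector of per-wave measurements (`NA` =
#'   missing wave).
#' @param wave_times Times (years on study) of the waves, sorted.
#' @param interval_starts Start times of the follow-up intervals.
#' @param freeze_time Optional freeze time; `NA`/`NULL` for none.
#' @return Numeric vector over intervals; `NA` where no usable wave exists
#'   yet.
#' @examples
#' cumulative_average(c(2, 4, 6), c(0, 4, 8), seq(0, 10, 2), freeze_time = 5)
#' @export
cumulative_average <- function(wave_values, wave_times, interval_starts,
                               freeze_time = NULL) {
  if (is.unsorted(wave_times)) abort("wave_times must be sorted")
  freeze <- freeze_time %||% Inf
  if (is.na(freeze)) freeze <- Inf
  vapply(interval_starts, function(t0) {
    use <- wave_times <= min(t0, freeze) & !is.na(wave_values)
    if (!any(use)) NA_real_ else mean(wave_values[use])
  }, numeric(1))
}

#' Build the time-varying exposure panel
#'
#' Converts the FFQ panel to servings/day, derives nutrient intakes from
#' the composition table, and cumulative-averages every food and nutrient
#' exposure onto the follow-up interval grid, honouring per-subject freeze
#' times (dietary updates stop at an intermediate diagnosis).  A wave in
#' which a subject answered no items at all is treated as a missing wave;
#' item-level blanks within a returned wave count as zero intake.
#'
#' @param ffq FFQ response panel.
#' @param composition Composition table.
#' @param wave_times Times of the FFQ waves (years on study).
#' @param interval_starts Start times of the follow-up intervals.
#' @param freeze_times Optional tibble `subject_id`,
#'   `intermediate_diagnosis_time`; non-`NA` entries freeze later waves.
#' @param exposures Optional character vector restricting the exposures
#'   (food and/or nutrient ids) in the panel; default all.
#' @param servings_map See [ffq_servings_map()].
#' @return Long tibble `subject_id`, `interval_index`, `exposure_id`,
#'   `type` (`"food"`/`"nutrient"`), `value`.
#' @export
build_exposure_panel <- function(ffq, composition, wave_times,
                                 interval_starts, freeze_times = NULL,
                                 exposures = NULL,
                                 servings_map = ffq_servings_map()) {
  foods <- sort(unique(ffq$food_id))
  nutrients <- unique(composition$nutrient_id)
  keep <- exposures %||% c(foods, nutrients)
  unknown <- setdiff(keep, c(foods, nutrients))
  if (length(unknown)) {
    abort(paste0("unknown exposure(s): ", paste(unknown, collapse = ", ")))
  }

  subjects <- sort(unique(ffq$subject_id))
  n <- length(subjects)
  cycles <- sort(unique(ffq$cycle_index))
  w <- length(cycles)
  if (length(wave_times) != w) {
    abort("wave_times must match the number of FFQ cycles")
  }

  # servings array (subject x food x wave) and whole-wave missingness
  serv <- array(NA_real_, c(n, length(foods), w))
  idx <- cbind(
    match(ffq$subject_id, subjects),
    match(ffq$food_id, foods),
    match(ffq$cycle_index, cycles)
  )
  serv[idx] <- servings_per_day(ffq$frequency_category, servings_map)
  wave_missing <- apply(is.na(serv), c(1, 3), all)
  serv[is.na(serv)] <- 0

  comp_m <- composition_matrix(
    composition %>% filter(food_id %in% foods), foods
  )

  keep_foods <- intersect(keep, foods)
  keep_nutrients <- intersect(keep, nutrients)
  p <- length(keep_foods) + length(keep_nutrients)
  wave_vals <- array(NA_real_, c(n, p, w))
  for (t in seq_len(w)) {
    st <- serv[, , t, drop = FALSE]
    dim(st) <- c(n, length(foods))
    block <- cbind(
      st[, match(keep_foods, foods), drop = FALSE],
      st %*% t(comp_m[keep_nutrients, , drop = FALSE])
    )
    block[wave_missing[, t], ] <- NA_real_
    wave_vals[, , t] <- block
  }

  freeze <- rep(Inf, n)
  if (!is.null(freeze_times)) {
    m <- match(subjects, freeze_times$subject_id)
    f <- freeze_times$intermediate_diagnosis_time[m]
    freeze[!is.na(f)] <- f[!is.na(f)]
  }

  n_int <- length(interval_starts)
  value <- array(0, c(n, p, n_int))
  for (i in seq_len(n_int)) {
    num <- matrix(0, n, p)
    den <- matrix(0, n, p)
    for (t in seq_len(w)) {
      use <- (wave_times[t] <= pmin(interval_starts[i], freeze)) &
        !wave_missing[, t]
      if (any(use)) {
        vt <- wave_vals[, , t, drop = FALSE]
        dim(vt) <- c(n, p)
        num[use, ] <- num[use, ] + vt[use, , drop = FALSE]
        den[use, ] <- den[use, ] + 1
      }
    }
    vals <- num / den
    vals[den == 0] <- NA_real_
    value[, , i] <- vals
  }

  exposure_ids <- c(keep_foods, keep_nutrients)
  tibble(
    subject_id = rep(subjects, times = p * n_int),
    exposure_id = rep(rep(exposure_ids, each = n), times = n_int),
    interval_index = rep(seq_len(n_int), each = n * p),
    value = as.vector(value)
  ) %>%
    mutate(type = if_else(exposure_id %in% foods, "food", "nutrient")) %>%
    select(subject_id, interval_index, exposure_id, type, value) %>%
    arrange(subject_id, interval_index, exposure_id)
}
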