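#' Configuration for a synthetic longitudinal diet-disease cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size, the
#' dietary instrument (number of FFQ food items, derivable nutrients, and
#' questionnaire waves), the follow-up grid, the generative hazard model
#' (true exposure effects, confounder effects, baseline hazard, censoring),
#' the strength of confounding between covariates and diet, and the
#' fractions of subjects seeded with records that must trigger the baseline
#' exclusion rules.
#'
#' Effects are on the log-hazard scale: `true_effects` per 1 SD of the
#' population cumulative-average intake of the named exposure,
#' `confounder_effects` per 1 SD of a continuous covariate or per level of
#' an indicator.
#'
#' @param n_subjects Number of subjects.
#' @param n_foods Number of FFQ food items.
#' @param n_nutrients Number of derivable nutrients, including energy
#'   (kcal/day), which is always the first nutrient.
#' @param n_cycles Number of FFQ waves (every `cycle_spacing` years from
#'   baseline).
#' @param cycle_spacing Years between FFQ waves.
#' @param interval_length Years per follow-up interval (the grid on which
#'   exposures and covariates are updated).
#' @param followup_years Total administrative follow-up.
#' @param true_effects Named numeric vector, exposure id -> log-hazard per SD.
#' @param confounder_effects Named numeric vector over the generator's
#'   hazard covariates (`age`, `bmi`, `activity`, `smoking_current`,
#'   `calories`).
#' @param confounding_strength Scale of the covariate -> diet propensity
#'   link; 0 switches confounding off.
#' @param latent_hazard_effect Log-hazard per unit of the latent
#'   healthy-diet propensity itself (default 0).  A nonzero value models
#'   residual confounding: an unmeasured health-behaviour factor that
#'   shapes both diet and risk and is not in the adjustment set.
#' @param within_person_sd SD of wave-to-wave noise on the latent
#'   consumption scale (random within-person variation of the instrument).
#' @param baseline_hazard Baseline event rate per person-year.
#' @param censoring_rate Independent censoring rate per person-year.
#' @param intermediate_rate Rate per person-year of intermediate (non-case)
#'   diagnoses that freeze dietary updates but keep the subject at risk.
#' @param exclusion_fractions Named numeric vector with entries
#'   `low_energy`, `high_energy`, `many_blanks`, `baseline_disease`,
#'   `missing_demographics`: fractions of subjects seeded to trigger each
#'   baseline exclusion rule.
#' @param seed Integer seed; identical configurations reproduce
#'   byte-identical studies.
#'
#' @return An object of class `study_config` (a validated named list).
#' @examples
#' cfg <- study_config(n_subjects = 200, n_foods = 20, n_nutrients = 6)
#' cfg$n_cycles
#' @export
study_config <- function(n_subjects = 2000,
                         n_foods = 80,
                         n_nutrients = 25,
                         n_cycles = 3,
                         cycle_spacing = 4,
                         interval_length = 2,
                         followup_years = 10,
                         true_effects = c(),
                         confounder_effects = c(
                           age = 0.9, bmi = 0.25, activity = -0.25,
                           smoking_current = 0.6, calories = 0.15
                         ),
                         confounding_strength = 0.8,
                         latent_hazard_effect = 0,
                         within_person_sd = 0.4,
                         baseline_hazard = 0.004,
                         censoring_rate = 0.015,
                         intermediate_rate = 0.008,
                         exclusion_fractions = c(
                           low_energy = 0.01, high_energy = 0.01,
                           many_blanks = 0.01, baseline_disease = 0.03,
                           missing_demographics = 0.01
                         ),
                         seed = 1L) {
  counts <- c(
    n_subjects = n_subjects, n_foods = n_foods, n_nutrients = n_nutrients,
    n_cycles = n_cycles
  )
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("all counts must be positive integers")
  }
  if (n_cycles < 2) abort("n_cycles must be at least 2")
  if (n_nutrients < 1) abort("need at least the energy nutrient")
  if (baseline_hazard < 0) abort("baseline_hazard must be nonnegative")
  if (censoring_rate < 0 || intermediate_rate < 0) {
    abort("rates must be nonnegative")
  }
  if (interval_length <= 0 || followup_years <= 0 || cycle_spacing <= 0) {
    abort("time parameters must be positive")
  }
  needed <- c(
    "low_energy", "high_energy", "many_blanks", "baseline_disease",
    "missing_demographics"
  )
  fr <- setNames(rep(0, length(needed)), needed)
  for (nm in intersect(names(unlist(exclusion_fractions)), needed)) {
    fr[nm] <- exclusion_fractions[[nm]]
  }
  if (any(fr < 0 | fr > 1)) abort("exclusion fractions must lie in [0, 1]")
  if (sum(fr) > 1) abort("exclusion fractions must sum to at most 1")
  true_effects <- unlist(true_effects)
  if (length(true_effects) && is.null(names(true_effects))) {
    abort("true_effects must be a named vector (exposure id -> log-hazard)")
  }
  conf_names <- c("age", "bmi", "activity", "smoking_current", "calories")
  confounder_effects <- unlist(confounder_effects)
  if (length(confounder_effects) &&
    !all(names(confounder_effects) %in% conf_names)) {
    abort(paste(
      "confounder_effects names must be among:",
      paste(conf_names, collapse = ", ")
    ))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_foods = as.integer(n_foods),
      n_nutrients = as.integer(n_nutrients), n_cycles = as.integer(n_cycles),
      cycle_spacing = cycle_spacing, interval_length = interval_length,
      followup_years = followup_years,
      true_effects = true_effects,
      confounder_effects = confounder_effects,
      confounding_strength = confounding_strength,
      latent_hazard_effect = latent_hazard_effect,
      within_person_sd = within_person_sd,
      baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
      intermediate_rate = intermediate_rate,
      exclusion_fractions = fr,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf(
    "  %d subjects, %d foods, %d nutrients, %d FFQ waves\n",
    x$n_subjects, x$n_foods, x$n_nutrients, x$n_cycles
  ))
  cat(sprintf(
    "  follow-up %g y on a %g-y grid; h0 = %g /py, censoring %g /py\n",
    x$followup_years, x$interval_length, x$baseline_hazard, x$censoring_rate
  ))
  cat(sprintf(
    "  %d true exposure effect(s); confounding strength %g\n",
    length(x$true_effects), x$confounding_strength
  ))
  invisible(x)
}

#' Read or write a study configuration as YAML
#'
#' @param path File path.
#' @return `read_study_config()` returns a [study_config()];
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("true_effects", "confounder_effects", "exclusion_fractions")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(study_config, raw)
}

#' @param config A [study_config()].
#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- unclass(config)
  out$true_effects <- as.list(out$true_effects)
  out$confounder_effects <- as.list(out$confounder_effects)
  out$exclusion_fractions <- as.list(out$exclusion_fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

food_ids <- function(n) sprintf("food_%03d", seq_len(n))

nutrient_ids <- function(n) {
  c("energy_kcal", sprintf("nutrient_%03d", seq_len(n))[-1])
}
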