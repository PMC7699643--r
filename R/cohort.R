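# Synthetic longitudinal cohort with confounded diet, repeated FFQ waves,
# and proportional-hazards event times with known true effects.

#' Simulate event and censoring times from a piecewise-exponential hazard
#'
#' Event times are drawn by inverse-transform sampling from the hazard
#' `h0 * exp(lp(t))`, with the linear predictor `lp` piecewise-constant on
#' the follow-up interval grid.  Censoring is an independent exponential
#' clock plus an administrative end of follow-up.
#'
#' @param lp Numeric matrix, subjects by intervals: the linear predictor on
#'   each follow-up interval.
#' @param baseline_hazard Baseline event rate per person-year (`h0`).
#' @param censoring_rate Censoring rate per person-year (0 for none).
#' @param interval_length Years per interval.
#' @param followup_years Administrative end of follow-up; defaults to the
#'   end of the grid.  May be `Inf` only when `censoring_rate > 0` or every
#'   subject is guaranteed an event within the grid extended indefinitely
#'   at its final hazard.
#' @return A tibble with `exit_time` and `event_indicator` per subject
#'   (`event_indicator = 1` iff the event precedes censoring and the
#'   administrative end).
#' @examples
#' lp <- matrix(0, 100, 5)
#' simulate_event_times(lp, baseline_hazard = 0.1, censoring_rate = 0)
#' @export
simulate_event_times <- function(lp, baseline_hazard, censoring_rate = 0,
                                 interval_length = 2,
                                 followup_years = NULL) {
  lp <- as.matrix(lp)
  n <- nrow(lp)
  k <- ncol(lp)
  if (baseline_hazard < 0) abort("negative hazard")
  if (censoring_rate < 0) abort("negative censoring rate")
  followup_years <- followup_years %||% (k * interval_length)

  # cumulative hazard at the end of each interval; beyond the grid the
  # hazard continues at its final interval value
  haz <- baseline_hazard * exp(lp)
  cumhaz <- t(apply(haz * interval_length, 1, cumsum))
  if (k == 1) cumhaz <- matrix(cumhaz, ncol = 1)
  target <- rexp(n)
  event_time <- rep(Inf, n)
  if (baseline_hazard > 0) {
    for (j in seq_len(n)) {
      idx <- which(cumhaz[j, ] >= target[j])
      if (length(idx)) {
        i <- idx[1]
        prev <- if (i == 1) 0 else cumhaz[j, i - 1]
        event_time[j] <- (i - 1) * interval_length +
          (target[j] - prev) / haz[j, i]
      } else {
        event_time[j] <- k * interval_length +
          (target[j] - cumhaz[j, k]) / haz[j, k]
      }
    }
  }
  censor_time <- if (censoring_rate > 0) rexp(n, censoring_rate) else Inf
  exit_time <- pmin(event_time, censor_time, followup_years)
  if (any(!is.finite(exit_time))) {
    abort("infinite follow-up requires censoring or a positive hazard")
  }
  tibble(
    exit_time = exit_time,
    event_indicator = as.integer(event_time <= pmin(
      censor_time, followup_years
    ))
  )
}

#' Generate a synthetic longitudinal diet-disease study
#'
#' Draws baseline covariates, a latent healthy-diet propensity confounded
#' with those covariates, repeated FFQ waves with within-subject
#' autocorrelation, composition-derived nutrient exposures, and
#' proportional-hazards event times whose linear predictor combines the
#' configured covariate effects with the configured true exposure effects
#' (per 1 SD of the population cumulative-average intake).  Subjects seeded
#' to trigger each baseline exclusion rule are flagged in the output.
#'
#' Intermediate (non-case) diagnoses arrive as an independent Poisson
#' process; they freeze later dietary updates but leave the subject at
#' risk, mirroring the stop-update rule for non-cases.
#'
#' @param config A [study_config()].
#' @param composition Optional composition table; defaults to
#'   [make_composition_table()] under the same seed.
#' @return An object of class `synthetic_study`: a list with `subjects`,
#'   `ffq`, `composition`, `wave_times`, and `truth` (the configuration
#'   echo plus the exposure scales used when applying true effects).
#' @export
generate_cohort <- function(config, composition = NULL) {
  stopifnot(inherits(config, "study_config"))
  composition <- composition %||% make_composition_table(config)
  foods <- food_ids(config$n_foods)
  nutrients <- nutrient_ids(config$n_nutrients)
  known <- c(foods, nutrients)
  bad <- setdiff(names(config$true_effects), known)
  if (length(bad)) {
    abort(paste0(
      "true_effects name unknown exposure(s): ", paste(bad, collapse = ", ")
    ))
  }

  n <- config$n_subjects
  waves <- config$n_cycles
  wave_times <- (seq_len(waves) - 1) * config$cycle_spacing
  n_int <- ceiling(config$followup_years / config$interval_length)
  interval_starts <- (seq_len(n_int) - 1) * config$interval_length

  with_seed(config$seed, {
    subjects <- draw_baseline_covariates(n)
    seeded <- seed_exclusion_groups(n, config$exclusion_fractions)
    subjects$seeded_exclusion <- seeded

    # confounded healthy-diet propensity
    z_age <- (subjects$age - 52.5) / 7.2
    z_bmi <- (subjects$bmi - 25.5) / 4.5
    z_act <- (log(subjects$activity) - log(15)) / 0.6
    smk <- as.numeric(subjects$smoking == "current")
    u <- config$confounding_strength *
      (0.35 * z_act - 0.30 * z_bmi - 0.50 * smk - 0.15 * z_age) + rnorm(n)

    food_mean <- rnorm(config$n_foods, -0.9, 0.8)
    food_loading <- runif(config$n_foods, -1, 1)
    latent <- ffq_latent(
      n, config$n_foods, waves, food_mean, food_loading, u,
      config$within_person_sd
    )

    # per-subject appetite shift keeping non-seeded baseline energy inside
    # the plausible-reporting window, and pushing seeded subjects outside it
    energy_row <- composition_matrix(
      composition %>% filter(nutrient_id == "energy_kcal"), foods
    )[1, ]
    shift <- calibrate_energy(
      latent, energy_row, seeded,
      in_range = c(600, 3500), low = c(200, 599), high = c(3501, 6000)
    )
    latent <- latent + array(shift, dim = dim(latent))

    categories <- latent_to_category(latent)

    # seed FFQ blanks at baseline for the many-blanks group
    n_blank <- min(config$n_foods, ceiling(0.9 * config$n_foods))
    for (j in which(seeded == "many_blanks")) {
      blank <- sample(config$n_foods, n_blank)
      categories[j, blank, 1] <- NA_integer_
    }

    ffq <- tibble(
      subject_id = rep(subjects$subject_id, times = config$n_foods * waves),
      cycle_index = rep(seq_len(waves), each = n * config$n_foods),
      food_id = rep(rep(foods, each = n), times = waves),
      frequency_category = as.integer(as.vector(categories))
    ) %>% arrange(subject_id, cycle_index, food_id)

    # linear predictor on the interval grid
    lp <- matrix(0, n, n_int)
    ce <- config$confounder_effects
    eff <- function(nm) if (nm %in% names(ce)) ce[[nm]] else 0
    if (eff("age") != 0) {
      for (i in seq_len(n_int)) {
        lp[, i] <- lp[, i] +
          eff("age") * (subjects$age + interval_starts[i] - 52.5) / 7.2
      }
    }
    lp <- lp + eff("bmi") * z_bmi + eff("activity") * z_act +
      eff("smoking_current") * smk +
      (config$latent_hazard_effect %||% 0) * u

    # exposure paths actually used by the hazard (true long-term diet,
    # unfrozen): cumulative averages of the composition-derived intakes
    need <- union(
      names(config$true_effects),
      if (eff("calories") != 0) "energy_kcal" else character()
    )
    scales <- list()
    if (length(need)) {
      cumavg <- cumavg_exposure_matrix(
        categories, foods, composition, need, wave_times, interval_starts
      )
      for (ex in need) {
        v <- cumavg[[ex]]
        if (ex == "energy_kcal" && eff("calories") != 0) {
          # the calorie confounder acts on the raw scale, matching its
          # untransformed entry in the adjustment set
          lp <- lp + eff("calories") * (v - mean(v[, 1])) / sd(v[, 1])
        }
        if (ex %in% names(config$true_effects)) {
          # true effects are per 1 SD of the variance-stabilized
          # (Box-Cox) cumulative-average intake, the scale on which the
          # scan reports effect sizes
          tr <- transform_exposure(as.vector(v))
          zv <- matrix(apply_transform(tr, as.vector(v)), nrow(v), ncol(v))
          scales[[ex]] <- tr
          lp <- lp + unname(config$true_effects[ex]) * zv
        }
      }
    }

    surv <- simulate_event_times(
      lp, config$baseline_hazard, config$censoring_rate,
      config$interval_length, config$followup_years
    )
    subjects$entry_time <- 0
    subjects$exit_time <- surv$exit_time
    subjects$event_indicator <- surv$event_indicator

    # intermediate non-case diagnoses (freeze dietary updates only)
    inter <- if (config$intermediate_rate > 0) {
      rexp(n, config$intermediate_rate)
    } else {
      rep(Inf, n)
    }
    subjects$intermediate_diagnosis_time <-
      if_else(inter < subjects$exit_time, inter, NA_real_)

    # exclusion seeding that lives on the subject record (applied last so
    # the generative model above sees complete values)
    dis <- which(seeded == "baseline_disease")
    if (length(dis)) {
      flag <- sample(
        c("baseline_cvd", "baseline_diabetes", "baseline_cancer"),
        length(dis),
        replace = TRUE
      )
      for (f in unique(flag)) subjects[[f]][dis[flag == f]] <- 1L
    }
    subjects$bmi[seeded == "missing_demographics"] <- NA_real_
  })

  structure(
    list(
      subjects = subjects, ffq = ffq, composition = composition,
      wave_times = wave_times,
      truth = list(
        config = config, true_effects = config$true_effects,
        exposure_scales = scales
      )
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf(
    "  %d subjects, %d events (%.1f%%), %d FFQ waves, %d foods\n",
    nrow(x$subjects), sum(x$subjects$event_indicator),
    100 * mean(x$subjects$event_indicator), length(x$wave_times),
    length(unique(x$ffq$food_id))
  ))
  invisible(x)
}

draw_baseline_covariates <- function(n) {
  tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = runif(n, 40, 65),
    bmi = pmax(rnorm(n, 25.5, 4.5), 15),
    activity = stats::rlnorm(n, log(15), 0.6),
    smoking = sample(c("never", "past", "current"), n, TRUE,
      prob = c(0.45, 0.30, 0.25)
    ),
    ethnicity = sample(c("white", "black", "asian", "other"), n, TRUE,
      prob = c(0.90, 0.04, 0.03, 0.03)
    ),
    multivitamin = rbinom(n, 1, 0.35),
    vitamin_e_supp = rbinom(n, 1, 0.15),
    pm_hormones = rbinom(n, 1, 0.30),
    aspirin = rbinom(n, 1, 0.25),
    high_bp = rbinom(n, 1, 0.20),
    high_chol = rbinom(n, 1, 0.25),
    famhx_mi = rbinom(n, 1, 0.15),
    famhx_bp = rbinom(n, 1, 0.30),
    baseline_cvd = 0L, baseline_diabetes = 0L, baseline_cancer = 0L
  )
}

seed_exclusion_groups <- function(n, fractions) {
  seeded <- rep("none", n)
  pool <- sample.int(n)
  taken <- 0
  for (grp in names(fractions)) {
    k <- round(fractions[[grp]] * n)
    if (k > 0) {
      seeded[pool[taken + seq_len(k)]] <- grp
      taken <- taken + k
    }
  }
  seeded
}

# latent consumption array: subjects x foods x waves
ffq_latent <- function(n, n_foods, waves, food_mean, food_loading, u,
                       within_sd) {
  between <- matrix(rnorm(n * n_foods, sd = 0.6), n, n_foods)
  base <- outer(u, food_loading) + between +
    matrix(food_mean, n, n_foods, byrow = TRUE)
  arr <- array(0, dim = c(n, n_foods, waves))
  for (t in seq_len(waves)) {
    arr[, , t] <- base + matrix(rnorm(n * n_foods, sd = within_sd), n, n_foods)
  }
  arr
}

ffq_category_thresholds <- function() c(-0.5, 0, 0.5, 1, 1.5, 2, 2.5, 3)

latent_to_category <- function(latent) {
  arr <- array(
    findInterval(latent, ffq_category_thresholds()),
    dim = dim(latent)
  )
  arr
}

# Bisect an additive latent shift per subject so baseline energy lands in
# the target window.  Energy is nondecreasing in the shift, so bisection on
# the (step-valued) map is safe; the windows are wide relative to the step
# caused by one food moving one frequency category.
calibrate_energy <- function(latent, energy_row, seeded, in_range, low,
                             high) {
  n <- dim(latent)[1]
  shift <- numeric(n)
  base <- latent[, , 1, drop = FALSE]
  dim(base) <- dim(latent)[1:2]
  energy_of <- function(lat_row, s) {
    cats <- findInterval(lat_row + s, ffq_category_thresholds())
    sum(servings_per_day(cats) * energy_row)
  }
  target <- rbind(
    none = in_range, low_energy = low, high_energy = high
  )
  for (j in seq_len(n)) {
    grp <- switch(seeded[j],
      low_energy = "low_energy",
      high_energy = "high_energy",
      "none"
    )
    win <- target[grp, ]
    e <- energy_of(base[j, ], 0)
    if (e >= win[1] && e <= win[2]) next
    lo <- -10
    hi <- 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      e <- energy_of(base[j, ], mid)
      if (e < win[1]) lo <- mid else if (e > win[2]) hi <- mid else break
    }
    shift[j] <- mid
  }
  shift
}

# cumulative-average intake matrices (subjects x intervals) for the named
# exposures, computed directly from the category array (generator-internal
# fast path; the analysis-facing path lives in the diet-processing module)
cumavg_exposure_matrix <- function(categories, foods, composition, need,
                                   wave_times, interval_starts) {
  n <- dim(categories)[1]
  waves <- dim(categories)[3]
  serv <- array(
    servings_per_day(as.vector(categories)),
    dim = dim(categories)
  )
  serv[is.na(serv)] <- 0
  comp_m <- composition_matrix(composition, foods)
  out <- list()
  for (ex in need) {
    wave_vals <- matrix(0, n, waves)
    for (t in seq_len(waves)) {
      if (ex %in% rownames(comp_m)) {
        wave_vals[, t] <- serv[, , t] %*% comp_m[ex, ]
      } else {
        wave_vals[, t] <- serv[, match(ex, foods), t]
      }
    }
    csum <- t(apply(wave_vals, 1, cumsum))
    if (waves == 1) csum <- matrix(csum, ncol = 1)
    vals <- matrix(0, n, length(interval_starts))
    for (i in seq_along(interval_starts)) {
      k <- sum(wave_times <= interval_starts[i])
      k <- max(k, 1)
      vals[, i] <- csum[, k] / k
    }
    out[[ex]] <- vals
  }
  out
}
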