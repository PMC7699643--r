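# Shared fixtures, all built in code.

# tiny study configuration used across module tests
small_config <- function(...) {
  study_config(
    n_subjects = 300, n_foods = 15, n_nutrients = 6, n_cycles = 3,
    followup_years = 8, seed = 42, ...
  )
}

# wrap a plain tibble as a counting_process table with the attributes the
# engine expects
as_counting_process <- function(df, exposure_cols,
                                covariate_cols = character(0),
                                exposure_types = NULL,
                                reference_levels = list()) {
  structure(
    df,
    exposure_cols = exposure_cols,
    exposure_types = exposure_types %||%
      setNames(rep("nutrient", length(exposure_cols)), exposure_cols),
    covariate_cols = covariate_cols,
    reference_levels = reference_levels,
    class = c("counting_process", class(df))
  )
}

# random single-interval survival data for engine-level tests: one row per
# subject, exposure x (optionally null), k extra covariates
sim_simple_surv <- function(n, beta = 0, n_cov = 0, rate = 0.1,
                            cens = 0.05, admin = Inf) {
  x <- rnorm(n)
  cm <- if (n_cov > 0) matrix(rnorm(n * n_cov), n, n_cov) else NULL
  lp <- beta * x
  t_event <- rexp(n, rate * exp(lp))
  t_cens <- pmin(rexp(n, cens), admin)
  tibble::tibble(
    subject_id = sprintf("P%04d", seq_len(n)),
    start = 0,
    stop = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    x = x
  ) -> df
  if (!is.null(cm)) {
    colnames(cm) <- paste0("c", seq_len(n_cov))
    df <- dplyr::bind_cols(df, tibble::as_tibble(cm))
  }
  df
}

`%||%` <- rlang::`%||%`
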