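# End-to-end driver: synthetic study -> exclusions -> exposures ->
# counting process -> scan -> permutation FDR -> network -> replication.
# Every artifact is written as delimited text so a run is fully inspectable
# and reproducible from its config and seed.

#' Run the full association-scan pipeline on a synthetic study
#'
#' Generates the discovery cohort, applies the baseline exclusions, builds
#' the cumulative-average exposure panel and counting-process table, runs
#' the per-exposure Cox scan, estimates the permutation FDR with the
#' biased-pool null, builds the food-nutrient network and its actual
#' versus food-implied hazard-ratio comparison, and (when
#' `replication_config` is given) repeats the scan on an independent
#' replication cohort to validate the significant set.
#'
#' @param config Discovery [study_config()].
#' @param out_dir Optional directory; when given, every artifact is
#'   written there as TSV/YAML/GraphML/JSON.
#' @param exposures Exposure ids to scan; default all foods and nutrients.
#' @param m_permutations Permutations for the null distribution.
#' @param q Target FDR level.
#' @param replication_config Optional [study_config()] for the
#'   replication cohort (use a different seed).
#' @param covariates Adjustment covariates; default the full recorded set
#'   of the counting-process table.
#' @param max_blanks Blank-item threshold of the exclusion filter.
#' @return A list with the study, exclusion log, exposure panel,
#'   counting-process table, scan results (FDR-annotated), propensity
#'   scores, null p-values, fdr estimate, network, comparison,
#'   replication results, validation decisions, manhattan table, and
#'   written paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, exposures = NULL,
                         m_permutations = 100, q = 0.05,
                         replication_config = NULL, covariates = NULL,
                         max_blanks = 70) {
  study <- generate_cohort(config)
  n_int <- ceiling(config$followup_years / config$interval_length)
  interval_starts <- (seq_len(n_int) - 1) * config$interval_length

  excl <- apply_exclusions(
    study$subjects, study$ffq, study$composition,
    max_blanks = max_blanks
  )
  retained <- excl$retained
  ffq_kept <- study$ffq %>% semi_join(retained, by = "subject_id")

  panel <- build_exposure_panel(
    ffq_kept, study$composition, study$wave_times, interval_starts,
    freeze_times = retained %>%
      select(subject_id, intermediate_diagnosis_time),
    exposures = if (!is.null(exposures)) union(exposures, "energy_kcal")
  )
  cp <- build_counting_process(
    retained, panel,
    interval_length = config$interval_length
  )

  scan_exposures <- exposures %||% attr(cp, "exposure_cols")
  results <- run_ewas(cp, scan_exposures, covariates = covariates)
  if (!nrow(results)) {
    fails <- attr(results, "failures")
    abort(paste0(
      "every exposure fit failed (first error: ", fails$error[1],
      "); the cohort is probably too small for the adjustment set - ",
      "reduce `covariates` or enlarge the study"
    ))
  }
  scores <- fit_case_propensity(cp, covariates)
  null <- build_null_distribution(
    cp, results$exposure_id, covariates,
    m = m_permutations, scores = scores,
    seed = config$seed + 10000L
  )
  results <- add_fdr(results, null, q)
  est <- attr(results, "fdr_estimate")

  network <- build_network(results, study$composition)
  comparison <- if (nrow(network$edges)) {
    compare_actual_vs_expected(network)
  }
  manhattan <- manhattan_table(results, est$alpha_star)

  replication <- validation <- NULL
  if (!is.null(replication_config)) {
    sig <- results %>%
      filter(significant) %>%
      pull(exposure_id)
    rep_run <- run_scan_only(
      replication_config, exposures = scan_exposures,
      covariates = covariates, max_blanks = max_blanks
    )
    replication <- rep_run$results
    if (length(sig)) {
      validation <- validate_replication(
        results %>% filter(significant), replication,
        q = q
      )
    }
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_pipeline_outputs(
      out_dir, config, study, excl, panel, cp, results, null, est,
      network, comparison, manhattan, replication, validation
    )
  }

  list(
    study = study, exclusion_log = excl$log, retained = retained,
    panel = panel, counting_process = cp, results = results,
    propensity = scores, null = null, fdr = est, network = network,
    comparison = comparison, manhattan = manhattan,
    replication = replication, validation = validation, paths = paths
  )
}

# generate + process + scan, without FDR machinery (replication arm)
run_scan_only <- function(config, exposures = NULL, covariates = NULL,
                          max_blanks = 70) {
  study <- generate_cohort(config)
  n_int <- ceiling(config$followup_years / config$interval_length)
  interval_starts <- (seq_len(n_int) - 1) * config$interval_length
  excl <- apply_exclusions(
    study$subjects, study$ffq, study$composition,
    max_blanks = max_blanks
  )
  panel <- build_exposure_panel(
    study$ffq %>% semi_join(excl$retained, by = "subject_id"),
    study$composition, study$wave_times, interval_starts,
    freeze_times = excl$retained %>%
      select(subject_id, intermediate_diagnosis_time),
    exposures = if (!is.null(exposures)) union(exposures, "energy_kcal")
  )
  cp <- build_counting_process(
    excl$retained, panel,
    interval_length = config$interval_length
  )
  list(
    study = study, counting_process = cp,
    results = run_ewas(
      cp, exposures %||% attr(cp, "exposure_cols"),
      covariates = covariates
    )
  )
}

write_pipeline_outputs <- function(out_dir, config, study, excl, panel, cp,
                                   results, null, est, network, comparison,
                                   manhattan, replication, validation) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(study$subjects, p("subjects.tsv"))
  readr::write_tsv(study$ffq, p("ffq.tsv"))
  readr::write_tsv(study$composition, p("composition.tsv"))
  write_study_config(config, p("config.yml"))
  readr::write_tsv(excl$log, p("exclusion_log.tsv"))
  readr::write_tsv(panel, p("exposure_panel.tsv"))
  readr::write_tsv(as_tibble(cp), p("counting_process.tsv"))
  readr::write_tsv(format_results_table(results), p("results.tsv"))
  readr::write_tsv(
    as_tibble(as.data.frame(null$p)), p("null_pvalues.tsv")
  )
  jsonlite::write_json(
    list(
      m = null$m, seed = null$seed, method = null$method,
      n_cases = null$n_cases, exposures = null$exposures,
      alpha_star = est$alpha_star
    ),
    p("null_pvalues.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_network(network, p("network.graphml"), p("network_edges.tsv"))
  if (!is.null(comparison)) {
    readr::write_tsv(comparison, p("actual_vs_expected.tsv"))
  }
  readr::write_tsv(manhattan, p("manhattan.tsv"))
  if (!is.null(replication)) {
    readr::write_tsv(
      format_results_table(replication), p("replication_results.tsv")
    )
  }
  if (!is.null(validation)) {
    readr::write_tsv(validation, p("validation.tsv"))
  }
  list.files(out_dir, full.names = TRUE)
}

#' Format scan results in the reporting column layout
#'
#' Orders columns as Type, Exposure, Effect size, SE, Hazard ratio, 95%
#' CI, P value of PH, VIF, P value, FDR (values unrounded).
#'
#' @param results An `ewas_results` tibble.
#' @return A plain tibble in reporting column order.
#' @export
format_results_table <- function(results) {
  as_tibble(results) %>%
    select(
      type, exposure = exposure_id, effect_size, se, hazard_ratio,
      ci_low, ci_high, p_ph, vif, p_wald, fdr,
      any_of(c("significant", "boxcox_lambda"))
    ) %>%
    arrange(p_wald)
}
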