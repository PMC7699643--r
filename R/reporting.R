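# Interpretation aids: quintile dose-response, correlations among
# significant exposures, discovery -> replication validation, and the
# Manhattan-style plot table.

#' Hazard ratios by exposure quintile
#'
#' Cuts the pooled subject-interval distribution of the cumulative-average
#' exposure into quintiles and fits the adjusted Cox model with indicator
#' coding, first quintile as reference.
#'
#' @param table A `counting_process` tibble.
#' @param exposure Exposure column.
#' @param covariates Adjustment covariates; default the table's set.
#' @param level Confidence level.
#' @return Tibble with rows Q2-Q5: `quintile`, `effect_size`, `se`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_wald`, plus per-quintile
#'   occupancy counts in the `occupancy` attribute.
#' @export
quintile_hrs <- function(table, exposure, covariates = NULL, level = 0.95) {
  x <- table[[exposure]]
  keep <- !is.na(x)
  breaks <- quantile(x[keep], probs = seq(0, 1, 0.2), names = FALSE)
  if (length(unique(breaks)) < 6) {
    abort(paste0(
      "too few distinct values for quintiles; breaks: ",
      paste(signif(unique(breaks), 4), collapse = ", ")
    ))
  }
  qg <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  covariates <- covariates %||% attr(table, "covariate_cols")
  cm <- covariate_design(table, setdiff(covariates, exposure))
  ok <- keep & complete.cases(cm)
  qf <- factor(qg[ok], levels = 1:5)
  dummies <- stats::model.matrix(~qf)[, -1, drop = FALSE]
  colnames(dummies) <- paste0("Q", 2:5)
  x_design <- cbind(dummies, cm[ok, , drop = FALSE])
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ x_design,
    data = tibble(
      start = table$start[ok], stop = table$stop[ok],
      event = table$event[ok]
    ),
    ties = "efron"
  )
  beta <- coef(fit)[1:4]
  se <- sqrt(diag(vcov(fit)))[1:4]
  hr <- hr_ci_from_beta(unname(beta), unname(se), level)
  out <- tibble(
    quintile = paste0("Q", 2:5),
    effect_size = unname(beta), se = unname(se),
    hazard_ratio = hr$hazard_ratio, ci_low = hr$ci_low,
    ci_high = hr$ci_high,
    p_wald = 2 * pnorm(-abs(unname(beta / se)))
  )
  attr(out, "occupancy") <- as.vector(table(qf))
  out
}

#' Correlations among significant exposures
#'
#' Pairwise Spearman correlations of the cumulative-average exposures,
#' computed across subjects on each subject's average over follow-up
#' intervals.
#'
#' @param exposure_panel Output of [build_exposure_panel()].
#' @param exposures Exposure ids to correlate (at least two; typically the
#'   significant set).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
exposure_correlations <- function(exposure_panel, exposures) {
  if (length(exposures) < 2) abort("need at least two exposures")
  wide <- exposure_panel %>%
    filter(exposure_id %in% exposures) %>%
    group_by(subject_id, exposure_id) %>%
    summarise(value = mean(value, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = exposure_id, values_from = value)
  m <- as.matrix(wide[, exposures, drop = FALSE])
  cor(m, method = "spearman", use = "pairwise.complete.obs")
}

#' Validate discovery findings in a replication cohort
#'
#' An exposure is tentatively validated when it reached FDR significance
#' in the discovery scan (`fdr < q`), reached nominal significance in the
#' replication scan (`p_wald < p`), and the effect signs agree.  Exposures
#' missing from the replication results are flagged and not validated.
#'
#' @param discovery,replication `ewas_results` tibbles (discovery must
#'   have `fdr` filled in).
#' @param q Discovery FDR threshold.
#' @param p Replication nominal significance threshold.
#' @return Tibble: `exposure_id`, `discovery_q`, `discovery_sign`,
#'   `p_replication`, `replication_sign`, `in_replication`, `validated`.
#' @export
validate_replication <- function(discovery, replication, q = 0.05,
                                 p = 0.05) {
  rep_sub <- replication %>%
    select(
      exposure_id,
      p_replication = p_wald, rep_effect = effect_size
    )
  discovery %>%
    select(exposure_id, discovery_q = fdr, effect_size) %>%
    left_join(rep_sub, by = "exposure_id") %>%
    mutate(
      discovery_sign = sign(effect_size),
      replication_sign = sign(.data$rep_effect),
      in_replication = !is.na(p_replication),
      validated = !is.na(discovery_q) & discovery_q < q &
        in_replication & p_replication < p &
        discovery_sign == replication_sign
    ) %>%
    select(
      exposure_id, discovery_q, discovery_sign, p_replication,
      replication_sign, in_replication, validated
    )
}

#' Manhattan-style plot table
#'
#' One row per exposure with the hazard-ratio rank order on the x axis and
#' `-log10(p)` on the y axis, plus the two reference levels: the nominal
#' 0.05 line and the permutation-FDR threshold `alpha_star`.
#'
#' @param results An `ewas_results` tibble.
#' @param alpha_star Optional FDR-derived p-value threshold (from
#'   [significance_threshold()]).
#' @return Tibble ordered by hazard ratio: `exposure_id`, `type`,
#'   `hazard_ratio`, `hr_rank`, `neg_log10_p`, `direction`, `significant`;
#'   reference lines in the `reference_levels` attribute.
#' @export
manhattan_table <- function(results, alpha_star = NA_real_) {
  if (!nrow(results)) abort("results are empty")
  out <- results %>%
    arrange(hazard_ratio) %>%
    mutate(
      hr_rank = row_number(),
      neg_log10_p = -log10(p_wald),
      direction = if_else(hazard_ratio < 1, "negative", "positive")
    ) %>%
    select(
      exposure_id, type, hazard_ratio, hr_rank, neg_log10_p, direction,
      significant
    )
  attr(out, "reference_levels") <- c(nominal = 0.05, alpha_star = alpha_star)
  out
}
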