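# The scan: transform -> fit -> diagnostics for every exposure.

#' Run the environment-wide association scan
#'
#' For each exposure: Box-Cox transform and z-score the pooled
#' subject-interval values, fit the adjusted time-varying Cox model, and
#' collect effect size, SE, hazard ratio with confidence interval, Wald
#' p-value, proportional-hazards p-value, and VIF.  Per-exposure failures
#' are logged and do not abort the scan.
#'
#' @param table A `counting_process` tibble.
#' @param exposures Exposure columns to scan; defaults to every exposure
#'   column in the table.
#' @param covariates Adjustment covariates; defaults to the table's
#'   recorded set.
#' @param level Confidence level for the hazard-ratio interval.
#' @return An `ewas_results` tibble with one row per successfully fitted
#'   exposure: `exposure_id`, `type`, `effect_size`, `se`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p_ph`, `vif`, `p_wald`, `fdr` (`NA` until
#'   [add_fdr()]), `significant`.  Failures are recorded in the
#'   `failures` attribute.
#' @export
run_ewas <- function(table, exposures = NULL, covariates = NULL,
                     level = 0.95) {
  exposures <- exposures %||% attr(table, "exposure_cols")
  types <- attr(table, "exposure_types")
  rows <- vector("list", length(exposures))
  failures <- list()
  for (ex in exposures) {
    res <- tryCatch(
      scan_one(table, ex, covariates, level),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      failures[[ex]] <- res
    } else {
      rows[[ex]] <- res
    }
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    out$type <- unname(types[out$exposure_id]) %||% NA_character_
    out <- out %>% select(exposure_id, type, dplyr::everything())
  }
  structure(
    out,
    failures = tibble(
      exposure_id = names(failures),
      error = unlist(failures) %||% character(0)
    ),
    class = c("ewas_results", class(out))
  )
}

scan_one <- function(table, exposure, covariates, level) {
  tr <- transform_exposure(table[[exposure]][!is.na(table[[exposure]])])
  tbl2 <- table
  tbl2[[exposure]] <- ifelse(
    is.na(table[[exposure]]), NA_real_,
    apply_transform(tr, table[[exposure]])
  )
  fit <- fit_cox(tbl2, exposure, covariates)
  hr <- hr_ci_from_beta(fit$beta, fit$se, level)
  vif <- if (ncol(fit$design$covariates) == 0) {
    1 # nothing to be collinear with
  } else {
    compute_vif(
      cbind(exposure = fit$design$exposure, fit$design$covariates),
      "exposure"
    )
  }
  p_ph <- ph_test(fit)
  tibble(
    exposure_id = exposure,
    effect_size = fit$beta, se = fit$se,
    hazard_ratio = hr$hazard_ratio, ci_low = hr$ci_low,
    ci_high = hr$ci_high,
    p_ph = p_ph, vif = vif,
    p_wald = 2 * pnorm(-abs(fit$beta / fit$se)),
    boxcox_lambda = tr$boxcox_lambda,
    fdr = NA_real_, significant = NA
  )
}

#' @export
print.ewas_results <- function(x, ...) {
  cat(sprintf(
    "<ewas_results> %d exposures (%d failed)\n",
    nrow(x), nrow(attr(x, "failures") %||% tibble())
  ))
  NextMethod()
}
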