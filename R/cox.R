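# Per-exposure extended Cox fits and their diagnostics.

#' Fit the extended (time-varying) Cox model for one exposure
#'
#' Maximises the Cox partial likelihood with Efron tie handling over the
#' counting-process risk sets, adjusting for the table's covariates.  Rows
#' with a missing exposure or covariate are dropped.
#'
#' @param table A `counting_process` tibble (see
#'   [build_counting_process()]).
#' @param exposure Name of the exposure column to test (already
#'   transformed, or raw if you want the untransformed effect).
#' @param covariates Covariate columns; defaults to the table's recorded
#'   adjustment set.
#' @return An `ewas_cox_fit`: list with `beta`, `se`, `loglik`, the full
#'   `coxph` fit (`fit`), the analysis design (`design`), and counts.
#' @export
fit_cox <- function(table, exposure, covariates = NULL) {
  design <- cox_design(table, exposure, covariates)
  if (sum(design$event) < 1) abort("no events in analysis rows")
  x <- cbind(design$exposure, design$covariates)
  colnames(x)[1] <- exposure
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    abort("design matrix is rank deficient")
  }
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(start, stop, event) ~ x,
      data = tibble(
        start = design$start, stop = design$stop, event = design$event
      ),
      ties = "efron", x = TRUE, y = TRUE
    ),
    warning = function(w) {
      # a diverging coefficient on a sparse covariate level is tolerated
      # (coxph reports it and caps the step); outright non-convergence is
      # an error
      if (grepl("did not converge|out of iterations",
        conditionMessage(w),
        ignore.case = TRUE
      )) {
        abort(paste0(
          "Cox fit failed for ", exposure, ": ", conditionMessage(w)
        ))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (anyNA(coef(fit))) abort("Cox fit produced NA coefficients")
  beta <- unname(coef(fit)[1])
  se <- unname(sqrt(diag(vcov(fit)))[1])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    abort(paste0("exposure coefficient diverged for ", exposure))
  }
  structure(
    list(
      exposure = exposure, beta = beta, se = se,
      coefficients = coef(fit), loglik = fit$loglik[2], fit = fit,
      design = design, n = nrow(x), n_events = sum(design$event)
    ),
    class = "ewas_cox_fit"
  )
}

# analysis rows and numeric design pieces for one exposure
cox_design <- function(table, exposure, covariates = NULL) {
  covariates <- covariates %||% attr(table, "covariate_cols")
  covariates <- setdiff(covariates, exposure)
  cm <- covariate_design(table, covariates)
  keep <- !is.na(table[[exposure]]) & complete.cases(cm)
  list(
    exposure = table[[exposure]][keep],
    covariates = cm[keep, , drop = FALSE],
    start = table$start[keep], stop = table$stop[keep],
    event = as.integer(table$event[keep]),
    subject_id = table$subject_id[keep],
    keep = keep
  )
}

#' @export
print.ewas_cox_fit <- function(x, ...) {
  cat(sprintf(
    "<ewas_cox_fit> %s: beta = %.4f (se %.4f), HR = %.3f, %d events / %d rows\n",
    x$exposure, x$beta, x$se, exp(x$beta), x$n_events, x$n
  ))
  invisible(x)
}

#' @method tidy ewas_cox_fit
#' @export
tidy.ewas_cox_fit <- function(x, ...) {
  co <- x$coefficients
  se <- sqrt(diag(vcov(x$fit)))
  tibble(
    term = c(x$exposure, names(co)[-1]),
    estimate = unname(co),
    std.error = unname(se),
    statistic = unname(co / se),
    p.value = 2 * pnorm(-abs(unname(co / se)))
  )
}

#' @method glance ewas_cox_fit
#' @export
glance.ewas_cox_fit <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, logLik = x$loglik,
    beta = x$beta, se = x$se, hazard_ratio = exp(x$beta)
  )
}

#' Hazard ratio and Wald confidence interval from (beta, se)
#'
#' `HR = exp(beta)`, `CI = exp(beta -/+ z * se)` with the two-sided normal
#' quantile for the requested level.  No rounding is applied; round only at
#' report time.
#'
#' @param beta Log-hazard effect size(s).
#' @param se Standard error(s), positive.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `hazard_ratio`, `ci_low`, `ci_high`.
#' @examples
#' hr_ci_from_beta(-0.13, 0.02) # HR 0.88, CI (0.84, 0.91) at 2 decimals
#' @export
hr_ci_from_beta <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) abort("se must be positive")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se)
  )
}

#' Variance inflation factor of the exposure column
#'
#' `VIF = 1 / (1 - R^2)` from the least-squares regression of the exposure
#' on all other design columns (with intercept).  Perfect collinearity is
#' reported as `Inf` rather than an error.
#'
#' @param design Numeric matrix or data frame of analysis columns
#'   (exposure plus dummy-coded covariates).
#' @param exposure_column Name or index of the exposure column.
#' @return A single number `>= 1`, possibly `Inf`.
#' @export
compute_vif <- function(design, exposure_column) {
  design <- as.matrix(design)
  if (ncol(design) < 2) abort("need at least two design columns")
  j <- if (is.character(exposure_column)) {
    match(exposure_column, colnames(design))
  } else {
    exposure_column
  }
  if (is.na(j)) abort("exposure column not found in design")
  y <- design[, j]
  x <- design[, -j, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("constant exposure column")
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) {
    return(Inf)
  }
  1 / (1 - r2)
}

#' Proportional-hazards test for the exposure term
#'
#' Score test for a zero slope of the scaled Schoenfeld residuals of the
#' exposure against Kaplan-Meier-transformed time; one two-sided p-value
#' per fitted exposure.
#'
#' @param fit An `ewas_cox_fit` from [fit_cox()].
#' @return Two-sided p-value in `[0, 1]`.
#' @export
ph_test <- function(fit) {
  stopifnot(inherits(fit, "ewas_cox_fit"))
  if (fit$n_events < 2) abort("proportionality test needs at least 2 events")
  zph <- survival::cox.zph(fit$fit, transform = "km", terms = FALSE)
  unname(zph$table[1, "p"])
}

# ---- fast fitter used by the permutation engine -------------------------

# Precompute the pieces of one exposure's Cox problem that never change
# across permutations: design, sort orders, last-at-risk row per subject.
cox_problem <- function(table, exposure, covariates = NULL,
                        transform = TRUE) {
  design <- cox_design(table, exposure, covariates)
  xvals <- if (transform) transform_exposure(design$exposure)$values
    else design$exposure
  x <- cbind(xvals, design$covariates)
  storage.mode(x) <- "double"
  sid <- design$subject_id
  last_row <- tapply(seq_along(sid), sid, max)
  list(
    x = x, start = design$start, stop = design$stop,
    event = design$event,
    ord_stop = order(design$stop) - 1L,
    ord_start = order(design$start) - 1L,
    last_row_of = setNames(as.integer(last_row), names(last_row)),
    n = nrow(x)
  )
}

# Fit a precomputed problem, optionally replacing the event vector by a
# permuted case set (event at each permuted case's final at-risk row).
cox_problem_fit <- function(prob, case_subjects = NULL, init = NULL) {
  event <- prob$event
  if (!is.null(case_subjects)) {
    event <- integer(prob$n)
    rows <- prob$last_row_of[as.character(case_subjects)]
    rows <- rows[!is.na(rows)]
    event[rows] <- 1L
  }
  .cox_fit_cpp(
    prob$x, prob$start, prob$stop, event, prob$ord_stop, prob$ord_start,
    init %||% numeric(0)
  )
}
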