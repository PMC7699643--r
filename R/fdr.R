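# Permutation false discovery rate with a confounding-preserving null:
# case labels are re-drawn as a biased sample weighted by covariate-
# predicted risk, so the covariate-outcome structure survives permutation
# while every exposure-outcome association is destroyed.

#' Covariate-predicted case propensity scores
#'
#' Fits the covariates-only Cox model on the counting-process table and
#' returns each subject's baseline linear predictor and the induced
#' sampling weight `exp(lp)` (scale-free: adding a constant to every
#' linear predictor leaves the sampling distribution unchanged).
#'
#' @param table A `counting_process` tibble.
#' @param covariates Covariate columns; defaults to the table's recorded
#'   adjustment set.
#' @return Tibble with `subject_id`, `lp`, `weight`.
#' @export
fit_case_propensity <- function(table, covariates = NULL) {
  covariates <- covariates %||% attr(table, "covariate_cols")
  cm <- covariate_design(table, covariates)
  keep <- complete.cases(cm)
  fit <- survival::agreg.fit(
    x = cm[keep, , drop = FALSE],
    y = survival::Surv(
      table$start[keep], table$stop[keep], table$event[keep]
    ),
    strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(), weights = NULL,
    method = "efron", rownames = NULL, resid = FALSE
  )
  if (anyNA(fit$coefficients)) abort("propensity Cox fit did not converge")
  # baseline covariate values = each subject's first at-risk row
  first <- table[keep, ] %>%
    mutate(.row = seq_len(sum(keep))) %>%
    group_by(subject_id) %>%
    slice(1) %>%
    ungroup()
  lp <- as.vector(
    cm[keep, , drop = FALSE][first$.row, , drop = FALSE] %*% fit$coefficients
  )
  lp <- lp - mean(lp)
  tibble(subject_id = first$subject_id, lp = lp, weight = exp(lp))
}

#' Permute case labels as a biased sample from the propensity pool
#'
#' Draws exactly `n_cases` subjects without replacement with inclusion
#' probability increasing in their propensity weight (weighted sampling
#' without replacement by exponential keys: `key_j = Exp(1) / weight_j`,
#' the `n_cases` smallest keys are selected).  Permuted cases keep their
#' observed exit time as the event time; exposure and covariate histories
#' are untouched.
#'
#' @param scores Tibble from [fit_case_propensity()] (or any tibble with
#'   `subject_id` and positive `weight`).
#' @param n_cases Number of cases to draw.
#' @return Character vector of the selected case `subject_id`s.
#' @export
permute_case_labels <- function(scores, n_cases) {
  n <- nrow(scores)
  if (n_cases > n) abort("n_cases exceeds the number of subjects")
  if (any(!is.finite(scores$weight) | scores$weight <= 0)) {
    abort("weights must be finite and positive")
  }
  keys <- rexp(n) / scores$weight
  scores$subject_id[order(keys)[seq_len(n_cases)]]
}

#' Build the permutation null distribution of Wald p-values
#'
#' For each of `m` permutations, re-draws the case set (biased by the
#' propensity weights, or uniformly when `scores` is `NULL`), rebuilds the
#' event vector with each permuted case failing at its observed exit time,
#' and re-runs the per-exposure Cox scan, storing the exposure Wald
#' p-value.  The Box-Cox/z transform depends only on the (unpermuted)
#' exposures, so each exposure's observed transform is reused.
#'
#' @param table A `counting_process` tibble.
#' @param exposures Exposure columns to scan.
#' @param covariates Adjustment covariates.
#' @param m Number of permutations.
#' @param scores Propensity tibble from [fit_case_propensity()], or `NULL`
#'   for a naive uniform permutation.
#' @param seed Integer master seed; permutation `b` uses `seed + b`, so
#'   results are independent of execution order.
#' @return A `null_pvalues` object: list with `p` (an `m x n_exposures`
#'   matrix, `NA` where a fit failed), `exposures`, `m`, `seed`, `method`.
#' @export
build_null_distribution <- function(table, exposures = NULL,
                                    covariates = NULL, m = 1000,
                                    scores = NULL, seed = 1L) {
  if (m < 1) abort("m must be at least 1")
  exposures <- exposures %||% attr(table, "exposure_cols")
  subjects <- unique(table$subject_id)
  n_cases <- table %>%
    group_by(subject_id) %>%
    summarise(ev = max(event), .groups = "drop") %>%
    pull(ev) %>%
    sum()
  if (is.null(scores)) {
    scores <- tibble(subject_id = subjects, weight = 1)
  }

  probs <- lapply(exposures, function(ex) {
    prob <- cox_problem(table, ex, covariates, transform = TRUE)
    obs <- tryCatch(cox_problem_fit(prob), error = function(e) NULL)
    prob$init <- if (!is.null(obs)) obs$coef else NULL
    prob
  })
  names(probs) <- exposures

  p <- matrix(NA_real_, m, length(exposures),
    dimnames = list(NULL, exposures)
  )
  for (b in seq_len(m)) {
    cases <- with_seed(seed + b, permute_case_labels(scores, n_cases))
    for (j in seq_along(exposures)) {
      prob <- probs[[j]]
      f <- tryCatch(
        cox_problem_fit(prob, case_subjects = cases, init = prob$init),
        error = function(e) NULL
      )
      if (!is.null(f) && is.finite(f$se[1]) && f$se[1] > 0) {
        p[b, j] <- 2 * pnorm(-abs(f$coef[1] / f$se[1]))
      }
    }
  }
  structure(
    list(
      p = p, exposures = exposures, m = m, seed = seed,
      method = if (all(scores$weight == scores$weight[1])) {
        "uniform"
      } else {
        "biased_pool"
      },
      n_cases = n_cases
    ),
    class = "null_pvalues"
  )
}

#' @export
print.null_pvalues <- function(x, ...) {
  cat(sprintf(
    "<null_pvalues> %d permutations x %d exposures (%s sampling, %d cases)\n",
    x$m, length(x$exposures), x$method, x$n_cases
  ))
  invisible(x)
}

#' Estimate the false discovery rate at a significance level
#'
#' `FDR(alpha)` is the ratio of the expected proportion of null p-values
#' at or below `alpha` (averaged over permutations) to the observed
#' proportion, capped at 1.  A 0/0 ratio is defined as 0; a zero observed
#' proportion with a nonzero null proportion is capped at 1 with a
#' warning.
#'
#' @param observed_p Observed Wald p-values.
#' @param null A `null_pvalues` object (or a numeric matrix of null
#'   p-values, permutations in rows).
#' @param alpha Significance level in (0, 1).
#' @return `FDR(alpha)` in `[0, 1]`.
#' @export
estimate_fdr <- function(observed_p, null, alpha) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  pm <- if (inherits(null, "null_pvalues")) null$p else as.matrix(null)
  null_prop <- mean(apply(pm <= alpha, 1, mean, na.rm = TRUE), na.rm = TRUE)
  obs_prop <- mean(observed_p <= alpha)
  if (obs_prop == 0) {
    if (null_prop == 0) {
      return(0)
    }
    warn("no observed discoveries at this alpha; FDR capped at 1")
    return(1)
  }
  min(null_prop / obs_prop, 1)
}

#' Permutation-FDR significance threshold and q-values
#'
#' Evaluates `FDR(alpha)` on the grid of observed p-values, reports the
#' largest observed p with `FDR <= q` as the significance threshold
#' `alpha_star`, and assigns each exposure the q-value
#' `min_{alpha >= p_i} FDR(alpha)` (monotone step-up).  Exposures with
#' q-value strictly below `q` form the significant set.
#'
#' @param observed_p Observed Wald p-values (nonempty).
#' @param null A `null_pvalues` object or null p-value matrix.
#' @param q Target FDR level.
#' @return An `fdr_estimate`: list with `alpha_star`, `q_values` (aligned
#'   with `observed_p`), `significant` (logical), and `fdr_grid` (tibble
#'   `alpha`, `fdr`).
#' @export
significance_threshold <- function(observed_p, null, q = 0.05) {
  if (!length(observed_p)) abort("observed_p is empty")
  grid <- sort(unique(observed_p))
  grid <- grid[grid > 0 & grid < 1]
  fdr_at <- vapply(
    grid, function(a) estimate_fdr(observed_p, null, a), numeric(1)
  )
  # q-value: smallest FDR at any alpha >= p_i, enforced monotone in p
  qv_grid <- rev(cummin(rev(fdr_at)))
  idx <- findInterval(observed_p, grid)
  idx[idx == 0] <- 1 # p below the smallest grid point (numerically 0)
  q_values <- qv_grid[idx]
  q_values[observed_p >= 1] <- 1
  ok <- which(fdr_at <= q)
  alpha_star <- if (length(ok)) grid[max(ok)] else NA_real_
  structure(
    list(
      alpha_star = alpha_star, q_values = q_values,
      significant = q_values < q, q = q,
      fdr_grid = tibble(alpha = grid, fdr = fdr_at)
    ),
    class = "fdr_estimate"
  )
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(
    "<fdr_estimate> alpha* = %s at FDR %g; %d significant of %d\n",
    format(x$alpha_star), x$q, sum(x$significant), length(x$q_values)
  ))
  invisible(x)
}

#' Merge permutation-FDR q-values into scan results
#'
#' @param results An `ewas_results` tibble.
#' @param null A `null_pvalues` object built on the same exposures.
#' @param q Target FDR level for the significance flag.
#' @return The results tibble with `fdr` (q-values) and `significant`
#'   filled in, plus an `fdr_estimate` attribute.
#' @export
add_fdr <- function(results, null, q = 0.05) {
  est <- significance_threshold(results$p_wald, null, q)
  results$fdr <- est$q_values
  results$significant <- est$significant
  attr(results, "fdr_estimate") <- est
  results
}
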