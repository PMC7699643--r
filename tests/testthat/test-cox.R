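test_that("the fit matches brute-force maximization of the written-out
           Efron likelihood on tiny instances", {
  # all-events instance with a binary exposure
  df <- tibble::tibble(
    subject_id = paste0("s", 1:4),
    start = 0, stop = c(1, 2, 3, 4),
    event = 1L, x = c(1, 0, 1, 0)
  )
  cp <- as_counting_process(df, "x")
  fit <- fit_cox(cp, "x", covariates = character(0))
  oracle <- grid_max_beta(df$x, df$start, df$stop, df$event)
  expect_lt(abs(fit$beta - oracle), 1e-3)

  # tied event times force the Efron correction to matter
  df2 <- tibble::tibble(
    subject_id = paste0("s", 1:6),
    start = 0, stop = c(1, 1, 2, 2, 3, 3),
    event = c(1L, 1L, 1L, 0L, 1L, 0L),
    x = c(0.5, -1, 2, 0, 1, -0.5)
  )
  cp2 <- as_counting_process(df2, "x")
  fit2 <- fit_cox(cp2, "x", covariates = character(0))
  oracle2 <- grid_max_beta(df2$x, df2$start, df2$stop, df2$event)
  expect_lt(abs(fit2$beta - oracle2), 1e-3)
})

test_that("negating the exposure negates the estimate exactly", {
  set.seed(201)
  df <- sim_simple_surv(150, beta = 0.4)
  cp <- as_counting_process(df, "x")
  f1 <- fit_cox(cp, "x", covariates = character(0))
  df$x <- -df$x
  f2 <- fit_cox(as_counting_process(df, "x"), "x",
    covariates = character(0)
  )
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(202)
  p <- replicate(400, {
    df <- sim_simple_surv(120, beta = 0)
    cp <- as_counting_process(df, "x")
    f <- fit_cox(cp, "x", covariates = character(0))
    2 * pnorm(-abs(f$beta / f$se))
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("tidy and glance summarise a fit", {
  set.seed(203)
  df <- sim_simple_surv(200, beta = 0.5, n_cov = 2)
  cp <- as_counting_process(df, "x", covariate_cols = c("c1", "c2"))
  f <- fit_cox(cp, "x")
  td <- tidy(f)
  expect_equal(nrow(td), 3)
  expect_equal(td$term[1], "x")
  gl <- glance(f)
  expect_equal(gl$hazard_ratio, exp(f$beta))
  expect_error(fit_cox(cp, "x", covariates = "x"), NA)
})

test_that("hazard-ratio intervals have the closed form", {
  out <- hr_ci_from_beta(0, 0.1)
  expect_equal(out$hazard_ratio, 1)
  expect_equal(out$ci_low, exp(-qnorm(0.975) * 0.1))
  expect_equal(out$ci_high, exp(qnorm(0.975) * 0.1))
  expect_equal(out$ci_low * out$ci_high, 1, tolerance = 1e-12)
  expect_error(hr_ci_from_beta(1, 0), "positive")
})

test_that("the VIF follows its closed form and degenerates to Inf", {
  set.seed(204)
  n <- 500
  a <- rnorm(n)
  b <- rnorm(n)
  d <- cbind(x = a, c1 = b) # orthogonal in expectation, small sample noise
  v <- compute_vif(d, "x")
  expect_gt(v, 1 - 1e-9)
  expect_lt(v, 1.05)
  # construct R^2 = 0.9 exactly: x = c1 with noise variance ratio 1:9
  c1 <- rnorm(n)
  resid <- rnorm(n)
  resid <- resid - drop(coef(lm(resid ~ c1))[2]) * c1 # orthogonalize
  c1s <- c1 / sd(c1)
  rs <- resid / sd(resid)
  x <- 3 * c1s + 1 * rs
  v2 <- compute_vif(cbind(x = x, c1 = c1s), "x")
  expect_equal(v2, 10, tolerance = 0.05)
  expect_equal(
    compute_vif(cbind(x = a, dup = a), "x"), Inf
  )
})

test_that("the proportionality test is calibrated and detects violations", {
  set.seed(205)
  # constant effect: p uniform-ish
  p_null <- replicate(200, {
    df <- sim_simple_surv(150, beta = 0.5)
    f <- fit_cox(as_counting_process(df, "x"), "x",
      covariates = character(0)
    )
    ph_test(f)
  })
  expect_true(all(p_null >= 0 & p_null <= 1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)

  # effect reversing sign mid-follow-up: strong violation
  detected <- replicate(20, {
    n <- 2000
    x <- rnorm(n)
    # piecewise hazard: beta = +0.8 before t = 5, -0.8 after
    t1 <- rexp(n, 0.08 * exp(0.8 * x))
    t2 <- 5 + rexp(n, 0.08 * exp(-0.8 * x))
    tt <- ifelse(t1 < 5, t1, t2)
    df <- tibble::tibble(
      subject_id = sprintf("p%04d", 1:n), start = 0,
      stop = pmin(tt, 15), event = as.integer(tt <= 15), x = x
    )
    f <- fit_cox(as_counting_process(df, "x"), "x",
      covariates = character(0)
    )
    ph_test(f) < 0.05
  })
  expect_gte(mean(detected), 0.8)
})

test_that("the scan runs per exposure without aborting on failures", {
  set.seed(206)
  df <- sim_simple_surv(300, beta = 0.6, n_cov = 1)
  df$x <- exp(df$x) # intakes are nonnegative; log-scale effect kept
  df$y <- rexp(300) # null exposure
  df$z <- 1 # degenerate exposure, must fail but not abort
  cp <- as_counting_process(df, c("x", "y", "z"),
    covariate_cols = "c1"
  )
  res <- run_ewas(cp)
  expect_equal(nrow(res), 2)
  fails <- attr(res, "failures")
  expect_equal(fails$exposure_id, "z")
  expect_match(fails$error, "degenerate")
  expect_lt(
    res$p_wald[res$exposure_id == "x"],
    res$p_wald[res$exposure_id == "y"]
  )
  expect_true(all(res$ci_low < res$hazard_ratio))
  expect_true(all(res$hazard_ratio < res$ci_high))
  expect_equal(res$hazard_ratio, exp(res$effect_size))

  empty <- run_ewas(cp, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("a true effect ranks first among null exposures", {
  set.seed(207)
  hits <- replicate(10, {
    df <- sim_simple_surv(800, beta = 0.4)
    df$x <- exp(df$x)
    for (j in 1:9) df[[paste0("null", j)]] <- rexp(800)
    cp <- as_counting_process(df, c("x", paste0("null", 1:9)))
    res <- run_ewas(cp)
    res$exposure_id[which.min(res$p_wald)] == "x"
  })
  expect_gte(mean(hits), 0.9)
})
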