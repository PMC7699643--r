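test_that("propensity weights are constant when covariates carry no risk", {
  set.seed(401)
  df <- sim_simple_surv(300, beta = 0, n_cov = 1)
  df$c1 <- 0.5 # constant covariate column is rank-deficient; use noise-free
  df$c1 <- rep(c(0, 1), length.out = 300) # balanced, effect 0
  cp <- as_counting_process(df, "x", covariate_cols = "c1")
  sc <- fit_case_propensity(cp)
  # coefficient near zero => near-equal weights
  expect_lt(diff(range(sc$lp)), 0.5)
  expect_true(all(sc$weight > 0 & is.finite(sc$weight)))
})

test_that("a positive covariate effect orders the weights monotonely", {
  set.seed(402)
  n <- 400
  c1 <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, 0.1 * exp(1 * c1))
  df <- tibble::tibble(
    subject_id = sprintf("p%04d", 1:n), start = 0,
    stop = pmin(t_event, 8), event = as.integer(t_event <= 8),
    x = rnorm(n), c1 = c1
  )
  cp <- as_counting_process(df, "x", covariate_cols = "c1")
  sc <- fit_case_propensity(cp) %>%
    dplyr::left_join(df, by = "subject_id")
  expect_true(
    min(sc$weight[sc$c1 == 1]) > max(sc$weight[sc$c1 == 0])
  )
  # recentring a covariate leaves relative weights unchanged
  df2 <- df %>% dplyr::mutate(c1 = c1 - 10)
  sc2 <- fit_case_propensity(
    as_counting_process(df2, "x", covariate_cols = "c1")
  )
  expect_equal(
    sc$weight / sum(sc$weight), sc2$weight / sum(sc2$weight),
    tolerance = 1e-8
  )
})

test_that("equal weights reduce biased sampling to a uniform permutation", {
  set.seed(403)
  sc <- tibble::tibble(subject_id = sprintf("s%02d", 1:50), weight = 1)
  draws <- replicate(10000, permute_case_labels(sc, 10))
  freq <- table(factor(c(draws), levels = sc$subject_id)) / 10000
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 10000) + 0.02))
  expect_equal(length(permute_case_labels(sc, 7)), 7)
  expect_error(permute_case_labels(sc, 51), "exceeds")
})

test_that("extreme weights dominate the sampled case set", {
  set.seed(404)
  sc <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    weight = c(1e9, 1e9, 1, 1)
  )
  draws <- replicate(2000, sort(permute_case_labels(sc, 2)))
  expect_gt(mean(draws[1, ] == "a" & draws[2, ] == "b"), 0.999)
})

test_that("the null matrix has the right shape and is reproducible", {
  set.seed(405)
  df <- sim_simple_surv(150, beta = 0)
  df$x <- exp(df$x)
  df$y <- runif(150)
  df$w <- rexp(150)
  cp <- as_counting_process(df, c("x", "y", "w"))
  n1 <- build_null_distribution(cp, c("x", "y", "w"), m = 2, seed = 9)
  expect_equal(dim(n1$p), c(2, 3))
  expect_true(all(n1$p >= 0 & n1$p <= 1, na.rm = TRUE))
  n2 <- build_null_distribution(cp, c("x", "y", "w"), m = 2, seed = 9)
  expect_identical(n1$p, n2$p)
  expect_equal(n1$method, "uniform")
})

test_that("pooled null p-values are uniform under equal weights", {
  # cohort-like conditions: modest event fraction, administratively
  # capped follow-up (the permutation null is conditional on the exposure
  # and exit-time structure, so chance exposure/exit correlation must be
  # small for marginal uniformity)
  set.seed(406)
  ps <- lapply(1:4, function(r) {
    df <- sim_simple_surv(800, beta = 0, rate = 0.015, cens = 0.01,
      admin = 10)
    for (j in 1:4) df[[paste0("e", j)]] <- rexp(800)
    exps <- paste0("e", 1:4)
    cp <- as_counting_process(df, exps)
    as.vector(build_null_distribution(cp, exps, m = 60, seed = r)$p)
  })
  expect_gt(stats::ks.test(unlist(ps), "punif")$p.value, 0.01)
})

test_that("the FDR ratio follows its definition with caps and 0/0", {
  observed <- c(rep(0.001, 10), seq(0.3, 0.99, length.out = 90))
  # each permutation has exactly 1 of 100 p-values at or below 0.01
  null_m <- matrix(rep(seq(0.005, 0.9955, by = 0.01), 50),
    nrow = 50, byrow = TRUE
  )
  # observed proportion at 0.01: 10/100; null exactly 0.01 => FDR = 0.1
  expect_equal(estimate_fdr(observed, null_m, 0.01), 0.1)
  # null proportion >= observed proportion => capped at 1
  all_small <- matrix(rep(1e-6, 200), 10, 20)
  expect_equal(estimate_fdr(runif(20, 0.5, 1), all_small, 0.05), 1)
  # 0/0 convention
  expect_equal(
    estimate_fdr(rep(0.9, 5), matrix(0.9, 3, 5), 0.05), 0
  )
  expect_error(estimate_fdr(observed, null_m, 1.5), "alpha")
})

test_that("the threshold separates signal from a uniform null", {
  set.seed(407)
  observed <- c(rep(0.0005, 10), runif(90, 0.2, 1))
  null_m <- matrix(runif(1000 * 100), 1000, 100)
  est <- significance_threshold(observed, null_m, q = 0.05)
  expect_gte(est$alpha_star, 0.0005)
  expect_equal(sum(est$significant), 10)
  expect_true(all(which(est$significant) <= 10))
  # q-values are monotone in p
  ord <- order(observed)
  expect_true(all(diff(est$q_values[ord]) >= -1e-12))
  # all p above the null support: nothing significant
  est2 <- significance_threshold(
    runif(20, 0.5, 1), matrix(runif(200, 0, 0.2), 10, 20)
  )
  expect_equal(sum(est2$significant), 0)
})

test_that("q-values merge back into scan results consistently", {
  set.seed(408)
  res <- tibble::tibble(
    exposure_id = paste0("e", 1:30), type = "nutrient",
    effect_size = rnorm(30), se = 1,
    hazard_ratio = 1, ci_low = 0.9, ci_high = 1.1,
    p_ph = 0.5, vif = 1,
    p_wald = c(rep(0.0001, 3), runif(27, 0.2, 1)),
    fdr = NA_real_, significant = NA
  )
  null_m <- matrix(runif(3000), 100, 30)
  out <- add_fdr(res, null_m, q = 0.05)
  expect_true(all(out$significant == (out$fdr < 0.05)))
  expect_true(all(out$fdr >= 0 & out$fdr <= 1))
  expect_true(all(out$significant[1:3]))
})
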