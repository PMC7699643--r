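fake_results <- function(df) {
  tibble::as_tibble(df) %>%
    dplyr::mutate(
      se = 0.05,
      hazard_ratio = exp(effect_size),
      ci_low = exp(effect_size - 0.1), ci_high = exp(effect_size + 0.1),
      p_ph = 0.5, vif = 1.1, p_wald = dplyr::if_else(significant, 1e-4, 0.5),
      fdr = dplyr::if_else(significant, 0.01, 0.9)
    )
}

test_that("normalized weights sum to one and are scale invariant", {
  comp <- tibble::tibble(
    nutrient_id = "n1", food_id = c("f1", "f2", "f3"),
    amount = c(2, 2, 5)
  )
  w <- normalized_food_weights(comp, "n1", c("f1", "f2"))
  expect_equal(unname(w), c(0.5, 0.5))
  expect_equal(sum(w), 1)
  w10 <- normalized_food_weights(
    dplyr::mutate(comp, amount = amount * 10), "n1", c("f1", "f2")
  )
  expect_equal(w, w10)
  single <- normalized_food_weights(comp, "n1", "f3")
  expect_equal(unname(single), 1)
  expect_null(normalized_food_weights(comp, "n1", "f9"))
})

test_that("the expected hazard ratio is the weighted geometric mean", {
  expect_equal(expected_nutrient_hr(1, log(1.2)), 1.2)
  expect_equal(
    expected_nutrient_hr(c(0.5, 0.5), log(c(0.8, 1.25))), 1
  )
  expect_error(expected_nutrient_hr(c(0.5, 0.5), 1), "length")

  # exp-of-sum and product-of-powers forms agree to machine precision
  set.seed(501)
  for (i in 1:1000) {
    k <- sample(1:6, 1)
    w <- runif(k)
    w <- w / sum(w)
    beta <- rnorm(k, sd = 0.5)
    expect_equal(
      expected_nutrient_hr(w, beta),
      prod(exp(beta)^w),
      tolerance = 1e-12
    )
  }

  # all-protective sources imply a protective expected HR
  for (i in 1:50) {
    k <- sample(2:5, 1)
    w <- runif(k)
    w <- w / sum(w)
    beta <- -runif(k, 0.01, 1)
    expect_lt(expected_nutrient_hr(w, beta), 1)
  }
})

test_that("the network restricts to significant exposures", {
  comp <- tibble::tibble(
    nutrient_id = c("n1", "n1", "n2", "n3"),
    food_id = c("f1", "f2", "f1", "f9"),
    amount = c(1, 3, 2, 5)
  )
  res <- fake_results(tibble::tibble(
    exposure_id = c("n1", "n2", "n3", "f1", "f2", "f9"),
    type = c("nutrient", "nutrient", "nutrient", "food", "food", "food"),
    effect_size = c(-0.2, 0.1, -0.3, -0.1, 0.15, -0.2),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  ))
  net <- build_network(res, comp)
  # n3's only source (f9) is not significant -> dropped with a log entry
  expect_equal(net$dropped, "n3")
  expect_setequal(net$nodes$name, c("n1", "n2", "f1", "f2"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(
    igraph::vcount(net$graph),
    sum(net$nodes$type == "food") + sum(net$nodes$type == "nutrient")
  )
  w_n1 <- net$edges %>% dplyr::filter(nutrient_id == "n1")
  expect_equal(sum(w_n1$weight), 1)
  expect_equal(w_n1$weight[w_n1$food_id == "f2"], 0.75)

  cmp <- compare_actual_vs_expected(net)
  expect_equal(nrow(cmp), 2)
  # n1: sources f1 (w .25, beta -.1) and f2 (w .75, beta .15)
  expected_n1 <- exp(0.25 * -0.1 + 0.75 * 0.15)
  expect_equal(
    cmp$expected_hr[cmp$nutrient_id == "n1"], expected_n1
  )
  expect_equal(
    cmp$agree[cmp$nutrient_id == "n1"],
    sign(log(exp(-0.2))) == sign(log(expected_n1))
  )
  # n2: actual positive, expected from f1 negative -> disagree
  expect_false(cmp$agree[cmp$nutrient_id == "n2"])
})

test_that("single-source significant nutrients give a one-edge network", {
  comp <- tibble::tibble(
    nutrient_id = "n1", food_id = "f1", amount = 4
  )
  res <- fake_results(tibble::tibble(
    exposure_id = c("n1", "f1"), type = c("nutrient", "food"),
    effect_size = c(-0.2, -0.25), significant = TRUE
  ))
  net <- build_network(res, comp)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  cmp <- compare_actual_vs_expected(net)
  expect_equal(cmp$expected_hr, exp(-0.25))
  expect_true(cmp$agree)
})

test_that("graphml and edge-list exports are written", {
  comp <- tibble::tibble(
    nutrient_id = "n1", food_id = "f1", amount = 4
  )
  res <- fake_results(tibble::tibble(
    exposure_id = c("n1", "f1"), type = c("nutrient", "food"),
    effect_size = c(-0.2, -0.25), significant = TRUE
  ))
  net <- build_network(res, comp)
  g <- withr::local_tempfile(fileext = ".graphml")
  e <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, g, e)
  expect_true(file.exists(g))
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_equal(nrow(readr::read_tsv(e, show_col_types = FALSE)), 1)
})

test_that("a carried effect propagates to agreement between actual and
           expected hazard ratios", {
  # one nutrient sourced from one food; the food's consumption drives risk
  # through the nutrient, so both sit on the same side of 1
  set.seed(502)
  agree <- replicate(10, {
    cfg <- study_config(
      n_subjects = 1500, n_foods = 10, n_nutrients = 3,
      n_cycles = 2, followup_years = 6,
      true_effects = c(nutrient_002 = 0.4),
      seed = sample.int(1e6, 1)
    )
    comp <- make_composition_table(cfg, sources_per_nutrient = 1)
    st <- generate_cohort(cfg, composition = comp)
    panel <- build_exposure_panel(
      st$ffq, st$composition, st$wave_times, seq(0, 4, 2)
    )
    cp <- build_counting_process(st$subjects, panel)
    src <- comp$food_id[comp$nutrient_id == "nutrient_002"]
    res <- run_ewas(
      cp, c("nutrient_002", src),
      covariates = c("age", "bmi", "smoking")
    )
    res$significant <- TRUE
    res$fdr <- 0.01
    net <- build_network(res, comp)
    cmp <- compare_actual_vs_expected(net)
    cmp$agree[cmp$nutrient_id == "nutrient_002"]
  })
  expect_gte(mean(agree), 0.9)
})
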