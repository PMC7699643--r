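test_that("the servings map anchors and monotonicity hold", {
  expect_equal(servings_per_day(5), 1) # once per day
  expect_equal(servings_per_day(0), 0) # almost never
  all9 <- servings_per_day(0:8)
  expect_true(all(diff(all9) > 0))
  expect_true(is.na(servings_per_day(NA)))
  expect_error(servings_per_day(9), "outside")
  expect_error(servings_per_day(-1), "outside")
})

test_that("the servings map round-trips through YAML and is validated", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_servings_map(ffq_servings_map(), path)
  expect_equal(read_servings_map(path), ffq_servings_map())
  bad <- ffq_servings_map()
  bad[3] <- 5
  write_servings_map(bad, path)
  expect_error(read_servings_map(path), "monotone")
})

test_that("nutrient derivation is a linear servings-weighted sum", {
  comp <- tibble::tibble(
    nutrient_id = c("n1", "n1", "n2"),
    food_id = c("f1", "f2", "f2"),
    amount = c(3, 1, 10)
  )
  serv <- tibble::tibble(
    subject_id = "s1", cycle_index = 1,
    food_id = c("f1", "f2"), servings = c(2, 0)
  )
  out <- nutrient_intakes(serv, comp)
  expect_equal(out$value[out$nutrient_id == "n1"], 6) # 2 * 3
  expect_equal(out$value[out$nutrient_id == "n2"], 0)

  doubled <- nutrient_intakes(
    dplyr::mutate(serv, servings = servings * 2), comp
  )
  expect_equal(doubled$value, out$value * 2)

  zero <- nutrient_intakes(dplyr::mutate(serv, servings = 0), comp)
  expect_true(all(zero$value == 0))

  expect_error(
    nutrient_intakes(dplyr::mutate(serv, food_id = "mystery"), comp),
    "unknown food"
  )
})

test_that("exclusion boundaries follow the strict inequalities", {
  # energy carried by a single food consumed once per day, so baseline
  # energy equals that food's per-serving energy content
  energies <- c(599, 600, 3500, 3501)
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:4),
    age = 50, bmi = 25, activity = 10, smoking = "never",
    ethnicity = "white",
    baseline_cvd = 0L, baseline_diabetes = 0L, baseline_cancer = 0L
  )
  ffq <- tibble::tibble(
    subject_id = subjects$subject_id,
    cycle_index = 1L,
    food_id = sprintf("f%02d", 1:4),
    frequency_category = 5L
  )
  comp <- tibble::tibble(
    nutrient_id = "energy_kcal",
    food_id = sprintf("f%02d", 1:4),
    amount = energies
  )
  out <- apply_exclusions(subjects, ffq, comp)
  expect_setequal(out$retained$subject_id, c("s02", "s03"))
  expect_equal(
    sort(out$log$reason), c("high_energy", "low_energy")
  )
})

test_that("the blank-item rule excludes at more than the threshold", {
  n_foods <- 80
  subjects <- tibble::tibble(
    subject_id = c("a", "b"),
    age = 50, bmi = 25, activity = 10, smoking = "never",
    ethnicity = "white",
    baseline_cvd = 0L, baseline_diabetes = 0L, baseline_cancer = 0L
  )
  ffq <- tidyr::expand_grid(
    subject_id = c("a", "b"), food_id = sprintf("f%03d", 1:n_foods)
  ) %>%
    dplyr::mutate(cycle_index = 1L, frequency_category = 5L)
  # subject a: 71 blanks; subject b: 70 blanks
  ffq$frequency_category[
    ffq$subject_id == "a"
  ][1:71] <- NA_integer_
  ffq$frequency_category[
    ffq$subject_id == "b"
  ][1:70] <- NA_integer_
  comp <- tibble::tibble(
    nutrient_id = "energy_kcal", food_id = sprintf("f%03d", 1:n_foods),
    amount = 200
  )
  out <- apply_exclusions(subjects, ffq, comp, max_blanks = 70)
  expect_equal(out$log$subject_id, "a")
  expect_equal(out$log$reason, "many_blanks")
  expect_equal(out$retained$subject_id, "b")
})

test_that("baseline disease history excludes, and exclusion is idempotent", {
  cfg <- small_config()
  st <- generate_cohort(cfg)
  st$subjects$baseline_cancer[1] <- 1L
  out <- apply_exclusions(
    st$subjects, st$ffq, st$composition,
    max_blanks = 10
  )
  expect_true(st$subjects$subject_id[1] %in% out$log$subject_id)
  expect_true(
    out$log$reason[out$log$subject_id == st$subjects$subject_id[1]] ==
      "baseline_disease"
  )
  # reasons partition the excluded set
  expect_equal(anyDuplicated(out$log$subject_id), 0)
  expect_equal(
    nrow(out$retained) + nrow(out$log), nrow(st$subjects)
  )
  # idempotence
  again <- apply_exclusions(
    out$retained,
    st$ffq %>% dplyr::semi_join(out$retained, by = "subject_id"),
    st$composition,
    max_blanks = 10
  )
  expect_equal(nrow(again$log), 0)
  expect_equal(again$retained, out$retained)
})

test_that("cumulative averages follow the at-or-before and freeze rules", {
  # waves measured at years 0 and 4; the interval starting at year 4 sees
  # both waves
  expect_equal(
    cumulative_average(c(2, 4), c(0, 4), seq(0, 8, 2)),
    c(2, 2, 3, 3, 3)
  )
  expect_equal(
    cumulative_average(5, 0, seq(0, 6, 2)), rep(5, 4)
  )
  # freeze between waves 2 and 3 holds the two-wave average
  expect_equal(
    cumulative_average(c(2, 4, 6), c(0, 4, 8), seq(0, 10, 2),
      freeze_time = 5
    ),
    c(2, 2, 3, 3, 3, 3)
  )
  # missing middle wave is skipped
  expect_equal(
    cumulative_average(c(2, NA, 6), c(0, 4, 8), c(8)), 4
  )
  expect_error(cumulative_average(1:2, c(4, 0), 0), "sorted")
})

test_that("nutrient derivation commutes with cumulative averaging", {
  cfg <- small_config(exclusion_fractions = c())
  st <- generate_cohort(cfg)
  starts <- seq(0, 6, 2)
  panel <- build_exposure_panel(
    st$ffq, st$composition, st$wave_times, starts
  )
  # derive-then-average (what the panel does) vs average-then-derive
  serv <- st$ffq %>%
    dplyr::mutate(servings = servings_per_day(frequency_category))
  nut <- "nutrient_002"
  comp_n <- st$composition %>% dplyr::filter(nutrient_id == nut)
  # complete the sparse row with explicit zeros so every consumed food
  # is covered
  comp_n <- dplyr::bind_rows(
    comp_n,
    tibble::tibble(
      nutrient_id = nut,
      food_id = setdiff(unique(st$ffq$food_id), comp_n$food_id),
      amount = 0
    )
  )
  per_wave <- nutrient_intakes(serv, comp_n)
  direct <- per_wave %>%
    dplyr::group_by(subject_id) %>%
    dplyr::summarise(
      avg = mean(value[st$wave_times[cycle_index] <= 4]),
      .groups = "drop"
    )
  from_panel <- panel %>%
    dplyr::filter(exposure_id == nut, interval_index == 3)
  merged <- dplyr::left_join(
    direct, from_panel,
    by = "subject_id"
  )
  expect_equal(merged$avg, merged$value, tolerance = 1e-12)
})
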