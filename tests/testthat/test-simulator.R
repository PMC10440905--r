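test_that("a noise-free single-effect model shifts the outcome exactly", {
  g <- tiny_graph(effects = c(-2, -4))
  des <- fixed_design(c(1, 2, 1, 2), period_length = 3)
  pf <- simulate_patient(g, des, config = list(ordinal_outcome = FALSE), seed = 1)
  expect_equal(pf$pain[pf$treatment == 1], rep(4, 6))
  expect_equal(pf$pain[pf$treatment == 2], rep(2, 6))
  # with tau = gamma = 1 the outcome depends on the current day only,
  # not on treatment history
  des2 <- fixed_design(c(2, 1, 2, 1), period_length = 3)
  pf2 <- simulate_patient(g, des2, config = list(ordinal_outcome = FALSE), seed = 1)
  expect_equal(sort(unique(pf2$pain)), c(2, 4))
})

test_that("carry-over wash-in scales the first-day treatment contribution", {
  g <- tiny_graph(tau = c(6, 5), gamma = c(3, 4))
  des <- fixed_design(c(1, 2), period_length = 28)
  pf <- simulate_patient(g, des, config = list(ordinal_outcome = FALSE), seed = 1)
  # day 1 of a treatment-1 period starting from zero exposure: -2 * (1/6)
  expect_equal(pf$pain[1], 6 - 2 * (1 / 6))
  expect_equal(pf$pain[2], 6 - 2 * (1 / 6 + (1 - 1 / 6) / 6))
})

test_that("a threshold above the support yields all zeros", {
  g <- causal_graph(
    nodes = data.frame(
      name = c("treatment", "x", "pain"),
      role = c("treatment", "time_varying", "outcome"),
      distribution = c(NA, "uniform", NA),
      param1 = c(NA, 0, NA), param2 = c(NA, 1, NA),
      threshold = c(NA, 99, NA),
      noise_mean = c(NA, NA, 6), noise_sd = c(NA, NA, 0)
    ),
    edges = data.frame(from = "x", to = "pain", weight = 1)
  )
  pf <- simulate_patient(g, fixed_design(c(1, 2), 5), seed = 2)
  expect_true(all(pf$x == 0))
})

test_that("binary nodes emit only 0/1 and constants are constant per patient", {
  co <- simulate_cohort(scenario_config(1, n_population = 6), seed = 9)
  for (col in c("education", "work", "prev_diagnosis", "chronic_diseases",
                "medication")) {
    expect_true(all(co[[col]] %in% c(0, 1)), label = col)
  }
  per_patient <- tapply(co$education, co$patient_id, function(v) length(unique(v)))
  expect_true(all(per_patient == 1))
  per_patient <- tapply(co$demographics, co$patient_id, function(v) length(unique(v)))
  expect_true(all(per_patient == 1))
  expect_true(all(co$pain >= 0 & co$pain <= 10))
  expect_true(all(co$pain == round(co$pain)))
})

test_that("with all noise silenced the mean outcome contrast equals the truth exactly", {
  cfg <- scenario_config(1, n_population = 4, ordinal_outcome = FALSE)
  g <- noisefree_backpain_graph(cfg)
  co <- simulate_cohort(cfg, seed = 30, graph = g)
  diff <- mean(co$pain[co$treatment == 1]) - mean(co$pain[co$treatment == 2])
  expect_equal(diff, 2)
})

test_that("cohorts are seed-deterministic and vary across seeds", {
  cfg <- scenario_config(2, n_population = 5)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  # different seeds eventually produce different block orders
  orders <- vapply(1:20, function(s) {
    co <- simulate_cohort(scenario_config(1, n_population = 1), seed = s)
    paste(unique(co$treatment[order(co$day)])[1], co$treatment[57], sep = "")
  }, character(1))
  expect_gt(length(unique(orders)), 1)
})

test_that("the activity interaction adds an arm contrast in activity", {
  cfg3 <- scenario_config(3, n_population = 40)
  co3 <- simulate_cohort(cfg3, seed = 77)
  # treatment 2 on the previous day raises activity (temporal effect)
  lagged <- co3 |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(prev2 = dplyr::lag(treatment) == 2) |>
    dplyr::filter(!is.na(prev2))
  gap <- mean(lagged$activity[lagged$prev2]) - mean(lagged$activity[!lagged$prev2])
  expect_gt(gap, 0.5)
  # scenario 1 has no such effect
  co1 <- simulate_cohort(scenario_config(1, n_population = 40), seed = 77)
  lagged1 <- co1 |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(prev2 = dplyr::lag(treatment) == 2) |>
    dplyr::filter(!is.na(prev2))
  gap1 <- mean(lagged1$activity[lagged1$prev2]) - mean(lagged1$activity[!lagged1$prev2])
  expect_lt(abs(gap1), 0.2)
})
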