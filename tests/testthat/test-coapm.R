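test_that("exposure columns reduce to binary indicators at tau = gamma = 1", {
  co <- simulate_cohort(scenario_config(1, n_population = 3), seed = 6)
  d <- coapm_design(co, 1, 1, 1, 1)
  expect_equal(d$e1, as.numeric(d$treatment == 1))
  expect_equal(d$e2, as.numeric(d$treatment == 2))
})

test_that("the exposure column follows the wash-in worked example", {
  d <- toy_trial(treatment = c(1, 1, 1, 2, 2), pain = rep(5, 5))
  des <- coapm_design(d, tau1 = 2, gamma1 = 1, tau2 = 1, gamma2 = 1)
  expect_equal(des$e1[1:3], c(1 / 2, 3 / 4, 7 / 8))
})

test_that("exposure evolves through masked days but masked rows leave the fit", {
  d <- toy_trial(treatment = c(1, 1, 1, 1), pain = c(5, 5, 5, 5))
  d$missing[2] <- TRUE
  des <- coapm_design(d, tau1 = 2, gamma1 = 1, tau2 = 1, gamma2 = 1)
  expect_equal(des$e1, c(1 / 2, 3 / 4, 7 / 8, 15 / 16))
  des2 <- coapm_design(d, tau1 = 2, gamma1 = 1, tau2 = 1, gamma2 = 1,
                       evolve_through_missing = FALSE)
  expect_equal(des2$e1, c(1 / 2, 3 / 4, 7 / 8))
})

test_that("an all-missing patient contributes no rows to the fit", {
  co <- simulate_cohort(scenario_config(1, n_population = 3), seed = 6)
  co$missing[co$patient_id == 2] <- TRUE
  fit <- coapm_grid_search(co, covariates = character(), grid_max = 3)
  expect_equal(fit$n_patients, 2)
  expect_equal(fit$n_obs, 2 * 112)
})

test_that("noise-free carry-over data are recovered exactly with R^2 = 1", {
  g <- tiny_graph(tau = c(6, 5), gamma = c(3, 4))
  cfg <- list(ordinal_outcome = FALSE)
  co <- dplyr::bind_rows(lapply(1:2, function(i) {
    simulate_patient(g, generate_design(seed = i), cfg, seed = i,
                     patient_id = i)
  }))
  fit <- suppressWarnings(coapm_grid_search(co, covariates = character()))
  expect_equal(fit$details$tau1, 6)
  expect_equal(fit$details$gamma1, 3)
  expect_equal(fit$details$tau2, 5)
  expect_equal(fit$details$gamma2, 4)
  expect_equal(fit$details$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$details$beta1, -2, tolerance = 1e-8)
  expect_equal(fit$details$beta2, -4, tolerance = 1e-8)
  expect_equal(fit$estimate, 2, tolerance = 1e-8)
})

test_that("selected R^2 never falls below the plain linear model's", {
  for (sc in c(1, 2)) {
    co <- simulate_cohort(scenario_config(sc, n_population = 25), seed = 40 + sc)
    fit <- coapm_grid_search(co)
    lm_r2 <- linear_model_estimate(co)$details$r_squared
    expect_gte(fit$details$r_squared, lm_r2 - 1e-12)
  }
})

test_that("exposure regressors are bounded and monotone within sustained periods", {
  co <- simulate_cohort(scenario_config(2, n_population = 4), seed = 17)
  d <- coapm_design(co, 6, 3, 5, 4)
  expect_true(all(d$e1 >= 0 & d$e1 <= 1))
  expect_true(all(d$e2 >= 0 & d$e2 <= 1))
  within_run <- d |>
    dplyr::group_by(patient_id, period) |>
    dplyr::summarise(
      mono1 = all(diff(e1) >= 0) || all(treatment != 1),
      mono2 = all(diff(e2) >= 0) || all(treatment != 2),
      .groups = "drop"
    )
  expect_true(all(within_run$mono1))
  expect_true(all(within_run$mono2))
})

test_that("grid search recovers the generating decay parameters under low noise", {
  cfg <- scenario_config(2, n_population = 5, ordinal_outcome = FALSE)
  g <- scenario_graph(cfg)
  g$nodes$noise_sd[g$nodes$role == "outcome"] <- 0.05
  drift <- g$nodes$role == "drift"
  g$nodes$param2[drift] <- 0
  tv_covs <- c("activity", "stress", "quality_sleep", "medication")
  sel <- t(vapply(1:20, function(s) {
    co <- simulate_cohort(cfg, seed = 100 + s, graph = g)
    fit <- coapm_grid_search(co, covariates = tv_covs)
    unlist(fit$details[c("tau1", "gamma1", "tau2", "gamma2")])
  }, numeric(4)))
  expect_equal(unname(apply(sel, 2, stats::median)), c(6, 3, 5, 4))
})

test_that("a grid without any full-rank candidate errors", {
  co <- simulate_cohort(scenario_config(1, n_population = 2), seed = 6)
  expect_error(coapm_grid_search(co, covariates = character(), grid_max = 1),
               class = "nof1_estimation_error")
})
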