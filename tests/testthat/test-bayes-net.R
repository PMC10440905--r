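test_that("lag augmentation shifts within patients and drops first days", {
  d <- toy_trial(treatment = c(1, 1, 2, 2, 2, 1),
                 pain = c(5, 4, 3, 2, 6, 7),
                 patient_id = rep(1:2, each = 3))
  a <- augment_lags(d)
  expect_equal(nrow(a), 4)
  expect_equal(a$treatment_lag, c(1, 1, 2, 2))
  expect_equal(a$pain_lag, c(5, 4, 2, 6))
  # constant treatment within a period: lag equals current except at
  # period boundaries
  co <- simulate_cohort(scenario_config(1, n_population = 1), seed = 3)
  a2 <- augment_lags(co)
  boundary <- a2$day %in% (28 * (1:3) + 1)
  expect_true(all((a2$treatment_lag == a2$treatment)[!boundary]))
  dup <- d
  dup$day[2] <- dup$day[1]
  expect_error(augment_lags(dup), class = "nof1_argument_error")
})

test_that("the time-adjusted structure wires the lag nodes", {
  g <- scenario_graph(scenario_config(1))
  s0 <- bn_structure(g)
  st <- bn_structure(g, time_adjust = TRUE)
  expect_equal(length(st), length(s0) + 2)
  expect_true("treatment_lag" %in% st$pain_lag)
  expect_true("pain_lag" %in% st$pain)
  expect_true("treatment_lag" %in% st$treatment)
  expect_true("treatment_lag" %in% st$activity)
  expect_setequal(attr(st, "clamp"), c("treatment", "treatment_lag"))
  # the latent underlying state is never a network node
  expect_false("underlying_state" %in% names(st))
})

test_that("a single-edge network recovers its generating weight", {
  set.seed(71)
  n <- 5000
  d <- tibble::tibble(
    patient_id = 1L, day = 1:n,
    treatment = sample(1:2, n, replace = TRUE), missing = FALSE
  )
  d$pain <- 8 - 2 * d$treatment + rnorm(n, 0, 0.5)
  s <- structure(list(treatment = character(), pain = "treatment"),
                 treatment = "treatment", outcome = "pain",
                 clamp = "treatment")
  net <- fit_network(d, s, prior_weight = 0)
  ref <- lm(pain ~ treatment, data = d)
  expect_equal(unname(net$nodes$pain$coef), unname(coef(ref)), tolerance = 1e-8)
  # parent-free node: intercept is the plain mean at zero prior weight
  expect_equal(unname(net$nodes$treatment$coef[[1]]), mean(d$treatment))
})

test_that("posterior-mean coefficients equal the matched ridge solution", {
  set.seed(72)
  n <- 200
  d <- tibble::tibble(
    patient_id = 1L, day = 1:n, treatment = sample(1:2, n, replace = TRUE),
    x = rnorm(n), missing = FALSE
  )
  d$pain <- 3 + 0.7 * d$x - 1.2 * d$treatment + rnorm(n)
  s <- structure(list(treatment = character(), x = character(),
                      pain = c("treatment", "x")),
                 treatment = "treatment", outcome = "pain", clamp = "treatment")
  w <- 5
  net <- fit_network(d, s, prior_weight = w)
  # oracle via augmented-data least squares: scaling X'X by (1 + w/n) is
  # equivalent to shrinking the OLS solution by n / (n + w)
  X <- cbind(1, d$treatment, d$x)
  ols <- solve(crossprod(X), crossprod(X, d$pain))[, 1]
  expect_equal(unname(net$nodes$pain$coef), unname(ols) * n / (n + w),
               tolerance = 1e-8)
})

test_that("intervention sampling estimates the effect difference", {
  set.seed(73)
  n <- 4000
  d <- tibble::tibble(
    patient_id = 1L, day = 1:n,
    treatment = sample(1:2, n, replace = TRUE), missing = FALSE
  )
  d$pain <- 8 - 2 * d$treatment + rnorm(n, 0, 0.5)
  s <- structure(list(treatment = character(), pain = "treatment"),
                 treatment = "treatment", outcome = "pain", clamp = "treatment")
  net <- fit_network(d, s, prior_weight = 0)
  ate <- estimate_ate(net, n_samples = 1000, seed = 5)
  mc_se <- sqrt(2 * 0.5^2 / 1000)
  expect_equal(ate$estimate, 2, tolerance = 4 * mc_se + 0.05)
  expect_equal(length(ate$details$samples1), 1000)
  expect_equal(length(ate$details$samples2), 1000)
})

test_that("sampled effects agree with the path-tracing closed form", {
  # mediation structure: treatment -> mediator -> outcome plus direct edge
  set.seed(74)
  n <- 3000
  d <- tibble::tibble(patient_id = 1L, day = 1:n,
                      treatment = sample(1:2, n, replace = TRUE),
                      missing = FALSE)
  d$med <- 1 + 0.8 * d$treatment + rnorm(n, 0, 0.5)
  d$pain <- 7 - 1.5 * d$treatment - 0.6 * d$med + rnorm(n, 0, 0.5)
  s <- structure(list(treatment = character(), med = "treatment",
                      pain = c("treatment", "med")),
                 treatment = "treatment", outcome = "pain", clamp = "treatment")
  net <- fit_network(d, s, prior_weight = 0)
  # total effect per unit of treatment = direct + mediated path product
  w_tm <- net$nodes$med$coef[["treatment"]]
  w_to <- net$nodes$pain$coef[["treatment"]]
  w_mo <- net$nodes$pain$coef[["med"]]
  total <- w_to + w_tm * w_mo
  ate <- estimate_ate(net, n_samples = 5000, seed = 6)
  # arm 1 minus arm 2 flips the sign of the per-unit effect
  expect_equal(ate$estimate, -total, tolerance = 0.06)
})

test_that("lag coefficients vanish on temporally independent data", {
  set.seed(75)
  cfg <- scenario_config(1, n_population = 60)
  g <- scenario_graph(cfg)
  co <- simulate_cohort(cfg, seed = 75, graph = g)
  # break temporal dependence by shuffling days within patients
  shuffled <- co |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(day = sample(day)) |>
    dplyr::arrange(patient_id, day) |>
    dplyr::ungroup()
  net <- fit_network(augment_lags(shuffled), bn_structure(g, time_adjust = TRUE))
  expect_lt(abs(net$nodes$pain$coef[["pain_lag"]]), 0.05)
})

test_that("sampling noise shrinks with the per-arm sample count", {
  set.seed(76)
  d <- tibble::tibble(patient_id = 1L, day = 1:2000,
                      treatment = sample(1:2, 2000, replace = TRUE),
                      missing = FALSE)
  d$pain <- 6 - 1 * d$treatment + rnorm(2000)
  s <- structure(list(treatment = character(), pain = "treatment"),
                 treatment = "treatment", outcome = "pain", clamp = "treatment")
  net <- fit_network(d, s, prior_weight = 0)
  est_small <- vapply(1:40, function(s2) {
    estimate_ate(net, n_samples = 100, seed = s2)$estimate
  }, numeric(1))
  est_big <- vapply(1:40, function(s2) {
    estimate_ate(net, n_samples = 10000, seed = 1000 + s2)$estimate
  }, numeric(1))
  ratio <- sd(est_small) / sd(est_big)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("the full wrapper runs both network variants on a cohort", {
  cfg <- scenario_config(1, n_population = 30)
  g <- scenario_graph(cfg)
  co <- simulate_cohort(cfg, seed = 77, graph = g)
  bn <- bn_estimate(co, g, seed = 1)
  bnt <- bn_estimate(co, g, time_adjust = TRUE, seed = 1)
  expect_equal(bn$method, "bn")
  expect_equal(bnt$method, "bn_time")
  expect_equal(bn$estimate, 2, tolerance = 0.5)
  expect_equal(bnt$estimate, 2, tolerance = 0.5)
})
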