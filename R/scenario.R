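#' Scenario configuration for the simulation study
#'
#' The four study scenarios cross two switches: carry-over (exponential
#' wash-in/wash-out of the treatment effect) and the activity interaction
#' (treatment effect modified by activity, plus temporal effects of
#' treatment on activity and quality of sleep):
#'
#' | scenario | carry-over | activity interaction |
#' |---------:|:----------:|:--------------------:|
#' | 1 | no (`tau = gamma = 1`) | no (`w_AT = 0`) |
#' | 2 | yes (`tau1 = 6, gamma1 = 3, tau2 = 5, gamma2 = 4`) | no |
#' | 3 | no | yes (`w_AT != 0`) |
#' | 4 | yes | yes |
#'
#' The crossover design is 2 blocks of two 28-day treatment periods (16
#' weeks, 112 days) and the simulated population holds 1000 patients;
#' treatment effects on the outcome are -2 and -4, a true effect
#' difference of 2.
#'
#' @param scenario Integer in 1..4.
#' @param ... Named overrides of any configuration field (e.g.
#'   `period_length = 7`, `n_population = 200`).
#' @return A list of class `nof1_scenario` with fields `scenario`,
#'   `carry_over`, `activity_interaction`, `missingness`, `blocks`,
#'   `period_length`, `n_population`, `effects`, `tau`, `gamma`,
#'   `activity_modifier`, `ordinal_outcome`, `missing_rate`,
#'   `missing_block`.
#' @export
#' @examples
#' scenario_config(2)$tau
#' scenario_config(4, period_length = 7)
scenario_config <- function(scenario, ...) {
  if (!is.numeric(scenario) || length(scenario) != 1 || !scenario %in% 1:4) {
    abort("`scenario` must be one of 1, 2, 3, 4.", class = "nof1_argument_error")
  }
  scenario <- as.integer(scenario)
  carry <- scenario %in% c(2L, 4L)
  inter <- scenario %in% c(3L, 4L)
  cfg <- list(
    scenario = scenario,
    carry_over = carry,
    activity_interaction = inter,
    missingness = FALSE,
    blocks = 2L,
    period_length = 28L,
    n_population = 1000L,
    effects = c(-2, -4),
    tau = if (carry) c(6, 5) else c(1, 1),
    gamma = if (carry) c(3, 4) else c(1, 1),
    activity_modifier = if (inter) 0.3 else 0,
    ordinal_outcome = TRUE,
    missing_rate = 0.1,
    missing_block = 10L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("Unknown scenario override(s): ",
                   paste(unknown, collapse = ", ")),
            class = "nof1_argument_error")
    }
    cfg <- modifyList(cfg, dots)
  }
  structure(cfg, class = "nof1_scenario")
}

#' @export
print.nof1_scenario <- function(x, ...) {
  cat("<nof1_scenario>", x$scenario,
      "| carry-over:", x$carry_over,
      "| activity interaction:", x$activity_interaction,
      "| missingness:", x$missingness, "\n")
  cat("  design:", x$blocks, "blocks x 2 periods x", x$period_length,
      "days | population:", x$n_population, "\n")
  invisible(x)
}

#' Specialise a causal graph to a scenario
#'
#' Applies a scenario's switches to a graph: sets the carry-over parameters
#' `tau`/`gamma`, and either activates (scenarios 3/4) or removes
#' (scenarios 1/2) the activity interaction — the effect-modifier weight and
#' the lagged treatment edges. When the interaction is active, the modifier
#' is centred at the theoretical mean of the modifier node (its parents'
#' contribution plus half the lagged treatment weight, since under the
#' randomized design the previous day is under treatment 2 with long-run
#' probability 1/2), so the population-average effect difference stays at
#' the configured value.
#'
#' @param config A [scenario_config()].
#' @param graph A [causal_graph()]; defaults to [default_backpain_graph()].
#' @return A [causal_graph()] with scenario parameters applied.
#' @export
scenario_graph <- function(config, graph = default_backpain_graph()) {
  graph$tau <- config$tau
  graph$gamma <- config$gamma
  tn <- treatment_node(graph)
  lagged_trt <- graph$edges$lag > 0L & graph$edges$from %in% tn
  if (config$activity_interaction) {
    graph$activity_modifier <- config$activity_modifier
    lag_w <- graph$edges$weight[lagged_trt & graph$edges$to == graph$modifier_node]
    parent_mean <- 0 # modifier's non-treatment parents are centred in the default graph
    graph$modifier_center <- parent_mean + 0.5 * sum(lag_w)
  } else {
    graph$activity_modifier <- 0
    graph$modifier_center <- 0
    graph$edges <- graph$edges[!lagged_trt, , drop = FALSE]
  }
  graph$treatment_effects <- config$effects
  validate_graph(graph)
}
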