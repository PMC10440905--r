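#' Simulate one patient's N-of-1 trial trajectory
#'
#' Generates a per-day record for a single patient by evaluating the causal
#' graph's structural equations in topological order:
#' * exogenous (parent-free) nodes are drawn from their declared
#'   distributions — once at baseline for `constant` nodes, freshly each day
#'   for `time_varying` nodes;
#' * endogenous nodes are weighted sums of their parents plus Gaussian
#'   noise, with instantaneous and lagged edges (a lagged value before the
#'   study start counts as 0), then passed through a step function when a
#'   `threshold` is declared;
#' * the underlying state is a discrete-time Wiener process;
#' * the outcome adds the treatment contribution
#'   \eqn{\sum_k (\beta_k + w_{A,T}(A^t - \bar A)) E_k^t}, where
#'   \eqn{E_k^t} follows the exponential-decay recursion of
#'   [exposure_decay()] with the graph's `tau`/`gamma`, \eqn{\beta_k} are
#'   the graph's `treatment_effects`, and the modifier term is active only
#'   when `activity_modifier != 0`.
#'
#' When `ordinal_outcome` is `TRUE` (the study default), the continuous
#' outcome is truncated to \eqn{[0, 10]} and rounded to integers, emulating
#' a pain score scale; the analysis models deliberately treat this ordinal
#' score as continuous.
#'
#' @param graph A [causal_graph()] (typically from [scenario_graph()]).
#' @param design A design tibble from [generate_design()].
#' @param config Optional [scenario_config()]; only `ordinal_outcome` is
#'   consulted here (carry-over parameters live on the graph).
#' @param seed Integer seed.
#' @param patient_id Identifier stored in the output.
#' @return A tibble with one row per day: `patient_id`, `day`, `block`,
#'   `period`, `treatment`, one column per non-latent covariate node, the
#'   outcome column, and a logical `missing` mask (all `FALSE`; see
#'   [apply_missingness()]).
#' @export
simulate_patient <- function(graph, design, config = NULL, seed = 1L,
                             patient_id = 1L) {
  n_days <- nrow(design)
  trt <- design$treatment
  ordinal <- config$ordinal_outcome %||% TRUE
  order <- topological_order(graph)
  nodes <- graph$nodes
  out_nd <- outcome_node(graph)
  trt_nd <- treatment_node(graph)
  dft_nd <- drift_node(graph)

  e1 <- exposure_decay((trt == 1) * 1, graph$tau[1], graph$gamma[1])[-1]
  e2 <- exposure_decay((trt == 2) * 1, graph$tau[2], graph$gamma[2])[-1]

  values <- list()
  with_seed(seed, {
    for (nd in order) {
      spec <- nodes[nodes$name == nd, ]
      if (identical(nd, trt_nd)) {
        values[[nd]] <- as.numeric(trt)
        next
      }
      if (identical(nd, dft_nd)) {
        u <- simulate_underlying_state(
          n_days,
          drift_mean = if (is.na(spec$param1)) 0 else spec$param1,
          innovation_sd = if (is.na(spec$param2)) 0 else spec$param2
        )
        values[[nd]] <- u[-1]
        next
      }
      inc <- graph$edges[graph$edges$to == nd, , drop = FALSE]
      constant <- identical(spec$role, "constant")
      if (nrow(inc) == 0 && !identical(nd, out_nd)) {
        if (is.na(spec$distribution)) {
          abort(paste0("Node `", nd, "` has no parents and no distribution."),
                class = "nof1_config_error")
        }
        m <- if (constant) 1L else n_days
        v <- switch(spec$distribution,
          gaussian  = rnorm(m, spec$param1 %|0|% 0, spec$param2 %|0|% 1),
          bernoulli = rbinom(m, 1, spec$param1 %|0|% 0.5),
          poisson   = rpois(m, spec$param1 %|0|% 1),
          uniform   = runif(m, spec$param1 %|0|% 0, spec$param2 %|0|% 1)
        )
      } else {
        v <- rep(0, n_days)
        for (r in seq_len(nrow(inc))) {
          from <- inc$from[r]
          w <- inc$weight[r]
          l <- inc$lag[r]
          if (l == 0L) {
            pv <- if (identical(from, trt_nd)) e1 + e2 else values[[from]]
            if (is.null(pv)) {
              abort(paste0("Parent `", from, "` of `", nd,
                           "` not generated yet."),
                    class = "nof1_config_error")
            }
            v <- v + w * pv
          } else {
            pv <- if (identical(from, trt_nd)) {
              (values[[from]] %||% as.numeric(trt)) == 2
            } else {
              values[[from]]
            }
            if (is.null(pv)) {
              abort(paste0("Lagged parent `", from, "` of `", nd,
                           "` must precede it in generation order."),
                    class = "nof1_config_error")
            }
            # only lags l <= t contribute; earlier days see 0
            v <- v + w * c(rep(0, l), as.numeric(pv)[seq_len(n_days - l)])
          }
        }
        if (identical(nd, out_nd)) {
          eff <- graph$treatment_effects
          if (graph$activity_modifier != 0) {
            mod <- values[[graph$modifier_node]]
            if (is.null(mod)) {
              abort(paste0("Modifier node `", graph$modifier_node,
                           "` not generated before the outcome."),
                    class = "nof1_config_error")
            }
            mod <- graph$activity_modifier * (mod - graph$modifier_center)
          } else {
            mod <- 0
          }
          v <- v + (eff[1] + mod) * e1 + (eff[2] + mod) * e2
        }
        nm <- spec$noise_mean %|0|% 0
        ns <- spec$noise_sd %|0|% 0
        m <- if (constant) 1L else n_days
        noise <- if (ns > 0) rnorm(m, nm, ns) else rep(nm, m)
        v <- if (constant) v[1] + noise else v + noise
      }
      if (!is.na(spec$threshold)) v <- (v >= spec$threshold) * 1
      if (constant && length(v) == 1) v <- rep(v, n_days)
      values[[nd]] <- v
    }
  })

  outcome <- values[[out_nd]]
  if (ordinal) outcome <- round(pmin(10, pmax(0, outcome)))
  covars <- setdiff(order, c(trt_nd, out_nd, dft_nd))
  # stable, declaration-order columns
  covars <- nodes$name[nodes$name %in% covars]
  res <- tibble::tibble(
    patient_id = as.integer(patient_id),
    day = design$day,
    block = design$block,
    period = design$period,
    treatment = as.integer(trt)
  )
  for (cv in covars) res[[cv]] <- values[[cv]]
  res[[out_nd]] <- outcome
  res$missing <- FALSE
  res
}

# NA-tolerant default helper for scalar node parameters
`%|0|%` <- function(x, default) if (is.null(x) || is.na(x)) default else x

#' Simulate a cohort of independent N-of-1 trials
#'
#' Simulates `n_patients` independent patients under one scenario. Each
#' patient gets an independently randomized block order and an independent
#' RNG sub-stream derived from the master seed with [derive_seed()], so a
#' cohort is bit-identical under the same `(graph, config, seed)` and
#' patients are mutually independent. If `config$missingness` is `TRUE`, the
#' two drop-out mechanisms of [apply_missingness()] are applied.
#'
#' @param config A [scenario_config()].
#' @param n_patients Number of patients; defaults to the configured
#'   population size.
#' @param seed Integer master seed.
#' @param graph A [causal_graph()]; defaults to
#'   `scenario_graph(config)`.
#' @return A long tibble (class `nof1_cohort`), one row per patient-day,
#'   with attributes `config`, `graph` and `seed`.
#' @export
#' @examples
#' cfg <- scenario_config(1, n_population = 3, period_length = 2)
#' simulate_cohort(cfg, seed = 7)
simulate_cohort <- function(config, n_patients = config$n_population,
                            seed = 1L, graph = NULL) {
  if (n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "nof1_argument_error")
  }
  graph <- graph %||% scenario_graph(config)
  frames <- purrr::map(seq_len(n_patients), function(i) {
    design <- generate_design(config, seed = derive_seed(seed, i, 1L))
    simulate_patient(graph, design, config,
                     seed = derive_seed(seed, i, 2L), patient_id = i)
  })
  cohort <- dplyr::bind_rows(frames)
  cohort <- new_cohort(cohort, config = config, graph = graph, seed = seed)
  if (isTRUE(config$missingness)) {
    cohort <- apply_missingness(cohort, seed = derive_seed(seed, 0L, 3L),
                                rate = config$missing_rate,
                                block_length = config$missing_block)
  }
  cohort
}

new_cohort <- function(df, config = NULL, graph = NULL, seed = NULL) {
  structure(
    df,
    config = config, graph = graph, seed = seed,
    class = unique(c("nof1_cohort", class(tibble::as_tibble(df))))
  )
}
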