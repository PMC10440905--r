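#' Run one analysis method on a trial data set
#'
#' Dispatcher used by the Monte-Carlo harness and the command line. Method
#' names: `sample_mean`, `lm`, `coapm`, `gest_ind`, `gest_ar1`, `bn`,
#' `bn_time`.
#'
#' @param data A long trial tibble.
#' @param method Method name.
#' @param graph The assumed [causal_graph()] (needed by the network
#'   methods); defaults to the cohort's generating graph attribute, or
#'   [default_backpain_graph()].
#' @param seed Seed for methods with internal sampling (`bn`, `bn_time`).
#' @param ... Passed to the method function (e.g. `grid_max` for
#'   [coapm_grid_search()]).
#' @return An `nof1_estimate`.
#' @export
analyze <- function(data, method, graph = NULL, seed = 1L, ...) {
  graph <- graph %||% attr(data, "graph") %||% default_backpain_graph()
  switch(
    method,
    sample_mean = sample_mean_estimate(data, ...),
    lm = linear_model_estimate(data, ...),
    coapm = coapm_grid_search(data, ...),
    gest_ind = g_estimate(data, correlation = "independence", ...),
    gest_ar1 = g_estimate(data, correlation = "ar1", ...),
    bn = bn_estimate(data, graph, time_adjust = FALSE, seed = seed, ...),
    bn_time = bn_estimate(data, graph, time_adjust = TRUE, seed = seed, ...),
    abort(paste0("Unknown method `", method, "`."),
          class = "nof1_argument_error")
  )
}

#' All method names known to [analyze()]
#' @return Character vector.
#' @export
nof1_methods <- function() {
  c("sample_mean", "lm", "coapm", "gest_ind", "gest_ar1", "bn", "bn_time")
}

#' Monte-Carlo evaluation of one scenario
#'
#' Simulates one population under the scenario (default 1000 patients),
#' then for each requested sample size draws `replicates` independent
#' samples of patients without replacement, runs every requested method on
#' each sample, and summarises the estimates: the mean across replicates
#' measures bias, the empirical standard deviation across replicates is the
#' empirical standard error (the efficiency measure), and the mean of the
#' model-based SEs is reported where a method provides one. A method
#' failure on a replicate is caught and counted; cells with more than 10%
#' failures are flagged `degraded`.
#'
#' @param scenario Scenario id 1..4 or a [scenario_config()].
#' @param methods Character vector of method names (see [nof1_methods()]).
#' @param sample_sizes Patient counts to draw.
#' @param replicates Samples per size (default 100).
#' @param seed Integer master seed.
#' @param missing Apply the drop-out mechanisms to the population.
#' @param ... Overrides forwarded to [scenario_config()] when `scenario`
#'   is an id.
#' @return A tibble of class `nof1_mc` with one row per (method, sample
#'   size): `scenario`, `missing`, `method`, `n_patients`, `replicates`,
#'   `n_ok`, `mean_estimate`, `sd_estimate`, `mean_se`, `degraded`. The
#'   per-replicate results are attached as attribute `"replicates"`.
#' @export
#' @examples
#' run_scenario(1, methods = "sample_mean", sample_sizes = 5,
#'              replicates = 3, seed = 1, n_population = 20)
run_scenario <- function(scenario, methods = nof1_methods(),
                         sample_sizes = c(5L, 10L, 25L, 50L, 100L),
                         replicates = 100L, seed = 1L, missing = FALSE, ...) {
  config <- if (inherits(scenario, "nof1_scenario")) {
    scenario
  } else {
    scenario_config(scenario, missingness = missing, ...)
  }
  if (config$n_population < max(sample_sizes)) {
    abort("Population smaller than the largest sample size.",
          class = "nof1_argument_error")
  }
  graph <- scenario_graph(config)
  population <- simulate_cohort(
    config, seed = derive_seed(seed, config$scenario, as.integer(config$missingness)),
    graph = graph
  )
  ids <- unique(population$patient_id)
  cells <- tidyr::expand_grid(n_patients = as.integer(sample_sizes),
                              replicate = seq_len(replicates))
  rows <- purrr::pmap_dfr(cells, function(n_patients, replicate) {
    rep_seed <- derive_seed(seed, config$scenario,
                            as.integer(config$missingness),
                            n_patients, replicate)
    chosen <- with_seed(rep_seed, sample(ids, n_patients))
    samp <- population[population$patient_id %in% chosen, , drop = FALSE]
    attr(samp, "graph") <- graph
    purrr::map_dfr(seq_along(methods), function(mi) {
      est <- tryCatch(
        analyze(samp, methods[mi], graph = graph,
                seed = derive_seed(rep_seed, mi)),
        error = function(e) NULL
      )
      if (is.null(est)) {
        tibble::tibble(method = methods[mi], n_patients = n_patients,
                       replicate = replicate, estimate = NA_real_,
                       se = NA_real_, failed = TRUE)
      } else {
        dplyr::bind_cols(
          tibble::tibble(method = methods[mi], n_patients = n_patients,
                         replicate = replicate),
          glance(est)[setdiff(names(glance(est)), c("method", "n_patients"))],
          tibble::tibble(failed = FALSE)
        )
      }
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$method, .data$n_patients) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      n_ok = sum(!.data$failed),
      mean_estimate = mean(.data$estimate, na.rm = TRUE),
      sd_estimate = if (sum(!.data$failed) > 1) {
        sd(.data$estimate, na.rm = TRUE)
      } else {
        NA_real_
      },
      mean_se = if (all(is.na(.data$se))) NA_real_ else mean(.data$se, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degraded = (.data$replicates - .data$n_ok) / .data$replicates > 0.1,
      scenario = config$scenario,
      missing = config$missingness,
      .before = 1
    ) |>
    dplyr::relocate("method", "n_patients", .after = "missing") |>
    dplyr::arrange(match(.data$method, methods), .data$n_patients)
  attr(summary, "replicates") <- rows
  class(summary) <- c("nof1_mc", class(summary))
  summary
}

#' Full bias/efficiency study across all scenarios
#'
#' Runs every scenario with and without missing values for all requested
#' methods and sample sizes, and optionally writes the tidy results table
#' (CSV) and the summary figure (estimates with empirical-SE bars versus
#' sample size, one panel per scenario and missingness status, reference
#' line at the simulated truth of 2).
#'
#' @inheritParams run_scenario
#' @param scenarios Scenario ids to run.
#' @param with_missing Also run each scenario with drop-out applied.
#' @param out_dir Output directory for `results.csv` and `fig_summary.svg`;
#'   `NULL` writes nothing.
#' @return An `nof1_mc` table combining all runs.
#' @export
full_study <- function(seed = 1L, scenarios = 1:4,
                       methods = nof1_methods(),
                       sample_sizes = c(5L, 10L, 25L, 50L, 100L),
                       replicates = 100L, with_missing = TRUE,
                       out_dir = NULL, ...) {
  miss_levels <- if (with_missing) c(FALSE, TRUE) else FALSE
  grid <- tidyr::expand_grid(scenario = scenarios, missing = miss_levels)
  parts <- purrr::pmap(grid, function(scenario, missing) {
    run_scenario(scenario, methods = methods, sample_sizes = sample_sizes,
                 replicates = replicates, seed = seed, missing = missing, ...)
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "replicates") <- dplyr::bind_rows(
    purrr::map2(parts, seq_len(nrow(grid)), function(p, i) {
      dplyr::mutate(attr(p, "replicates"),
                    scenario = grid$scenario[i], missing = grid$missing[i],
                    .before = 1)
    })
  )
  class(out) <- c("nof1_mc", class(tibble::as_tibble(out)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tibble::as_tibble(out), file.path(out_dir, "results.csv"))
    ggplot2::ggsave(file.path(out_dir, "fig_summary.svg"), autoplot(out),
                    device = grDevices::svg,
                    width = 10, height = 2.5 * length(scenarios))
  }
  out
}

#' Plot a Monte-Carlo results table
#'
#' Mean estimated treatment effect difference with empirical-SE error bars
#' against sample size, per method, facetted by scenario and missingness,
#' with a dashed reference line at the simulated truth.
#'
#' @param object An `nof1_mc` table.
#' @param truth Reference value (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nof1_mc <- function(object, truth = 2, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      panel = paste0("scenario ", .data$scenario,
                     ifelse(.data$missing, " (missing)", ""))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_patients),
                                   y = .data$mean_estimate,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_hline(yintercept = truth, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_estimate - .data$sd_estimate,
                   ymax = .data$mean_estimate + .data$sd_estimate),
      width = 0.3, position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::facet_wrap(~panel, ncol = 2) +
    ggplot2::labs(x = "sample size (patients)",
                  y = "estimated treatment effect difference",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot one patient's simulated trajectory
#'
#' Outcome over time with treatment periods shaded, a quick visual check of
#' wash-in/wash-out behaviour.
#'
#' @param cohort A cohort tibble.
#' @param patient Patient id to plot.
#' @param outcome Outcome column.
#' @return A ggplot object.
#' @export
plot_patient <- function(cohort, patient = 1L, outcome = "pain") {
  df <- cohort[cohort$patient_id == patient, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data[[outcome]])) +
    ggplot2::geom_line(ggplot2::aes(colour = factor(.data$treatment),
                                    group = 1)) +
    ggplot2::geom_point(data = df[df$missing, , drop = FALSE],
                        shape = 4, colour = "grey40") +
    ggplot2::labs(colour = "treatment", x = "day", y = outcome) +
    ggplot2::theme_minimal()
}
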