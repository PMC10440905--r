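#' Add lag-1 columns for the time-adjusted network
#'
#' Creates within-patient lagged copies of the treatment and outcome
#' columns (`treatment_lag`, `pain_lag` for the default outcome) and drops
#' each patient's first `lag` days, which have no lagged value.
#'
#' @param data A long trial tibble with `patient_id` and `day`.
#' @param lag Lag size (days), default 1.
#' @param outcome Outcome column name.
#' @return The lag-augmented tibble.
#' @export
augment_lags <- function(data, lag = 1L, outcome = "pain") {
  if (anyDuplicated(data[, c("patient_id", "day")])) {
    abort("Duplicate (patient_id, day) rows; cannot order days.",
          class = "nof1_argument_error")
  }
  data |>
    dplyr::arrange(.data$patient_id, .data$day) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      treatment_lag = dplyr::lag(.data$treatment, n = lag),
      "{outcome}_lag" := dplyr::lag(.data[[outcome]], n = lag)
    ) |>
    dplyr::filter(dplyr::row_number() > lag) |>
    dplyr::ungroup()
}

#' Network structure implied by a causal graph
#'
#' Derives the Bayesian-network parent sets from a [causal_graph()]'s
#' instantaneous edges among the *observed* variables: the latent underlying
#' state is dropped, and the treatment node (coded numerically 1/2 in the
#' data) is a parent of the outcome. With `time_adjust = TRUE`, lag-1 nodes
#' are added and wired so that the lagged treatment drives the current
#' treatment, the modifier node, and the lagged outcome, whose value in turn
#' feeds the current outcome; the lagged treatment is clamped together with
#' the treatment during intervention sampling.
#'
#' @param graph A [causal_graph()].
#' @param time_adjust Add the lag-1 treatment and outcome nodes.
#' @return A named list of parent-name character vectors, with attributes
#'   `treatment`, `outcome` and `clamp`.
#' @export
bn_structure <- function(graph, time_adjust = FALSE) {
  tn <- treatment_node(graph)
  on <- outcome_node(graph)
  dn <- drift_node(graph)
  observed <- setdiff(graph$nodes$name, dn)
  e0 <- graph$edges[graph$edges$lag == 0L &
                      graph$edges$from %in% observed &
                      graph$edges$to %in% observed, , drop = FALSE]
  parents <- lapply(setNames(observed, observed),
                    function(nd) e0$from[e0$to == nd])
  parents[[on]] <- union(parents[[on]], tn)
  clamp <- tn
  if (time_adjust) {
    tl <- paste0(tn, "_lag")
    ol <- paste0(on, "_lag")
    parents[[tl]] <- character()
    parents[[ol]] <- c(tl, setdiff(parents[[on]], tn))
    parents[[tn]] <- union(parents[[tn]], tl)
    parents[[on]] <- union(parents[[on]], ol)
    if (graph$modifier_node %in% names(parents)) {
      parents[[graph$modifier_node]] <- union(parents[[graph$modifier_node]], tl)
    }
    clamp <- c(tn, tl)
  }
  structure(parents, treatment = tn, outcome = on, clamp = clamp)
}

#' Fit a linear-Gaussian Bayesian network
#'
#' Fits every node of the supplied structure as a Bayesian linear regression
#' of the node on its parents (Gaussian likelihood), with all variables —
#' including 0/1-coded binaries — modelled as Gaussian. The prior is a weak
#' unit-information Gaussian prior on the coefficients equivalent to
#' `prior_weight` pseudo-observations, so posterior-mean coefficients equal
#' the ridge solution \eqn{(X'X + w X'X/n)^{-1} X'y} and reduce to OLS as
#' `prior_weight` tends to 0. Masked rows are excluded per node
#' (complete-case).
#'
#' @param data A long trial tibble.
#' @param structure Parent sets from [bn_structure()].
#' @param prior_weight Prior pseudo-observation count (default 1).
#' @return An object of class `nof1_bn`: per-node `parents`, `coef`
#'   (intercept first), `sd`, plus the structure's metadata.
#' @export
fit_network <- function(data, structure, prior_weight = 1) {
  data <- data[!(data$missing %||% FALSE), , drop = FALSE]
  nodes <- names(structure)
  missing_cols <- setdiff(nodes, names(data))
  if (length(missing_cols)) {
    abort(paste0("Data lacks node column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "nof1_argument_error")
  }
  fits <- lapply(setNames(nodes, nodes), function(nd) {
    pa <- structure[[nd]]
    cols <- c(nd, pa)
    cc <- data[stats::complete.cases(as.data.frame(data[, cols, drop = FALSE])), cols, drop = FALSE]
    y <- as.numeric(cc[[nd]])
    X <- if (length(pa)) {
      cbind(`(Intercept)` = rep(1, length(y)),
            as.matrix(as.data.frame(lapply(cc[, pa, drop = FALSE], as.numeric))))
    } else {
      matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      abort(paste0("Rank-deficient parent design for node `", nd, "`."),
            class = "nof1_estimation_error")
    }
    n <- nrow(X)
    XtX <- crossprod(X)
    b <- drop(solve(XtX * (1 + prior_weight / n), crossprod(X, y)))
    res <- y - drop(X %*% b)
    sd_res <- sqrt(sum(res^2) / max(n - ncol(X), 1))
    list(parents = pa, coef = setNames(b, colnames(X)), sd = sd_res, n = n)
  })
  out <- list(nodes = fits,
              treatment = attr(structure, "treatment"),
              outcome = attr(structure, "outcome"),
              clamp = attr(structure, "clamp"))
  class(out) <- "nof1_bn"
  out
}

#' @export
print.nof1_bn <- function(x, ...) {
  cat("<nof1_bn> linear-Gaussian network,", length(x$nodes), "nodes\n")
  cat("  treatment:", x$treatment, "| outcome:", x$outcome,
      "| clamped under intervention:", paste(x$clamp, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_network Per-node coefficient table.
#' @param x An `nof1_bn`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nof1_bn <- function(x, ...) {
  purrr::map_dfr(names(x$nodes), function(nd) {
    f <- x$nodes[[nd]]
    tibble::tibble(node = nd, term = names(f$coef),
                   estimate = unname(f$coef), residual_sd = f$sd)
  })
}

#' Average treatment effect difference by intervention sampling
#'
#' Draws `n_samples` forward samples per treatment arm from the fitted
#' network with the treatment node (and its lag copy, if present) clamped
#' to the arm's value — sampling from the mutilated graph, which for a
#' point intervention on these nodes coincides with likelihood weighting on
#' point evidence. Confounders are sampled from their fitted models, so
#' both arms share the same confounder distribution. The estimate is the
#' difference in mean outcomes, arm 1 minus arm 2 (truth +2 under the study
#' convention).
#'
#' @param network An `nof1_bn` from [fit_network()].
#' @param n_samples Samples per arm (default 1000).
#' @param seed Integer seed.
#' @return An object of classes `bn_ate` and `nof1_estimate`; `details`
#'   holds the per-arm outcome means `mean1`, `mean2` and the per-arm
#'   sample vectors.
#' @export
estimate_ate <- function(network, n_samples = 1000L, seed = 1L) {
  order <- bn_topological_order(network)
  draw_arm <- function(arm) {
    vals <- list()
    for (nd in order) {
      if (nd %in% network$clamp) {
        vals[[nd]] <- rep(as.numeric(arm), n_samples)
        next
      }
      f <- network$nodes[[nd]]
      mu <- rep(f$coef[[1]], n_samples)
      for (pa in f$parents) mu <- mu + f$coef[[pa]] * vals[[pa]]
      vals[[nd]] <- mu + rnorm(n_samples, 0, f$sd)
    }
    vals[[network$outcome]]
  }
  with_seed(seed, {
    s1 <- draw_arm(1)
    s2 <- draw_arm(2)
  })
  new_estimate(
    if (any(grepl("_lag$", names(network$nodes)))) "bn_time" else "bn",
    estimate = mean(s1) - mean(s2),
    details = list(mean1 = mean(s1), mean2 = mean(s2),
                   samples1 = s1, samples2 = s2,
                   n_samples = n_samples, seed = seed),
    n_obs = network$nodes[[network$outcome]]$n,
    subclass = "bn_ate"
  )
}

bn_topological_order <- function(network) {
  nodes <- sort(names(network$nodes))
  done <- character()
  while (length(done) < length(nodes)) {
    ready <- nodes[!nodes %in% done &
                     vapply(nodes, function(nd) {
                       all(network$nodes[[nd]]$parents %in% done)
                     }, logical(1))]
    if (!length(ready)) {
      abort("Cycle in network structure.", class = "nof1_structure_error")
    }
    done <- c(done, ready[1])
  }
  done
}

#' Bayesian-network estimate of the effect difference from trial data
#'
#' Convenience wrapper chaining [bn_structure()], optional [augment_lags()],
#' [fit_network()] and [estimate_ate()].
#'
#' @inheritParams fit_network
#' @param graph The assumed [causal_graph()].
#' @param time_adjust Use the lag-1 time-adjusted network.
#' @param n_samples,seed Passed to [estimate_ate()].
#' @return A `bn_ate` estimate.
#' @export
bn_estimate <- function(data, graph, time_adjust = FALSE,
                        n_samples = 1000L, seed = 1L, prior_weight = 1) {
  if (time_adjust) data <- augment_lags(data, outcome = outcome_node(graph))
  net <- fit_network(data, bn_structure(graph, time_adjust = time_adjust),
                     prior_weight = prior_weight)
  est <- estimate_ate(net, n_samples = n_samples, seed = seed)
  est$n_patients <- dplyr::n_distinct(data$patient_id)
  est
}
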