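#' Causal graph for the N-of-1 trial data-generating model
#'
#' A `causal_graph` declares the structural model the simulator draws from:
#' a set of nodes (variables) with roles and distributions, weighted directed
#' edges that may be instantaneous (`lag = 0`) or lagged (`lag >= 1`), the
#' per-treatment carry-over parameters (wash-in `tau`, wash-out `gamma`), and
#' the per-treatment effects on the outcome.
#'
#' Node roles:
#' * `constant` — sampled once per patient at baseline and repeated daily.
#' * `time_varying` — fresh noise each day.
#' * `treatment` — values come from the crossover design, not a distribution.
#' * `outcome` — exactly one node; receives the treatment effects through the
#'   exponential-decay exposure indicators, plus all incoming edges and its
#'   own Gaussian noise (whose mean acts as the baseline intercept).
#' * `drift` — the underlying state, a discrete-time Wiener process; `param1`
#'   is the per-day drift mean and `param2` the innovation standard deviation.
#'
#' Edge conventions involving the treatment node (which is categorical with
#' levels 1 and 2):
#' * an instantaneous edge `treatment -> X` contributes
#'   `weight * (E1 + E2)`, i.e. a treatment-*presence* effect that is equal
#'   under both arms (every study day is under some treatment);
#' * a lagged edge `treatment -> X` contributes
#'   `weight * I(treatment at t - lag == 2)`, an arm contrast — these edges
#'   carry the temporal treatment–covariate effects of scenarios 3 and 4;
#' * treatment effects on the outcome are *not* edges: they are the
#'   `treatment_effects` field, applied as `sum_k effect_k * E_k(t)`.
#'
#' @param nodes A data frame with columns `name`, `role`, and optionally
#'   `distribution` (`gaussian`, `bernoulli`, `poisson`, `uniform`),
#'   `param1`, `param2` (distribution parameters for parent-free nodes),
#'   `threshold` (binarisation cut point, `NA` for none), `noise_mean`,
#'   `noise_sd` (structural-equation noise for nodes with parents).
#' @param edges A data frame with columns `from`, `to`, `weight` and
#'   optionally `lag` (default 0).
#' @param treatment_effects Numeric length 2: effects of treatments 1 and 2
#'   on the outcome, relative to no treatment. Defaults `c(-2, -4)`.
#' @param tau,gamma Numeric length 2, wash-in and wash-out parameters per
#'   treatment; both must be `>= 1`. `tau = gamma = c(1, 1)` is the
#'   no-carry-over case.
#' @param activity_modifier Effect-modifier weight \eqn{w_{A,T}} by which the
#'   (centred) modifier node multiplies into the treatment effect; 0 disables
#'   the interaction.
#' @param modifier_node Name of the effect-modifier node (default
#'   `"activity"`).
#' @param modifier_center Constant subtracted from the modifier before it
#'   scales the treatment effect, normally its population mean so that the
#'   average treatment effect is unchanged.
#'
#' @return An object of class `causal_graph`.
#' @seealso [parse_graph()], [topological_order()], [default_backpain_graph()]
#' @export
causal_graph <- function(nodes, edges,
                         treatment_effects = c(-2, -4),
                         tau = c(1, 1), gamma = c(1, 1),
                         activity_modifier = 0,
                         modifier_node = "activity",
                         modifier_center = 0) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("name", "role") %in% names(nodes))) {
    abort("`nodes` must have columns `name` and `role`.", class = "nof1_parse_error")
  }
  for (col in c("distribution", "param1", "param2", "threshold", "noise_mean", "noise_sd")) {
    if (!col %in% names(nodes)) {
      nodes[[col]] <- if (col == "distribution") NA_character_ else NA_real_
    }
  }
  nodes <- nodes[, c("name", "role", "distribution", "param1", "param2",
                     "threshold", "noise_mean", "noise_sd")]
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric(), lag = integer())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("from", "to", "weight") %in% names(edges))) {
      abort("`edges` must have columns `from`, `to`, `weight`.",
            class = "nof1_parse_error")
    }
    if (!"lag" %in% names(edges)) edges$lag <- 0L
    edges$lag <- as.integer(edges$lag)
    edges <- edges[, c("from", "to", "weight", "lag")]
  }
  g <- structure(
    list(nodes = nodes, edges = edges,
         treatment_effects = as.numeric(treatment_effects),
         tau = as.numeric(tau), gamma = as.numeric(gamma),
         activity_modifier = as.numeric(activity_modifier),
         modifier_node = modifier_node,
         modifier_center = as.numeric(modifier_center)),
    class = "causal_graph"
  )
  validate_graph(g)
}

validate_graph <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  if (anyDuplicated(nodes$name)) {
    abort(paste0("Duplicated node name: ",
                 paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", ")),
          class = "nof1_structure_error")
  }
  ok_roles <- c("constant", "time_varying", "treatment", "outcome", "drift")
  if (!all(nodes$role %in% ok_roles)) {
    abort(paste0("Unknown node role: ",
                 paste(setdiff(nodes$role, ok_roles), collapse = ", ")),
          class = "nof1_parse_error")
  }
  if (sum(nodes$role == "outcome") != 1) {
    abort("Exactly one node must have role `outcome`.",
          class = "nof1_structure_error")
  }
  bad_dist <- !is.na(nodes$distribution) &
    !nodes$distribution %in% c("gaussian", "bernoulli", "poisson", "uniform")
  if (any(bad_dist)) {
    abort(paste0("Unknown distribution: ",
                 paste(nodes$distribution[bad_dist], collapse = ", ")),
          class = "nof1_parse_error")
  }
  if (any(nodes$noise_sd < 0, na.rm = TRUE)) {
    abort("Node noise standard deviations must be >= 0.",
          class = "nof1_parse_error")
  }
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$from, edges$to)), nodes$name)
    if (length(unknown)) {
      abort(paste0("Edge references undeclared node(s): ",
                   paste(unknown, collapse = ", ")),
            class = "nof1_reference_error")
    }
    if (!is.numeric(edges$weight) || anyNA(edges$weight)) {
      abort("Edge weights must be finite numbers.", class = "nof1_parse_error")
    }
    if (any(edges$lag < 0)) {
      abort("Edge lags must be >= 0.", class = "nof1_parse_error")
    }
  }
  if (length(g$treatment_effects) != 2) {
    abort("`treatment_effects` must have length 2.", class = "nof1_parse_error")
  }
  if (any(g$tau < 1) || any(g$gamma < 1)) {
    abort("Carry-over parameters `tau` and `gamma` must be >= 1.",
          class = "nof1_argument_error")
  }
  # acyclicity of the zero-lag subgraph (also detects and names a cycle)
  topological_order(g)
  g
}

#' Topological order of the zero-lag subgraph
#'
#' Kahn's algorithm on the instantaneous (`lag = 0`) edges, with lexicographic
#' tie-breaking so the order is deterministic for a fixed graph. Lagged edges
#' never constrain the within-day ordering (they refer to past days).
#'
#' @param graph A [causal_graph()].
#' @return Character vector of node names; every zero-lag edge points from an
#'   earlier to a later position.
#' @export
#' @examples
#' g <- causal_graph(
#'   nodes = data.frame(name = c("a", "b", "o"),
#'                      role = c("constant", "constant", "outcome")),
#'   edges = data.frame(from = c("a", "b"), to = c("b", "o"), weight = 1)
#' )
#' topological_order(g)
topological_order <- function(graph) {
  nodes <- sort(graph$nodes$name)
  e0 <- graph$edges[graph$edges$lag == 0L, , drop = FALSE]
  e0 <- e0[e0$from != "" & e0$to != "", , drop = FALSE]
  indeg <- setNames(integer(length(nodes)), nodes)
  if (nrow(e0)) {
    tab <- table(e0$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- nodes[indeg[nodes] == 0L]
  indeg_work <- indeg
  remaining_edges <- e0
  while (length(avail)) {
    nxt <- sort(avail)[1]
    avail <- setdiff(avail, nxt)
    out <- c(out, nxt)
    if (nrow(remaining_edges)) {
      children <- remaining_edges$to[remaining_edges$from == nxt]
      remaining_edges <- remaining_edges[remaining_edges$from != nxt, , drop = FALSE]
      for (ch in children) {
        indeg_work[ch] <- indeg_work[ch] - 1L
        if (indeg_work[ch] == 0L) avail <- c(avail, ch)
      }
    }
  }
  if (length(out) != length(nodes)) {
    cyc <- setdiff(nodes, out)
    abort(paste0("Cycle detected in the zero-lag subgraph involving: ",
                 paste(cyc, collapse = ", ")),
          class = "nof1_structure_error")
  }
  out
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("<causal_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  outcome:", x$nodes$name[x$nodes$role == "outcome"],
      "| treatment effects:", paste(x$treatment_effects, collapse = ", "), "\n")
  cat("  carry-over: tau =", paste(x$tau, collapse = ", "),
      "| gamma =", paste(x$gamma, collapse = ", "),
      "| activity modifier =", x$activity_modifier, "\n")
  invisible(x)
}

outcome_node <- function(graph) graph$nodes$name[graph$nodes$role == "outcome"]
treatment_node <- function(graph) graph$nodes$name[graph$nodes$role == "treatment"]
drift_node <- function(graph) graph$nodes$name[graph$nodes$role == "drift"]
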