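#' Parse a causal-graph configuration
#'
#' Reads the package's YAML/JSON graph schema (`schema: 1`) into a validated
#' [causal_graph()]. The schema holds a `nodes:` table, an `edges:` list, and
#' optional `treatment_effects`, `carry_over: {tau, gamma}` and
#' `activity_modifier: {weight, node, center}` blocks; see
#' `system.file("extdata", "backpain_graph.yaml", package = "nofonesim")` for
#' the packaged default. JSON input is accepted because the parser is a YAML
#' superset parser.
#'
#' @param x Path to a config file, or a single string holding the config text.
#' @return A validated [causal_graph()].
#' @seealso [parse_dagitty()] for plain edge-list import, [write_graph()] for
#'   the inverse operation.
#' @export
parse_graph <- function(x) {
  txt <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  cfg <- tryCatch(
    yaml::yaml.load(txt),
    error = function(e) abort(paste0("Malformed graph config: ", conditionMessage(e)),
                              class = "nof1_parse_error")
  )
  if (!is.list(cfg) || is.null(cfg$nodes)) {
    abort("Graph config must contain a `nodes:` table.", class = "nof1_parse_error")
  }
  num_or_na <- function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) return(NA_real_)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) abort("Malformed numeric value in graph config.",
                          class = "nof1_parse_error")
    out
  }
  nodes <- purrr::map_dfr(cfg$nodes, function(nd) {
    params <- nd$params %||% list(NA_real_, NA_real_)
    noise <- nd$noise %||% list()
    tibble::tibble(
      name = nd$name,
      role = nd$role %||% "time_varying",
      distribution = nd$distribution %||% NA_character_,
      param1 = num_or_na(params[[1]]),
      param2 = if (length(params) >= 2) num_or_na(params[[2]]) else NA_real_,
      threshold = num_or_na(nd$threshold),
      noise_mean = num_or_na(noise$mean),
      noise_sd = num_or_na(noise$sd)
    )
  })
  edges <- if (length(cfg$edges)) {
    purrr::map_dfr(cfg$edges, function(ed) {
      w <- suppressWarnings(as.numeric(ed$weight))
      if (is.null(ed$weight) || is.na(w)) {
        abort(paste0("Malformed or missing weight on edge ", ed$from, " -> ", ed$to),
              class = "nof1_parse_error")
      }
      tibble::tibble(from = ed$from, to = ed$to, weight = w,
                     lag = as.integer(ed$lag %||% 0L))
    })
  } else {
    NULL
  }
  co <- cfg$carry_over %||% list()
  am <- cfg$activity_modifier %||% list()
  causal_graph(
    nodes = nodes, edges = edges,
    treatment_effects = as.numeric(cfg$treatment_effects %||% c(-2, -4)),
    tau = as.numeric(co$tau %||% c(1, 1)),
    gamma = as.numeric(co$gamma %||% c(1, 1)),
    activity_modifier = as.numeric(am$weight %||% 0),
    modifier_node = am$node %||% "activity",
    modifier_center = as.numeric(am$center %||% 0)
  )
}

#' Import a DAGitty-style edge list
#'
#' Parses plain-text lines of the form `"from -> to"` (optionally with a
#' trailing weight, e.g. `"T -> O -2"`) together with a node table into a
#' [causal_graph()]. Edges without an explicit weight get weight 1.
#'
#' @param text Character vector of edge lines (or one newline-separated
#'   string). Blank lines and `#` comments are ignored.
#' @param nodes Node table as for [causal_graph()].
#' @param ... Passed on to [causal_graph()] (carry-over parameters etc.).
#' @return A validated [causal_graph()].
#' @export
#' @examples
#' parse_dagitty(
#'   c("T -> O -2"),
#'   nodes = data.frame(name = c("T", "O"), role = c("treatment", "outcome"))
#' )
parse_dagitty <- function(text, nodes, ...) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  edges <- purrr::map_dfr(lines, function(ln) {
    m <- regmatches(ln, regexec("^(\\S+)\\s*->\\s*(\\S+)\\s*(\\S+)?$", ln))[[1]]
    if (length(m) == 0) {
      abort(paste0("Cannot parse edge line: '", ln, "'"), class = "nof1_parse_error")
    }
    w <- if (is.na(m[4]) || m[4] == "") 1 else suppressWarnings(as.numeric(m[4]))
    if (is.na(w)) abort(paste0("Malformed weight in edge line: '", ln, "'"),
                        class = "nof1_parse_error")
    tibble::tibble(from = m[2], to = m[3], weight = w, lag = 0L)
  })
  causal_graph(nodes = nodes, edges = edges, ...)
}

#' Serialize a causal graph back to the YAML schema
#'
#' `write_graph(parse_graph(x))` round-trips: parsing the written file yields
#' an identical graph.
#'
#' @param graph A [causal_graph()].
#' @param path Output file path; if `NULL`, the YAML text is returned
#'   invisibly instead of written.
#' @return The YAML text, invisibly.
#' @export
write_graph <- function(graph, path = NULL) {
  drop_na <- function(l) l[!vapply(l, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  nodes <- purrr::pmap(graph$nodes, function(name, role, distribution, param1,
                                             param2, threshold, noise_mean, noise_sd) {
    drop_na(list(
      name = name, role = role, distribution = distribution,
      params = if (!is.na(param1) || !is.na(param2)) c(param1, param2) else NULL,
      threshold = threshold,
      noise = if (!is.na(noise_mean) || !is.na(noise_sd)) {
        drop_na(list(mean = noise_mean, sd = noise_sd))
      } else NULL
    ))
  })
  edges <- purrr::pmap(graph$edges, function(from, to, weight, lag) {
    out <- list(from = from, to = to, weight = weight)
    if (lag != 0L) out$lag <- lag
    out
  })
  cfg <- list(
    schema = 1L,
    treatment_effects = graph$treatment_effects,
    carry_over = list(tau = graph$tau, gamma = graph$gamma),
    activity_modifier = list(weight = graph$activity_modifier,
                             node = graph$modifier_node,
                             center = graph$modifier_center),
    nodes = nodes,
    edges = edges
  )
  txt <- yaml::as.yaml(cfg, precision = 15)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' The default chronic low back pain study graph
#'
#' The packaged causal graph for the simulated multi-crossover study on
#' chronic nonspecific low back pain: twelve nodes (demographics, education,
#' work, previous diagnosis, chronic diseases, medication, activity, stress,
#' quality of sleep, treatment, pain, and the underlying state) with
#' moderate nonzero weights on all drawn edges and treatment effects on pain
#' fixed at -2 (treatment 1) and -4 (treatment 2). The file behind it is
#' `inst/extdata/backpain_graph.yaml`; carry-over and interaction parameters
#' are overridden per scenario by [scenario_graph()].
#'
#' @return A validated [causal_graph()].
#' @export
default_backpain_graph <- function() {
  parse_graph(system.file("extdata", "backpain_graph.yaml",
                          package = "nofonesim", mustWork = TRUE))
}
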