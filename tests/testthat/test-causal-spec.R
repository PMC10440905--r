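test_that("a minimal edge-list graph parses with its weight", {
  g <- parse_dagitty(
    "T -> O -2",
    nodes = data.frame(name = c("T", "O"), role = c("treatment", "outcome"))
  )
  expect_s3_class(g, "causal_graph")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, -2)
  expect_equal(g$edges$lag, 0L)
})

test_that("the packaged study graph has the expected nodes and wiring", {
  g <- default_backpain_graph()
  expect_setequal(
    g$nodes$name,
    c("demographics", "education", "work", "prev_diagnosis",
      "chronic_diseases", "medication", "activity", "stress",
      "quality_sleep", "treatment", "pain", "underlying_state")
  )
  expect_equal(nrow(g$nodes), 12)
  expect_equal(g$treatment_effects, c(-2, -4))
  has_edge <- function(from, to) {
    any(g$edges$from == from & g$edges$to == to)
  }
  for (child in c("education", "work", "activity", "prev_diagnosis",
                  "medication", "chronic_diseases")) {
    expect_true(has_edge("demographics", child), label = child)
  }
  expect_true(has_edge("treatment", "stress"))
  expect_true(has_edge("treatment", "quality_sleep"))
  expect_false(has_edge("demographics", "pain")) # only indirect paths
  for (parent in backpain_covariates()) {
    expect_true(has_edge(parent, "pain"), label = parent)
  }
})

test_that("structural validation rejects bad configs", {
  nodes <- data.frame(name = c("a", "o"), role = c("constant", "outcome"))
  # self-loop at lag 0
  expect_error(
    causal_graph(nodes, data.frame(from = "o", to = "o", weight = 1)),
    class = "nof1_structure_error"
  )
  # two-node cycle, error names the nodes involved
  err <- expect_error(
    causal_graph(nodes, data.frame(from = c("a", "o"), to = c("o", "a"),
                                   weight = 1)),
    class = "nof1_structure_error"
  )
  expect_match(conditionMessage(err), "a.*o|o.*a")
  # undeclared node
  expect_error(
    causal_graph(nodes, data.frame(from = "ghost", to = "o", weight = 1)),
    class = "nof1_reference_error"
  )
  # negative noise variance
  bad <- data.frame(name = c("a", "o"), role = c("constant", "outcome"),
                    noise_sd = c(-1, 0))
  expect_error(causal_graph(bad, NULL), class = "nof1_parse_error")
  # malformed weight in YAML
  expect_error(
    parse_graph(paste(
      "nodes:",
      "  - {name: a, role: constant, distribution: gaussian, params: [0, 1]}",
      "  - {name: o, role: outcome, noise: {mean: 0, sd: 1}}",
      "edges:",
      "  - {from: a, to: o, weight: wat}",
      sep = "\n"
    )),
    class = "nof1_parse_error"
  )
  # carry-over below 1
  expect_error(causal_graph(nodes, NULL, tau = c(0.5, 1)),
               class = "nof1_argument_error")
})

test_that("topological order respects zero-lag edges deterministically", {
  g <- causal_graph(
    nodes = data.frame(name = c("a", "b", "c"),
                       role = c("constant", "constant", "outcome")),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1)
  )
  expect_equal(topological_order(g), c("a", "b", "c"))

  gd <- default_backpain_graph()
  ord <- topological_order(gd)
  expect_lt(match("demographics", ord), match("activity", ord))
  expect_lt(match("treatment", ord), match("pain", ord))
  # brute force: no zero-lag edge points backwards
  e0 <- gd$edges[gd$edges$lag == 0, ]
  expect_true(all(match(e0$from, ord) < match(e0$to, ord)))

  # with no edges, all nodes appear (lexicographically)
  g0 <- causal_graph(data.frame(name = c("z", "o"),
                                role = c("constant", "outcome")), NULL)
  expect_equal(topological_order(g0), c("o", "z"))
})

test_that("graph configs round-trip through serialization", {
  g <- default_backpain_graph()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_graph(g, path)
  g2 <- parse_graph(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$treatment_effects, g$treatment_effects)
  expect_equal(g2$tau, g$tau)
  expect_equal(g2$gamma, g$gamma)
  expect_equal(g2$activity_modifier, g$activity_modifier)
})

test_that("scenario configs map onto the four study cells", {
  s1 <- scenario_config(1)
  expect_equal(s1$tau, c(1, 1))
  expect_equal(s1$gamma, c(1, 1))
  expect_identical(s1$activity_modifier, 0)

  s2 <- scenario_config(2)
  expect_equal(s2$tau, c(6, 5))
  expect_equal(s2$gamma, c(3, 4))
  expect_identical(s2$activity_modifier, 0)

  s3 <- scenario_config(3)
  expect_equal(s3$tau, c(1, 1))
  expect_true(s3$activity_modifier != 0)

  s4 <- scenario_config(4, period_length = 7)
  expect_equal(s4$tau, c(6, 5))
  expect_equal(s4$gamma, c(3, 4))
  expect_true(s4$activity_modifier != 0)
  expect_equal(s4$period_length, 7)

  # bijection onto the table's cells
  flags <- vapply(1:4, function(s) {
    cfg <- scenario_config(s)
    paste(cfg$carry_over, cfg$activity_interaction)
  }, character(1))
  expect_equal(sort(flags), sort(c("FALSE FALSE", "TRUE FALSE",
                                   "FALSE TRUE", "TRUE TRUE")))

  expect_error(scenario_config(5), class = "nof1_argument_error")
  expect_error(scenario_config(2, nonsense = 1), class = "nof1_argument_error")
})

test_that("scenario graphs carry the right carry-over and lag switches", {
  g1 <- scenario_graph(scenario_config(1))
  expect_equal(g1$tau, c(1, 1))
  expect_false(any(g1$edges$lag > 0))
  expect_identical(g1$activity_modifier, 0)

  g4 <- scenario_graph(scenario_config(4))
  expect_equal(g4$tau, c(6, 5))
  expect_true(any(g4$edges$lag > 0 & g4$edges$to == "activity"))
  expect_true(any(g4$edges$lag > 0 & g4$edges$to == "quality_sleep"))
  expect_true(g4$activity_modifier != 0)
  # modifier centring uses the long-run mean of the lagged treatment indicator
  lag_w <- g4$edges$weight[g4$edges$lag > 0 & g4$edges$to == "activity"]
  expect_equal(g4$modifier_center, 0.5 * sum(lag_w))
})
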