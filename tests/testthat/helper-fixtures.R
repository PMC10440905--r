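# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# minimal two-node graph: treatment and outcome only, baseline 6, no noise
tiny_graph <- function(effects = c(-2, -4), tau = c(1, 1), gamma = c(1, 1),
                       noise_sd = 0, baseline = 6) {
  causal_graph(
    nodes = data.frame(
      name = c("treatment", "pain"),
      role = c("treatment", "outcome"),
      noise_mean = c(NA, baseline),
      noise_sd = c(NA, noise_sd)
    ),
    edges = NULL,
    treatment_effects = effects, tau = tau, gamma = gamma
  )
}

# the full study graph with every noise source silenced (constants become
# deterministic threshold values, drift flat), for exactness checks
noisefree_backpain_graph <- function(config) {
  g <- scenario_graph(config)
  g$nodes$noise_sd[!is.na(g$nodes$noise_sd)] <- 0
  drift <- g$nodes$role == "drift"
  g$nodes$param1[drift] <- 0
  g$nodes$param2[drift] <- 0
  exo <- g$nodes$role == "constant" & !is.na(g$nodes$distribution)
  g$nodes$param2[exo] <- 0
  g
}

# fixed (non-randomized) design helper
fixed_design <- function(treatments, period_length = 1L) {
  n <- length(treatments) * period_length
  tibble::tibble(
    day = seq_len(n),
    block = rep(1L, n),
    period = rep(seq_along(treatments), each = period_length),
    treatment = rep(as.integer(treatments), each = period_length)
  )
}

# small pooled trial table built by hand
toy_trial <- function(treatment, pain, patient_id = NULL, ...) {
  n <- max(length(pain), length(treatment), length(patient_id))
  pid <- patient_id %||% rep(1L, n)
  tibble::tibble(
    patient_id = pid,
    day = stats::ave(seq_len(n), pid, FUN = seq_along),
    treatment = rep_len(as.integer(treatment), n),
    pain = rep_len(as.numeric(pain), n),
    missing = FALSE,
    ...
  )
}

`%||%` <- rlang::`%||%`
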