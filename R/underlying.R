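#' Simulate the underlying state (baseline drift)
#'
#' The untreated course of the outcome is modelled as a discrete-time Wiener
#' process with drift: \eqn{U^t = U^{t-1} + N(\mu, \sigma^2)} with fixed
#' \eqn{U^0} (default 0). The drift mean captures a systematic time trend;
#' the innovation standard deviation captures day-to-day random wandering of
#' the untreated pain level.
#'
#' @param n_days Number of days to simulate.
#' @param drift_mean Per-day drift mean \eqn{\mu}.
#' @param innovation_sd Per-day innovation standard deviation
#'   \eqn{\sigma \ge 0}.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param u0 Starting value \eqn{U^0}.
#' @return Numeric vector of length `n_days + 1`: \eqn{U^0, \dots,
#'   U^{n_{days}}}.
#' @export
#' @examples
#' simulate_underlying_state(10, drift_mean = 0.1, innovation_sd = 0, seed = 1)
simulate_underlying_state <- function(n_days, drift_mean = 0,
                                      innovation_sd = 0.05,
                                      seed = NULL, u0 = 0) {
  if (innovation_sd < 0) {
    abort("`innovation_sd` must be >= 0.", class = "nof1_argument_error")
  }
  draw <- function() rnorm(n_days, mean = drift_mean, sd = innovation_sd)
  inc <- if (is.null(seed)) draw() else with_seed(seed, draw())
  c(u0, u0 + cumsum(inc))
}
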