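#' Exponential-decay treatment exposure indicator
#'
#' The carry-over model replaces the binary treatment indicator
#' \eqn{T_k^t \in \{0,1\}} with a continuous exposure \eqn{E_k^t \in [0,1]}
#' that washes in towards 1 while the treatment is given and washes out
#' towards 0 while it is not:
#' \deqn{E_k^t = E_k^{t-1} + \frac{1 - E_k^{t-1}}{\tau_k} T_k^t
#'       - \frac{E_k^{t-1}}{\gamma_k} (1 - T_k^t),}
#' with \eqn{E_k^0 = 0} (no treatment effect at the start of the study).
#' `tau` (wash-in) and `gamma` (wash-out) must both be at least 1, otherwise
#' the recursion would overshoot \eqn{[0,1]}. With `tau = gamma = 1` the
#' exposure equals the binary indicator from day 1 on. Under sustained
#' treatment, \eqn{1 - E_k^t = (1 - 1/\tau_k)^t} in closed form.
#'
#' @param treatment Binary vector (`0`/`1`): was treatment `k` given on each
#'   day.
#' @param tau Wash-in parameter, `>= 1`.
#' @param gamma Wash-out parameter, `>= 1`.
#' @param init Initial exposure `E_k^0`, default 0.
#' @return Numeric vector of length `length(treatment) + 1`: the exposure at
#'   `t = 0, 1, ..., n`.
#' @export
#' @examples
#' exposure_decay(c(1, 1, 1), tau = 2, gamma = 1) # 0, 1/2, 3/4, 7/8
exposure_decay <- function(treatment, tau, gamma, init = 0) {
  if (tau < 1 || gamma < 1) {
    abort("`tau` and `gamma` must both be >= 1.", class = "nof1_argument_error")
  }
  treatment <- as.numeric(treatment)
  if (anyNA(treatment) || !all(treatment %in% c(0, 1))) {
    abort("`treatment` must be a binary 0/1 vector without NA.",
          class = "nof1_argument_error")
  }
  if (init < 0 || init > 1) {
    abort("`init` must lie in [0, 1].", class = "nof1_argument_error")
  }
  n <- length(treatment)
  e <- numeric(n + 1)
  e[1] <- init
  for (t in seq_len(n)) {
    prev <- e[t]
    e[t + 1] <- prev + (1 - prev) / tau * treatment[t] -
      prev / gamma * (1 - treatment[t])
  }
  e
}
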