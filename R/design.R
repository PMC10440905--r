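#' Randomize a crossover design for one patient
#'
#' Builds the day-indexed treatment schedule: `blocks` treatment blocks,
#' each holding one period of treatment 1 and one of treatment 2 in an order
#' drawn uniformly from \{AB, BA\} (A = treatment 1). The default 2 blocks of
#' two 4-week periods give schedules such as ABBA or ABAB over 112 days.
#'
#' @param config A [scenario_config()] (fields `blocks`, `period_length`),
#'   or `NULL` to use the defaults.
#' @param seed Integer seed for the block-order randomization.
#' @param blocks,period_length Direct design parameters, overriding `config`.
#' @return A tibble with one row per day: `day`, `block`, `period`
#'   (1..2*blocks), `treatment` (integer 1 or 2).
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d) # 112
#' table(d$treatment)
generate_design <- function(config = NULL, seed = 1L,
                            blocks = NULL, period_length = NULL) {
  blocks <- blocks %||% (config$blocks %||% 2L)
  period_length <- period_length %||% (config$period_length %||% 28L)
  if (blocks < 1 || period_length < 1) {
    abort("`blocks` and `period_length` must be positive.",
          class = "nof1_argument_error")
  }
  blocks <- as.integer(blocks)
  period_length <- as.integer(period_length)
  orders <- with_seed(seed, sample(c(TRUE, FALSE), blocks, replace = TRUE))
  per_block <- purrr::map(seq_len(blocks), function(b) {
    trts <- if (orders[b]) c(1L, 2L) else c(2L, 1L)
    rep(trts, each = period_length)
  })
  treatment <- unlist(per_block)
  n_days <- blocks * 2L * period_length
  tibble::tibble(
    day = seq_len(n_days),
    block = rep(seq_len(blocks), each = 2L * period_length),
    period = rep(seq_len(2L * blocks), each = period_length),
    treatment = treatment
  )
}
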