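#' Apply participant drop-out to a cohort
#'
#' Marks patient-days missing through two mechanisms, applied row-wise
#' (a missing day hides all of that day's time-varying measurements):
#'
#' 1. *Random drop-out*: each day `t` of an `n`-day record is deleted
#'    independently with probability increasing linearly in time,
#'    `p_t = 2 * rate * t / (n + 1)`, calibrated so the expected deleted
#'    fraction equals `rate` (default 10%).
#' 2. *Vacation*: one block of exactly `block_length` (default 10)
#'    consecutive days per patient, with a uniformly drawn start day.
#'
#' The underlying data are retained; only the logical `missing` mask is set.
#' Analysis functions drop masked rows (complete-case), while the treatment
#' schedule columns remain usable because they are fixed by design.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param seed Integer seed.
#' @param rate Target expected fraction of days deleted by mechanism 1; 0
#'   disables it.
#' @param block_length Length of the consecutive missing block; 0 or
#'   `vacation = FALSE` disables mechanism 2.
#' @param dropout,vacation Logical switches for the two mechanisms.
#' @return The cohort with its `missing` column updated.
#' @export
apply_missingness <- function(cohort, seed = 1L, rate = 0.1,
                              block_length = 10L,
                              dropout = TRUE, vacation = TRUE) {
  stopifnot(is.data.frame(cohort), "missing" %in% names(cohort))
  if (rate < 0 || rate >= 1) {
    abort("`rate` must lie in [0, 1).", class = "nof1_argument_error")
  }
  at <- attributes(cohort)
  ids <- unique(cohort$patient_id)
  pieces <- purrr::map(ids, function(pid) {
    rows <- cohort[cohort$patient_id == pid, , drop = FALSE]
    rows <- rows[order(rows$day), , drop = FALSE]
    n <- nrow(rows)
    with_seed(derive_seed(seed, pid), {
      mask <- rep(FALSE, n)
      if (dropout && rate > 0) {
        p <- 2 * rate * seq_len(n) / (n + 1)
        mask <- runif(n) < p
      }
      if (vacation && block_length > 0) {
        if (n < block_length) {
          abort(paste0("Patient ", pid, " has fewer than ", block_length,
                       " days; cannot place the consecutive missing block."),
                class = "nof1_argument_error")
        }
        start <- sample.int(n - block_length + 1L, 1L)
        mask[start:(start + block_length - 1L)] <- TRUE
      }
      rows$missing <- rows$missing | mask
    })
    rows
  })
  out <- dplyr::bind_rows(pieces)
  new_cohort(out, config = at$config, graph = at$graph, seed = at$seed)
}
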