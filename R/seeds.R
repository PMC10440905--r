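#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Sub-streams (per patient, per Monte-Carlo replicate, per mechanism) use
#' seeds derived deterministically from the master seed and a set of integer
#' indices through a splitmix-style integer hash, so that streams are
#' decoupled: patient 2 of seed 1 shares no prefix with patient 1 of seed 2.
#' Results always lie in `[0, 2^31 - 2]`, valid R RNG seeds.
#'
#' @param seed Integer master seed.
#' @param ... Further integer indices identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 5)
#' derive_seed(1, 5, 2)
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(length(idx) >= 1, all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, Lehmer modulus
  # multipliers kept small enough that every product is exact in a double
  h <- 17
  for (x in as.double(idx)) {
    h <- (h * 48271 + (x %% m) * 16807 + 1) %% m
    h <- (h * 48271 + 12345) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
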