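#' G-estimation of the treatment effect difference
#'
#' Estimates the average treatment effect difference in a structural nested
#' mean model. Because every study day is under one of the two treatments
#' (there are no untreated days in the crossover design), the treatment is
#' coded as a binary contrast `T = 1` for treatment 2 and `T = 0` for
#' treatment 1, so the structural parameter \eqn{\psi} is directly the
#' average effect of treatment 2 versus treatment 1 (truth -2 in the
#' simulated study). For a candidate \eqn{\psi} the residualised outcome
#' \eqn{H(\psi) = O - \psi T} is formed and the propensity model
#' \deqn{logit P(T = 1 \mid H(\psi), C) = \theta_0 + \theta_1 H(\psi)
#'   + \sum_j \theta_{2,j} C_j}
#' is fitted by [gee_logistic()] with the requested working correlation.
#' Under conditional exchangeability \eqn{\theta_1 = 0} at the true
#' \eqn{\psi}; the estimate is the root of \eqn{\theta_1(\psi)} found by
#' Brent's method over `interval`, with a fine grid scan (step 0.01) as a
#' fallback when the interval does not bracket a sign change. The reported
#' `estimate` is \eqn{-\hat\psi}, oriented to the package convention
#' (truth +2).
#'
#' @inheritParams linear_model_estimate
#' @param correlation Working correlation for the propensity GEE:
#'   `"independence"` or `"ar1"`.
#' @param interval Search interval for \eqn{\psi}.
#' @param tol Tolerance on \eqn{|\theta_1|} at the solution.
#' @return An object of classes `gest_fit` and `nof1_estimate`; `details`
#'   holds `psi`, `theta1_abs`, `correlation`, `alpha`. The SE is `NA`:
#'   the Monte-Carlo layer supplies the empirical one.
#' @export
g_estimate <- function(data, covariates = backpain_covariates(),
                       correlation = c("independence", "ar1"),
                       interval = c(-10, 10), tol = 1e-4,
                       outcome = "pain") {
  correlation <- match.arg(correlation)
  covariates <- intersect(covariates, names(data))
  cc <- complete_cases(data, outcome, covariates)
  cc <- cc[order(cc$patient_id, cc$day), , drop = FALSE]
  if (!nrow(cc)) abort("No complete-case rows.", class = "nof1_estimation_error")
  cc$..t <- as.numeric(cc$treatment == 2)
  rhs <- paste(c("..h", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("..t ~", rhs))
  last_fit <- NULL
  theta1 <- function(psi) {
    cc$..h <- cc[[outcome]] - psi * cc$..t
    fit <- gee_logistic(cc, fml, id = "patient_id", correlation = correlation)
    last_fit <<- fit
    unname(coef(fit)[["..h"]])
  }
  # At extreme psi the term psi * T dominates H and separates the propensity
  # fit; probe the interval on a coarse grid, treating failed fits as
  # unusable, and bracket the sign change among the finite evaluations.
  safe_theta1 <- function(psi) {
    tryCatch(theta1(psi), nof1_estimation_error = function(e) NA_real_)
  }
  probes <- sort(unique(c(interval, seq(interval[1], interval[2], length.out = 17))))
  vals <- vapply(probes, safe_theta1, numeric(1))
  fin <- which(is.finite(vals))
  bracket <- NULL
  for (j in seq_along(fin)[-1]) {
    a <- fin[j - 1]; b <- fin[j]
    if (vals[a] * vals[b] <= 0) { bracket <- c(a, b); break }
  }
  if (!is.null(bracket)) {
    root <- uniroot(theta1, interval = probes[bracket],
                    f.lower = vals[bracket[1]], f.upper = vals[bracket[2]],
                    tol = 1e-6)
    psi <- root$root
    iterations <- root$iter
  } else if (length(fin)) {
    warn("No sign change of theta1 over the interval; falling back to a grid scan. Consider widening `interval`.")
    grid <- seq(probes[min(fin)], probes[max(fin)], by = 0.01)
    gvals <- vapply(grid, function(p) abs(safe_theta1(p)), numeric(1))
    psi <- grid[which.min(gvals)]
    iterations <- length(grid)
  } else {
    abort("Propensity model failed over the whole search interval.",
          class = "nof1_estimation_error")
  }
  t1 <- theta1(psi)
  if (abs(t1) > tol) {
    abort(paste0("G-estimation did not reach |theta1| <= ", tol,
                 " (got ", format(abs(t1)), "); widen `interval` or the grid."),
          class = "nof1_estimation_error")
  }
  new_estimate(
    paste0("gest_", if (correlation == "ar1") "ar1" else "ind"),
    estimate = -psi,
    coefficients = coef(last_fit),
    details = list(psi = psi, theta1_abs = abs(t1),
                   correlation = correlation, alpha = last_fit$alpha,
                   iterations = iterations),
    n_patients = dplyr::n_distinct(cc$patient_id), n_obs = nrow(cc),
    subclass = "gest_fit"
  )
}
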