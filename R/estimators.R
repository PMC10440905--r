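#' @title Estimate objects
#' @description All estimators return an `nof1_estimate`: the method's point
#'   estimate of the treatment effect *difference* on the outcome scale,
#'   oriented by the package-wide sign convention — positive when treatment 2
#'   lowers the outcome more than treatment 1, so the simulated truth is +2 —
#'   plus a model-based standard error where the method provides one.
#' @name nof1_estimate
#' @keywords internal
NULL

new_estimate <- function(method, estimate, se = NA_real_,
                         coefficients = NULL, details = list(),
                         n_patients = NA_integer_, n_obs = NA_integer_,
                         subclass = character()) {
  stopifnot(is.na(se) || se >= 0)
  structure(
    list(method = method, estimate = as.numeric(estimate),
         se = as.numeric(se), coefficients = coefficients,
         details = details, n_patients = n_patients, n_obs = n_obs),
    class = c(subclass, "nof1_estimate")
  )
}

#' @export
print.nof1_estimate <- function(x, ...) {
  cat("<nof1_estimate>", x$method, "\n")
  cat("  effect difference:", format(x$estimate, digits = 4),
      if (!is.na(x$se)) paste0("(SE ", format(x$se, digits = 3), ")") else "(no model SE)",
      "\n")
  cat("  patients:", x$n_patients, "| observations:", x$n_obs, "\n")
  invisible(x)
}

#' @describeIn nof1_estimate One-row tibble with `method`, `estimate`, `se`.
#' @param x An `nof1_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nof1_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate, se = x$se)
}

#' @describeIn nof1_estimate One-row tibble adding sample sizes and any
#'   method-specific diagnostics.
#' @exportS3Method generics::glance
glance.nof1_estimate <- function(x, ...) {
  extra <- x$details[vapply(x$details, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  base <- tibble::tibble(method = x$method, estimate = x$estimate, se = x$se,
                         n_patients = x$n_patients, n_obs = x$n_obs)
  if (length(extra)) dplyr::bind_cols(base, tibble::as_tibble(extra)) else base
}

#' Default covariate adjustment set
#'
#' The covariates with direct effects on the pain outcome in the study
#' graph — activity, stress, quality of sleep, medication, previous
#' diagnosis, chronic diseases, education, work — excluding demographics,
#' which acts only through these proxies.
#'
#' @return Character vector of column names.
#' @export
backpain_covariates <- function() {
  c("activity", "stress", "quality_sleep", "medication",
    "prev_diagnosis", "chronic_diseases", "education", "work")
}

complete_cases <- function(data, outcome, cols = character()) {
  keep <- !data$missing & !is.na(data[[outcome]])
  for (cl in cols) keep <- keep & !is.na(data[[cl]])
  data[keep, , drop = FALSE]
}

#' Naive sample-mean contrast
#'
#' The simplest estimator: the difference of the mean outcome across all
#' treatment-1 days and all treatment-2 days, pooled over patients, after
#' dropping masked days. No covariate adjustment and no model-based SE (the
#' Monte-Carlo harness supplies the empirical one).
#'
#' @param data A long trial tibble (see [simulate_cohort()]) with columns
#'   `treatment`, the outcome, and `missing`.
#' @param outcome Outcome column name, default `"pain"`.
#' @return An `nof1_estimate`.
#' @export
#' @examples
#' cfg <- scenario_config(1, n_population = 4)
#' co <- simulate_cohort(cfg, seed = 1)
#' tidy(sample_mean_estimate(co))
sample_mean_estimate <- function(data, outcome = "pain") {
  cc <- complete_cases(data, outcome)
  o1 <- cc[[outcome]][cc$treatment == 1]
  o2 <- cc[[outcome]][cc$treatment == 2]
  if (!length(o1) || !length(o2)) {
    abort("Both treatment groups must be non-empty after dropping missing days.",
          class = "nof1_estimation_error")
  }
  new_estimate(
    "sample_mean", estimate = mean(o1) - mean(o2),
    n_patients = dplyr::n_distinct(cc$patient_id), n_obs = nrow(cc)
  )
}

#' Covariate-adjusted linear model
#'
#' Pooled ordinary least squares of the outcome on a treatment-2 indicator
#' and the adjustment covariates, assuming independence between
#' observations (within and between patients). The coefficient on the
#' indicator estimates the average direct effect of treatment 2 versus
#' treatment 1; it is sign-flipped to the package convention.
#'
#' @inheritParams sample_mean_estimate
#' @param covariates Covariate column names; defaults to
#'   [backpain_covariates()] intersected with the data's columns.
#' @return An `nof1_estimate` with the model-based SE of the contrast.
#' @export
linear_model_estimate <- function(data, covariates = backpain_covariates(),
                                  outcome = "pain") {
  covariates <- intersect(covariates, names(data))
  cc <- complete_cases(data, outcome, covariates)
  if (!nrow(cc)) abort("No complete-case rows.", class = "nof1_estimation_error")
  X <- cbind(`(Intercept)` = 1, treatment2 = as.numeric(cc$treatment == 2),
             as.matrix(cc[, covariates, drop = FALSE]))
  check_full_rank(X)
  fit <- lm(cc[[outcome]] ~ X - 1)
  b <- coef(fit)
  se <- sqrt(diag(vcov_lm(fit)))
  names(b) <- names(se) <- colnames(X)
  new_estimate(
    "lm", estimate = -b[["treatment2"]], se = se[["treatment2"]],
    coefficients = b,
    details = list(r_squared = 1 - sum(residuals(fit)^2) /
                     sum((cc[[outcome]] - mean(cc[[outcome]]))^2)),
    n_patients = dplyr::n_distinct(cc$patient_id), n_obs = nrow(cc)
  )
}

vcov_lm <- function(fit) {
  s <- summary(fit)
  s$sigma^2 * s$cov.unscaled
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "nof1_estimation_error")
  }
  invisible(TRUE)
}
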