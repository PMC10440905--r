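#' Build the carry-over adjusted regression table
#'
#' Replaces the binary treatment indicator with the two continuous exposure
#' columns `e1`, `e2` of [exposure_decay()], computed per patient over the
#' patient's full day-ordered treatment sequence. By default the recursion
#' evolves *through* masked days — the treatment schedule is a design
#' quantity known even when measurements are missing — and only the masked
#' rows are later excluded from the regression.
#'
#' @param data A long trial tibble with `patient_id`, `day`, `treatment`,
#'   `missing`.
#' @param tau1,gamma1,tau2,gamma2 Wash-in/wash-out parameters (`>= 1`) for
#'   treatments 1 and 2.
#' @param evolve_through_missing If `FALSE`, masked rows are removed before
#'   the recursion, so exposure evolves over observed days only.
#' @return The input tibble, day-ordered within patient, with columns `e1`
#'   and `e2` appended.
#' @export
coapm_design <- function(data, tau1, gamma1, tau2, gamma2,
                         evolve_through_missing = TRUE) {
  if (!evolve_through_missing) data <- data[!data$missing, , drop = FALSE]
  data <- data[order(data$patient_id, data$day), , drop = FALSE]
  if (anyNA(data$treatment)) {
    abort(paste0("Treatment is NA on some rows; the exposure recursion needs ",
                 "the full schedule (or set `evolve_through_missing = FALSE` ",
                 "after dropping those rows)."),
          class = "nof1_argument_error")
  }
  e <- lapply(split(data$treatment, data$patient_id), function(trt) {
    list(e1 = exposure_decay((trt == 1) * 1, tau1, gamma1)[-1],
         e2 = exposure_decay((trt == 2) * 1, tau2, gamma2)[-1])
  })
  ord <- as.character(unique(data$patient_id))
  data$e1 <- unlist(lapply(e[ord], `[[`, "e1"), use.names = FALSE)
  data$e2 <- unlist(lapply(e[ord], `[[`, "e2"), use.names = FALSE)
  data
}

#' COAPM: carry-over adjusted parametric model
#'
#' Fits the linear model
#' \deqn{O^t = \beta_0 + \beta_1 E_1^t(\tau_1, \gamma_1)
#'   + \beta_2 E_2^t(\tau_2, \gamma_2) + \sum_j \beta_{3,j} C_j^t + \epsilon}
#' by OLS at candidate wash-in/wash-out parameters and selects the
#' parameters with the highest \eqn{R^2}; \eqn{\hat\beta_1 - \hat\beta_2} is
#' then the carry-over adjusted estimate of the treatment effect difference,
#' and \eqn{\hat\beta_1}, \eqn{\hat\beta_2} estimate each treatment's effect
#' versus no treatment. Ties in \eqn{R^2} break toward the lexicographically
#' smallest \eqn{(\tau_1, \gamma_1, \tau_2, \gamma_2)}; candidate fits with
#' rank-deficient designs (notably \eqn{\tau = \gamma = 1} for both
#' treatments, where \eqn{E_1 + E_2 = 1} is collinear with the intercept)
#' are skipped.
#'
#' The full 4-dimensional integer grid `1..grid_max` per parameter is
#' scanned by default; after partialling the fixed covariate block out of
#' the outcome and the candidate exposure columns (Frisch-Waugh-Lovell),
#' each candidate costs only a bivariate regression, so the joint scan is
#' desk-scale. `joint = FALSE` instead sweeps the \eqn{(\tau_1, \gamma_1)}
#' and \eqn{(\tau_2, \gamma_2)} planes coordinate-wise (at most
#' `max_sweeps` sweeps), which is faster for very large `grid_max` but can
#' stall in a local optimum of the \eqn{R^2} surface.
#'
#' @inheritParams linear_model_estimate
#' @inheritParams coapm_design
#' @param grid_max Largest integer wash-in/wash-out value searched.
#' @param joint Search the full joint grid (default) instead of
#'   coordinate sweeps.
#' @param max_sweeps Maximum coordinate sweeps when `joint = FALSE`.
#' @return An object of classes `coapm_fit` and `nof1_estimate`; `estimate`
#'   is \eqn{\hat\beta_1 - \hat\beta_2} (truth +2 under the study's
#'   convention), `se` its model-based standard error from the selected fit,
#'   and `details` holds `tau1`, `gamma1`, `tau2`, `gamma2`, `r_squared`,
#'   `beta1`, `beta2`, `se_beta1`, `se_beta2`, `sweeps`.
#' @export
coapm_grid_search <- function(data, covariates = backpain_covariates(),
                              outcome = "pain", grid_max = 10L,
                              joint = TRUE, max_sweeps = 5L,
                              evolve_through_missing = TRUE) {
  covariates <- intersect(covariates, names(data))
  data <- data[order(data$patient_id, data$day), , drop = FALSE]
  keep <- !data$missing & !is.na(data[[outcome]])
  for (cl in covariates) keep <- keep & !is.na(data[[cl]])
  if (!any(keep)) abort("No complete-case rows.", class = "nof1_estimation_error")

  y <- data[[outcome]][keep]
  Xc <- cbind(`(Intercept)` = 1, as.matrix(data[keep, covariates, drop = FALSE]))
  tss <- sum((y - mean(y))^2)

  # exposure-column library: one matrix column pair per (tau, gamma) cell,
  # shared by every candidate evaluation
  if (!evolve_through_missing) {
    work <- data[keep, , drop = FALSE]
    keep_w <- rep(TRUE, nrow(work))
  } else {
    work <- data
    keep_w <- keep
  }
  if (anyNA(work$treatment)) {
    abort("Treatment is NA on some rows; cannot evolve exposure through them.",
          class = "nof1_argument_error")
  }
  trt_split <- split(work$treatment, factor(work$patient_id,
                                            levels = unique(work$patient_id)))
  lengths_equal <- length(unique(lengths(trt_split))) == 1
  grid <- expand.grid(gamma = seq_len(grid_max), tau = seq_len(grid_max))
  grid <- grid[order(grid$tau, grid$gamma), , drop = FALSE] # lexicographic (tau, gamma)
  e_lib <- function(k) {
    if (lengths_equal) {
      tm <- matrix(unlist(trt_split, use.names = FALSE),
                   nrow = length(trt_split[[1]]))
      tk <- (tm == k) * 1
      lapply(seq_len(nrow(grid)), function(i) {
        ek <- exposure_col_matrix(tk, grid$tau[i], grid$gamma[i])
        as.vector(ek)[keep_w]
      })
    } else {
      lapply(seq_len(nrow(grid)), function(i) {
        unlist(lapply(trt_split, function(trt) {
          exposure_decay((trt == k) * 1, grid$tau[i], grid$gamma[i])[-1]
        }), use.names = FALSE)[keep_w]
      })
    }
  }
  lib1 <- e_lib(1)
  lib2 <- e_lib(2)

  # Frisch-Waugh-Lovell: project the fixed block (intercept + covariates)
  # out of y and out of every candidate exposure column once; each candidate
  # then reduces to a 2-column regression with identical RSS.
  check_full_rank(Xc)
  qx <- qr(Xc)
  ry <- qr.resid(qx, y)
  rmat1 <- qr.resid(qx, do.call(cbind, lib1))
  rmat2 <- qr.resid(qx, do.call(cbind, lib2))
  ry2 <- sum(ry^2)
  # all candidate pairs at once: RSS(i1, i2) from the 2x2 normal equations
  # of the partialled exposure columns
  G11 <- colSums(rmat1^2)
  G22 <- colSums(rmat2^2)
  G12 <- crossprod(rmat1, rmat2)
  U1 <- drop(crossprod(rmat1, ry))
  U2 <- drop(crossprod(rmat2, ry))
  DET <- outer(G11, G22) - G12^2
  EXPL <- (outer(U1^2, G22) - 2 * G12 * outer(U1, U2) + outer(G11, U2^2)) / DET
  RSS <- ry2 - EXPL
  deficient <- !is.finite(DET) | DET <= 1e-10 * pmax(outer(G11, G22), 1e-300)
  RSS[deficient] <- Inf
  rss_of <- function(i1, i2) RSS[i1, i2]

  best <- list(i1 = 1L, i2 = 1L, rss = Inf)
  if (joint) {
    m <- min(RSS)
    if (is.finite(m)) {
      hits <- which(RSS == m, arr.ind = TRUE)
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      best <- list(i1 = unname(hits[1, 1]), i2 = unname(hits[1, 2]), rss = m)
    }
    sweeps <- 1L
  } else {
    sweeps <- 0L
    repeat {
      prev <- best[c("i1", "i2")]
      for (i1 in seq_len(nrow(grid))) {
        r <- rss_of(i1, best$i2)
        if (r < best$rss) best <- list(i1 = i1, i2 = best$i2, rss = r)
      }
      for (i2 in seq_len(nrow(grid))) {
        r <- rss_of(best$i1, i2)
        if (r < best$rss) best <- list(i1 = best$i1, i2 = i2, rss = r)
      }
      sweeps <- sweeps + 1L
      if (identical(prev, best[c("i1", "i2")]) || sweeps >= max_sweeps) break
    }
  }
  if (!is.finite(best$rss)) {
    abort("All candidate COAPM fits were rank deficient.",
          class = "nof1_estimation_error")
  }

  # refit at the selected parameters for coefficient SEs
  X <- cbind(`(Intercept)` = 1, e1 = lib1[[best$i1]], e2 = lib2[[best$i2]],
             Xc[, -1, drop = FALSE])
  fit <- lm(y ~ X - 1)
  b <- setNames(coef(fit), colnames(X))
  V <- vcov_lm(fit)
  dimnames(V) <- list(colnames(X), colnames(X))
  se_diff <- sqrt(V["e1", "e1"] + V["e2", "e2"] - 2 * V["e1", "e2"])
  r2 <- 1 - best$rss / tss
  new_estimate(
    "coapm",
    estimate = b[["e1"]] - b[["e2"]],
    se = se_diff,
    coefficients = b,
    details = list(
      tau1 = grid$tau[best$i1], gamma1 = grid$gamma[best$i1],
      tau2 = grid$tau[best$i2], gamma2 = grid$gamma[best$i2],
      r_squared = r2,
      beta1 = b[["e1"]], beta2 = b[["e2"]],
      se_beta1 = sqrt(V["e1", "e1"]), se_beta2 = sqrt(V["e2", "e2"]),
      sweeps = sweeps
    ),
    n_patients = dplyr::n_distinct(data$patient_id[keep]),
    n_obs = length(y),
    subclass = "coapm_fit"
  )
}

# vectorized exposure recursion over the columns of a 0/1 day-by-patient matrix
exposure_col_matrix <- function(tk, tau, gamma) {
  ek <- matrix(0, nrow(tk), ncol(tk))
  prev <- rep(0, ncol(tk))
  for (t in seq_len(nrow(tk))) {
    prev <- prev + (1 - prev) / tau * tk[t, ] - prev / gamma * (1 - tk[t, ])
    ek[t, ] <- prev
  }
  ek
}

#' @export
print.coapm_fit <- function(x, ...) {
  d <- x$details
  cat("<coapm_fit> effect difference:", format(x$estimate, digits = 4),
      "(SE", format(x$se, digits = 3), ")\n")
  cat("  beta1:", format(d$beta1, digits = 4),
      "| beta2:", format(d$beta2, digits = 4),
      "| R^2:", format(d$r_squared, digits = 4), "\n")
  cat("  selected tau/gamma:", d$tau1, d$gamma1, "(trt 1);",
      d$tau2, d$gamma2, "(trt 2) in", d$sweeps, "sweep(s)\n")
  invisible(x)
}

#' @describeIn coapm_grid_search Coefficient table of the selected fit.
#' @param x A `coapm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coapm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}
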