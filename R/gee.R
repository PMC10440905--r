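#' Logistic regression by generalized estimating equations
#'
#' Solves the GEE score equations for a binary response with logit link
#' under an `independence` or `ar1` working correlation, clusters being
#' patients (rows are used in their within-cluster order, i.e. study days).
#' Under independence the solution coincides with ordinary logistic maximum
#' likelihood. Under AR1, the correlation parameter is re-estimated at each
#' scoring step from the lag-1 autocorrelation of within-cluster Pearson
#' residuals, and the working-covariance solve exploits the closed-form
#' tridiagonal inverse of an AR1 correlation matrix.
#'
#' @param data A data frame.
#' @param formula Model formula; the response must be 0/1.
#' @param id Name of the cluster (patient) column.
#' @param correlation `"independence"` or `"ar1"`.
#' @param max_iter,tol Scoring iteration controls.
#' @return An object of class `nof1_gee`: `coefficients`, `correlation`,
#'   `alpha` (estimated AR1 parameter, `NA` under independence),
#'   `iterations`, `converged`.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40),
#'                 patient_id = rep(1:4, each = 10))
#' coef(gee_logistic(d, y ~ x))
gee_logistic <- function(data, formula, id = "patient_id",
                         correlation = c("independence", "ar1"),
                         max_iter = 50L, tol = 1e-8) {
  correlation <- match.arg(correlation)
  vars <- intersect(all.vars(formula), names(data))
  ok <- stats::complete.cases(as.data.frame(data[, c(vars, id), drop = FALSE]))
  data <- data[ok, , drop = FALSE]
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) {
    abort("GEE response must be binary 0/1.", class = "nof1_argument_error")
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  check_full_rank(X)
  cl <- data[[id]]
  idx <- split(seq_along(y), factor(cl, levels = unique(cl)))
  p <- ncol(X)
  n <- length(y)

  beta <- rep(0, p)
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) {
      abort("Separation detected in GEE logistic fit.",
            class = "nof1_estimation_error")
    }
    s <- sqrt(w)
    r <- (y - mu) / s
    if (correlation == "ar1") {
      alpha <- ar1_moment(r, idx, p)
    }
    H <- matrix(0, p, p)
    U <- rep(0, p)
    for (ii in idx) {
      Z <- X[ii, , drop = FALSE] * s[ii]
      ri <- r[ii]
      if (correlation == "ar1" && length(ii) > 1) {
        RZ <- ar1_inv_mult(Z, alpha)
        Rr <- drop(ar1_inv_mult(matrix(ri, ncol = 1), alpha))
      } else {
        RZ <- Z
        Rr <- ri
      }
      H <- H + crossprod(Z, RZ)
      U <- U + drop(crossprod(Z, Rr))
    }
    step <- solve(H, U)
    beta <- beta + step
    if (max(abs(beta)) > 1e3) {
      abort("GEE logistic fit diverged (possible separation).",
            class = "nof1_estimation_error")
    }
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("GEE did not converge in ", max_iter,
                 " iterations (last step ", format(max(abs(step))), ")."),
          class = "nof1_estimation_error")
  }
  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         correlation = correlation,
         alpha = if (correlation == "ar1") alpha else NA_real_,
         iterations = it, converged = converged, n = n, n_clusters = length(idx)),
    class = "nof1_gee"
  )
}

# moment estimator of the AR1 parameter from Pearson residuals
ar1_moment <- function(r, idx, p) {
  num <- 0
  npairs <- 0
  for (ii in idx) {
    ri <- r[ii]
    if (length(ri) > 1) {
      num <- num + sum(head(ri, -1) * tail(ri, -1))
      npairs <- npairs + length(ri) - 1
    }
  }
  phi <- sum(r^2) / (length(r) - p)
  denom <- (npairs - p) * phi
  if (denom <= 0) return(0)
  max(min(num / denom, 0.99), -0.99)
}

# multiply the inverse AR1 correlation matrix into the rows of M (n x p)
ar1_inv_mult <- function(M, alpha) {
  n <- nrow(M)
  if (n == 1 || alpha == 0) return(M / 1)
  up <- rbind(M[-1, , drop = FALSE], 0)    # row t holds M[t+1, ]
  down <- rbind(0, M[-n, , drop = FALSE])  # row t holds M[t-1, ]
  out <- (1 + alpha^2) * M - alpha * (up + down)
  out[1, ] <- M[1, ] - alpha * M[2, ]
  out[n, ] <- M[n, ] - alpha * M[n - 1, ]
  out / (1 - alpha^2)
}

#' @export
coef.nof1_gee <- function(object, ...) object$coefficients

#' @export
print.nof1_gee <- function(x, ...) {
  cat("<nof1_gee> logistic,", x$correlation, "working correlation\n")
  if (!is.na(x$alpha)) cat("  alpha-hat:", format(x$alpha, digits = 4), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @describeIn gee_logistic Coefficient table.
#' @param x An `nof1_gee` fit.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nof1_gee <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}
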