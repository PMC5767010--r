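# Center-adjusted logistic regression via iteratively reweighted least
# squares. The design is [intercept | center indicators | selected
# candidates]; candidates are addressed by bitmask.

design_matrix <- function(matrix, mask) {
  idx <- mask_indices(mask, ncol(matrix$x))
  cbind(`(Intercept)` = 1, matrix$z, matrix$x[, idx, drop = FALSE])
}

#' Fit one center-adjusted logistic model
#'
#' Maximum likelihood via IRLS; convergence is declared when the largest
#' coefficient change falls below `tol` (default 1e-8) within `maxit`
#' iterations (default 25). Perfect or quasi-perfect separation shows up as
#' diverging coefficients and is flagged: the fit is returned with
#' `converged = FALSE` and `separated = TRUE` together with a warning.
#'
#' @param matrix an `aki_matrix`.
#' @param mask integer bitmask of candidate predictors to include (0 for
#'   the center-only model). Alternatively a character vector of predictor
#'   names.
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @param warn warn on separation/non-convergence (default `TRUE`).
#' @return An object of class `"aki_fit"`: named `coefficients`, `loglik`,
#'   `df` (number of estimated parameters), `bic`, `converged`,
#'   `separated`, `cov` (inverse observed information), `mask`, `n`.
#' @export
fit_logistic <- function(matrix, mask = 0L, maxit = 25L, tol = 1e-8,
                         warn = TRUE) {
  if (is.character(mask)) mask <- mask_from_names(mask, matrix$predictor_names)
  X <- design_matrix(matrix, mask)
  f <- cpp_fit_logistic(X, as.numeric(matrix$y), maxit, tol, numeric(0), TRUE)
  if (f$singular) stop("singular design in logistic fit (rank-deficient)")
  if (warn && f$separated) {
    warning("separation detected: coefficients diverging, fit not converged")
  } else if (warn && !f$converged) {
    warning("IRLS did not converge in ", maxit, " iterations")
  }
  df <- ncol(X)
  coefs <- setNames(drop(f$coefficients), colnames(X))
  cov <- f$cov
  if (!is.null(cov)) dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = coefs,
    loglik = f$loglik,
    df = df,
    bic = -2 * f$loglik + df * log(matrix$n),
    converged = f$converged,
    ll_converged = f$ll_converged,
    separated = f$separated,
    cov = cov,
    mask = mask,
    predictor_names = matrix$predictor_names,
    n = matrix$n
  ), class = "aki_fit")
}

#' @export
print.aki_fit <- function(x, ...) {
  nm <- mask_names(x$mask, x$predictor_names)
  cat(sprintf("<aki_fit> %s + center | n=%d, loglik=%.3f, BIC=%.2f%s\n",
              if (length(nm)) paste(nm, collapse = " + ") else "(center only)",
              x$n, x$loglik, x$bic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

# Wald z-test p-values for the candidate coefficients of a fit.
wald_p <- function(fit) {
  se <- sqrt(diag(fit$cov))
  z <- fit$coefficients / se
  2 * pnorm(-abs(z))
}
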