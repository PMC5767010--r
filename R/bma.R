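# Bayesian model averaging for center-adjusted logistic regression.
# Candidate models are subsets of the candidate predictors; forced
# covariates (intercept + center indicators) appear in every model and
# carry prior probability 1. Posterior model probabilities use the BIC
# approximation to the integrated likelihood together with independent
# Bernoulli(pi) variable priors, and Occam's window discards models far
# behind the best before renormalization.

#' BMA configuration
#'
#' @param prior_pi prior inclusion probability per candidate (default 0.5,
#'   i.e. a uniform prior over the 2^p models).
#' @param occam_ratio Occam's-window width: models whose posterior odds
#'   against the best model exceed this ratio are discarded (default 20).
#' @param nbest subsets kept per model size by the branch-and-bound search
#'   stage (default 50).
#' @param search `"auto"` (exhaustive for p <= 16, otherwise
#'   branch-and-bound), `"exhaustive"`, or `"leaps"` (always use the
#'   branch-and-bound search on the IRLS linearization).
#' @param max_nodes node budget for the branch-and-bound search.
#' @return A list of class `"bma_config"`.
#' @export
bma_config <- function(prior_pi = 0.5, occam_ratio = 20, nbest = 50L,
                       search = c("auto", "exhaustive", "leaps"),
                       max_nodes = 5e6) {
  stopifnot(prior_pi > 0, prior_pi < 1, occam_ratio > 1, nbest >= 1)
  structure(list(prior_pi = prior_pi, occam_ratio = occam_ratio,
                 nbest = as.integer(nbest), search = match.arg(search),
                 max_nodes = max_nodes),
            class = "bma_config")
}

#' Candidate model search
#'
#' For small candidate sets, enumerates all 2^p subsets. Otherwise runs a
#' two-stage search: the full logistic model is fit by IRLS, the weighted
#' linearized least-squares problem is formed from the final IRLS working
#' response and weights, and a branch-and-bound best-subsets search returns
#' the `nbest` lowest-RSS subsets per model size. Exact logistic BICs are
#' recomputed downstream for every candidate, so the linearization affects
#' only which models are screened in.
#'
#' @param matrix an `aki_matrix`.
#' @param config a [bma_config()].
#' @return Sorted integer vector of unique candidate bitmasks.
#' @export
candidate_models <- function(matrix, config = bma_config()) {
  p <- ncol(matrix$x)
  stopifnot(p >= 1)
  exhaustive <- switch(config$search,
    exhaustive = TRUE,
    leaps = FALSE,
    auto = p <= 16)
  if (exhaustive) {
    if (p > 20) stop("exhaustive search infeasible for p = ", p,
                     "; use search = 'leaps'")
    return(0:(2^p - 1))
  }

  # the linearization point needs a maximized likelihood, not small
  # coefficient steps: quasi-separated fits with a stabilized likelihood
  # are accepted here
  full <- fit_logistic(matrix, mask_from_indices(seq_len(p)), maxit = 100L,
                       warn = FALSE)
  if (!full$converged && !full$ll_converged) {
    if (p <= 16) {
      warning("full-model IRLS did not converge; falling back to exhaustive")
      return(0:(2^p - 1))
    }
    stop("full-model IRLS did not converge; candidate search unavailable")
  }

  # weighted linearization at the full-model fit
  Fmat <- design_matrix(matrix, mask_from_indices(seq_len(p)))
  eta <- drop(Fmat %*% full$coefficients)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  z <- eta + (matrix$y - mu) / w
  nf <- ncol(Fmat) - p

  # order candidates by full-model Wald |z| so strong predictors are
  # branched first (tightens the bound early)
  se <- sqrt(diag(full$cov))
  tstat <- abs(full$coefficients / se)[nf + seq_len(p)]
  ord <- order(-tstat)

  Fo <- Fmat[, c(seq_len(nf), nf + ord), drop = FALSE]
  Fw <- Fo * w
  A <- crossprod(Fo, Fw)
  b <- crossprod(Fw, z)
  zz <- sum(w * z^2)

  res <- cpp_bnb_subsets(A, drop(b), zz, nf, config$nbest, config$max_nodes)
  if (isTRUE(res$truncated)) {
    warning("branch-and-bound node budget reached; candidate list may be ",
            "incomplete")
  }
  # map masks from search order back to original candidate indices
  masks <- vapply(res$mask, function(m) {
    mask_from_indices(ord[mask_indices(m, p)])
  }, integer(1))
  sort(unique(masks))
}

fit_candidates <- function(matrix, masks, maxit = 25L, tol = 1e-8) {
  p <- ncol(matrix$x)
  D <- cbind(1, matrix$z)
  full <- cpp_fit_logistic(cbind(D, matrix$x), as.numeric(matrix$y),
                           maxit, tol, numeric(0), FALSE)
  start <- if (full$converged) drop(full$coefficients) else numeric(0)
  f <- cpp_fit_masks(D, matrix$x, as.numeric(matrix$y),
                     as.integer(masks), maxit, tol, start)
  size <- mask_size(masks)
  df <- ncol(D) + size
  list(
    mask = as.integer(masks),
    size = size,
    loglik = f$loglik,
    df = df,
    bic = -2 * f$loglik + df * log(matrix$n),
    # usable for the posterior: likelihood maximized (coefficient
    # convergence, or a stabilized likelihood under quasi-separation)
    converged = (f$converged | f$ll_converged) & !f$singular,
    coefficients = f$coefficients,
    coef_names = c("(Intercept)", colnames(matrix$z),
                   matrix$predictor_names),
    n = matrix$n
  )
}

#' Posterior model and variable probabilities
#'
#' Combines BIC-approximated integrated likelihoods with independent
#' Bernoulli(`prior_pi`) variable priors: the unnormalized posterior of
#' model k is `exp(-bic_k / 2) * pi^|k| * (1-pi)^(p-|k|)`. Models whose
#' posterior odds against the best exceed `occam_ratio` are discarded
#' (Occam's window) and the survivors renormalized to sum to one. The
#' posterior variable probability of a candidate is the summed posterior of
#' retained models containing it; forced covariates have probability 1 by
#' construction.
#'
#' @param fits candidate fits from `fit_candidates()` (or a list with
#'   fields `mask`, `size`, `bic`, `converged`).
#' @param config a [bma_config()].
#' @param p number of candidate predictors.
#' @param predictor_names candidate names (length p).
#' @return An object of class `"bma_result"`: `models` (data frame of
#'   retained models with masks, sizes, BICs and posterior probabilities,
#'   sorted by decreasing posterior), `variable_probs`, `max_model`,
#'   `median_model`, `n_candidates_evaluated`, and the retained models'
#'   coefficients.
#' @export
posterior_probabilities <- function(fits, config = bma_config(),
                                    p = NULL,
                                    predictor_names = NULL) {
  if (is.null(p)) {
    if (is.null(predictor_names)) stop("supply p or predictor_names")
    p <- length(predictor_names)
  }
  if (is.null(predictor_names)) predictor_names <- paste0("x", seq_len(p))
  keep <- fits$converged
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " candidate fit(s) did not converge and were dropped")
  }
  if (!any(keep)) stop("no converged candidate fits")
  mask <- fits$mask[keep]
  size <- fits$size[keep]
  bic <- fits$bic[keep]

  pi <- config$prior_pi
  logpost <- -0.5 * (bic - min(bic)) + size * log(pi) + (p - size) * log(1 - pi)
  logpost <- logpost - logsumexp(logpost)
  best <- max(logpost)
  inwin <- (best - logpost) <= log(config$occam_ratio)
  mask <- mask[inwin]; size <- size[inwin]; bic <- bic[inwin]
  post <- exp(logpost[inwin])
  post <- post / sum(post)

  ord <- order(-post, size, mask)
  mask <- mask[ord]; size <- size[ord]; bic <- bic[ord]; post <- post[ord]

  varprob <- setNames(numeric(p), predictor_names)
  for (j in seq_len(p)) {
    varprob[j] <- sum(post[bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L])
  }

  # max model: highest posterior; exact ties go to the smaller model, then
  # the lexicographically smaller bitmask (already the sort order)
  tied <- which(post >= post[1] - 1e-12)
  max_model <- mask[tied[1]]
  median_model <- mask_from_indices(which(varprob > 0.5))

  coefficients <- NULL
  if (!is.null(fits$coefficients)) {
    coefficients <- fits$coefficients[, keep, drop = FALSE][, inwin,
                                                           drop = FALSE]
    coefficients <- coefficients[, ord, drop = FALSE]
    rownames(coefficients) <- fits$coef_names
  }

  structure(list(
    models = data.frame(mask = mask, size = size, bic = bic,
                        posterior = post),
    variable_probs = varprob,
    max_model = max_model,
    median_model = median_model,
    n_candidates_evaluated = length(fits$mask),
    coefficients = coefficients,
    prior_pi = pi,
    occam_ratio = config$occam_ratio,
    p = p,
    predictor_names = predictor_names
  ), class = "bma_result")
}

#' Run the full BMA analysis
#'
#' Candidate search, exact logistic refits of every candidate, posterior
#' model/variable probabilities, and the two selection rules. Deterministic
#' given the matrix and config.
#'
#' @param matrix an `aki_matrix`.
#' @param config a [bma_config()].
#' @return A `"bma_result"`; see [posterior_probabilities()].
#' @export
run_bma <- function(matrix, config = bma_config()) {
  masks <- candidate_models(matrix, config)
  fits <- fit_candidates(matrix, masks)
  posterior_probabilities(fits, config, p = ncol(matrix$x),
                          predictor_names = matrix$predictor_names)
}

#' Maximum posterior model probability combination
#'
#' @param result a `"bma_result"`.
#' @return Integer bitmask of the highest-posterior model.
#' @export
select_max_posterior <- function(result) {
  stopifnot(inherits(result, "bma_result"))
  result$max_model
}

#' Median probability combination
#'
#' The model containing exactly the candidates whose posterior variable
#' probability strictly exceeds 0.5 (a probability of exactly 0.5 is
#' excluded). May be empty (center-only model).
#'
#' @param result a `"bma_result"`.
#' @return Integer bitmask.
#' @export
select_median_probability <- function(result) {
  stopifnot(inherits(result, "bma_result"))
  result$median_model
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf(
    "<bma_result> %d candidates evaluated, %d models in Occam's window\n",
    x$n_candidates_evaluated, nrow(x$models)))
  cat(sprintf("  max posterior model (prob %.3f): %s\n",
              x$models$posterior[1],
              fmt_mask(x$max_model, x$predictor_names)))
  cat(sprintf("  median probability model: %s\n",
              fmt_mask(x$median_model, x$predictor_names)))
  vp <- sort(x$variable_probs[x$variable_probs > 0.05], decreasing = TRUE)
  if (length(vp) > 0) {
    cat("  posterior variable probabilities > 0.05:\n")
    for (nm in names(vp)) cat(sprintf("    %-12s %.3f\n", nm, vp[nm]))
  }
  invisible(x)
}

fmt_mask <- function(mask, names) {
  nm <- mask_names(mask, names)
  if (length(nm) == 0) "(center only)" else paste(nm, collapse = " + ")
}
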