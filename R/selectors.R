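# Selection procedures operating on an analysis matrix, plus the repeated
# stratified half-split experiment comparing them on held-out
# center-adjusted AUC and model size.

#' Construct a selection procedure
#'
#' A selector is a deterministic function of an `aki_matrix` returning the
#' selected candidate bitmask (with BMA detail attached where available).
#'
#' @param method `"bma-max"`, `"bma-median"`, `"forward"`, `"univariate"`,
#'   or `"fixed"` (a data-independent mask, for optimism baselines).
#' @param bma a [bma_config()] for the BMA selectors.
#' @param p_enter forward-selection entry threshold on the Wald p-value.
#' @param p_uni univariate-selection inclusion threshold.
#' @param mask fixed bitmask for `method = "fixed"`.
#' @return A function `matrix -> list(mask, detail)` with attribute
#'   `"method"`.
#' @export
make_selector <- function(method = c("bma-max", "bma-median", "forward",
                                     "univariate", "fixed"),
                          bma = bma_config(), p_enter = 0.1, p_uni = 0.1,
                          mask = 0L) {
  method <- match.arg(method)
  fn <- switch(method,
    "bma-max" = function(matrix) {
      res <- run_bma(matrix, bma)
      list(mask = res$max_model,
           detail = list(posterior = res$models$posterior[1],
                         variable_probs = res$variable_probs))
    },
    "bma-median" = function(matrix) {
      res <- run_bma(matrix, bma)
      post <- res$models$posterior[match(res$median_model, res$models$mask)]
      list(mask = res$median_model,
           detail = list(posterior = post,
                         variable_probs = res$variable_probs))
    },
    "forward" = function(matrix) {
      list(mask = forward_selection(matrix, p_enter), detail = NULL)
    },
    "univariate" = function(matrix) {
      list(mask = univariate_selection(matrix, p_uni), detail = NULL)
    },
    "fixed" = function(matrix) list(mask = mask, detail = NULL)
  )
  attr(fn, "method") <- method
  fn
}

#' Forward selection with a p-value threshold
#'
#' Starts from the center-only model and repeatedly adds the candidate
#' with the smallest Wald p-value among those below `p_enter`; stops when
#' no candidate qualifies. No removal step. Candidates whose trial fit
#' fails to converge are skipped with a warning.
#'
#' @param matrix an `aki_matrix`.
#' @param p_enter entry threshold (default 0.1).
#' @return Integer bitmask of the selected candidates.
#' @export
forward_selection <- function(matrix, p_enter = 0.1) {
  p <- ncol(matrix$x)
  current <- 0L
  remaining <- seq_len(p)
  nf <- 1 + ncol(matrix$z)
  repeat {
    if (length(remaining) == 0) break
    pvals <- rep(NA_real_, length(remaining))
    for (k in seq_along(remaining)) {
      trial <- mask_from_indices(c(mask_indices(current, p), remaining[k]))
      fit <- tryCatch(fit_logistic(matrix, trial, warn = FALSE),
                      error = function(e) NULL)
      if (is.null(fit) || !(fit$converged || fit$ll_converged)) next
      # p-value of the newly entered candidate
      nm <- matrix$predictor_names[remaining[k]]
      pvals[k] <- wald_p(fit)[nm]
    }
    if (any(is.na(pvals))) {
      warning("skipped ", sum(is.na(pvals)),
              " non-convergent candidate step(s)")
    }
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= p_enter) break
    add <- remaining[which.min(pvals)]
    current <- mask_from_indices(c(mask_indices(current, p), add))
    remaining <- setdiff(remaining, add)
  }
  current
}

#' Univariate selection with a p-value threshold
#'
#' Fits one center-adjusted logistic model per candidate and includes every
#' candidate whose Wald p-value is below `p_uni`. The selected candidates
#' form a single combination that downstream code refits jointly.
#'
#' @param matrix an `aki_matrix`.
#' @param p_uni inclusion threshold (default 0.1).
#' @return Integer bitmask of the selected candidates.
#' @export
univariate_selection <- function(matrix, p_uni = 0.1) {
  p <- ncol(matrix$x)
  sel <- logical(p)
  skipped <- 0
  for (j in seq_len(p)) {
    fit <- tryCatch(fit_logistic(matrix, mask_from_indices(j), warn = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || !(fit$converged || fit$ll_converged)) {
      skipped <- skipped + 1
      next
    }
    sel[j] <- wald_p(fit)[matrix$predictor_names[j]] < p_uni
  }
  if (skipped > 0) warning("skipped ", skipped, " non-convergent fit(s)")
  mask_from_indices(which(sel))
}

#' Split-sample comparison configuration
#'
#' @param n_splits number of random half-splits (default 1000).
#' @param p_enter,p_uni thresholds for the frequentist selectors.
#' @param bma a [bma_config()] for the BMA selectors.
#' @param seed integer seed.
#' @return A list of class `"split_config"`.
#' @export
split_config <- function(n_splits = 1000L, p_enter = 0.1, p_uni = 0.1,
                         bma = bma_config(), seed = 1L) {
  stopifnot(p_enter > 0, p_enter <= 1, p_uni >= 0, p_uni <= 1, n_splits >= 1)
  structure(list(n_splits = as.integer(n_splits), p_enter = p_enter,
                 p_uni = p_uni, bma = bma, seed = as.integer(seed)),
            class = "split_config")
}

#' Stratified half split
#'
#' Splits the rows into training and test halves of (as near as possible)
#' equal size with equal numbers of cases: cases are split as evenly as
#' possible, controls likewise, and with odd counts the training half takes
#' the extra subject. Deterministic given the seed.
#'
#' @param matrix an `aki_matrix` (split is stratified on its outcome).
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_half_split <- function(matrix, seed = 1L) {
  y <- matrix$y
  cases <- which(y == 1)
  controls <- which(y == 0)
  if (length(cases) < 2 || length(controls) < 2) {
    stop("need at least two cases and two controls to split")
  }
  with_seed(seed, {
    cases <- sample(cases)
    controls <- sample(controls)
    n1_train <- ceiling(length(cases) / 2)
    n0_train <- ceiling(length(controls) / 2)
    train <- sort(c(cases[seq_len(n1_train)], controls[seq_len(n0_train)]))
    test <- sort(c(cases[-seq_len(n1_train)], controls[-seq_len(n0_train)]))
    list(train = train, test = test)
  })
}

#' Compare selection strategies on repeated half-splits
#'
#' For each split, the four selectors (BMA maximum posterior, BMA median
#' probability, forward, univariate) are run on the training half, the
#' selected combinations are refit on the training half, and their
#' center-adjusted AUC is evaluated on the held-out test half only. Empty
#' selections score 0.5 (no discrimination).
#'
#' @param matrix a complete-case `aki_matrix`.
#' @param config a [split_config()].
#' @return An object of class `"selector_comparison"`: `per_split` (long
#'   data frame with split, method, auc, size) and `summary` (per method:
#'   mean AUC, 2.5th/97.5th percentiles, median and IQR of model size).
#' @export
compare_selectors <- function(matrix, config = split_config()) {
  methods <- c("bma-max", "bma-median", "forward", "univariate")
  rows <- vector("list", config$n_splits * length(methods))
  k <- 0
  for (s in seq_len(config$n_splits)) {
    sp <- stratified_half_split(matrix, seed = config$seed + s - 1L)
    train <- matrix_rows(matrix, sp$train)
    test <- matrix_rows(matrix, sp$test)

    bma_res <- run_bma(train, config$bma)
    masks <- c(
      "bma-max" = select_max_posterior(bma_res),
      "bma-median" = select_median_probability(bma_res),
      "forward" = forward_selection(train, config$p_enter),
      "univariate" = univariate_selection(train, config$p_uni)
    )
    for (m in methods) {
      mask <- masks[[m]]
      auc <- if (mask_size(mask) == 0) 0.5 else {
        fit <- fit_logistic(train, mask, warn = FALSE)
        adjusted_auc_of_fit(fit, test)$auc
      }
      k <- k + 1
      rows[[k]] <- data.frame(split = s, method = m, auc = auc,
                              size = mask_size(mask),
                              stringsAsFactors = FALSE)
    }
  }
  per_split <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    d <- per_split[per_split$method == m, ]
    data.frame(
      method = m,
      mean_auc = mean(d$auc),
      auc_lo = unname(quantile(d$auc, 0.025)),
      auc_hi = unname(quantile(d$auc, 0.975)),
      median_size = median(d$size),
      size_q1 = unname(quantile(d$size, 0.25)),
      size_q3 = unname(quantile(d$size, 0.75)),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(per_split = per_split, summary = summ, config = config),
            class = "selector_comparison")
}

#' @export
print.selector_comparison <- function(x, ...) {
  cat(sprintf("<selector_comparison> %d splits\n",
              max(x$per_split$split)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-11s held-out AUC %.3f (%.3f, %.3f) | size median %g (IQR %g-%g)\n",
      s$method[i], s$mean_auc[i], s$auc_lo[i], s$auc_hi[i],
      s$median_size[i], s$size_q1[i], s$size_q3[i]))
  }
  invisible(x)
}
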