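# Internal validation: apparent performance of a selected combination,
# bootstrap optimism correction in which the entire selection procedure is
# repeated on every resample, optimism-shifted confidence intervals,
# cross-outcome evaluation, and resampling diagnostics.

#' Validation configuration
#'
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param stratify_by_center resample within center (default `TRUE`), so
#'   every center is represented and center-adjusted fitting is defined in
#'   every replicate; set `FALSE` for a plain bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @return A list of class `"validation_config"`.
#' @export
validation_config <- function(n_boot = 1000L, seed = 1L,
                              stratify_by_center = TRUE, ci_level = 0.95) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 stratify_by_center = isTRUE(stratify_by_center),
                 ci_level = ci_level),
            class = "validation_config")
}

#' Apparent performance of a selected combination
#'
#' Runs the selector on the full data, refits the selected combination by
#' center-adjusted logistic regression, and evaluates its center-adjusted
#' AUC on the same data (resubstitution). An empty selection has no
#' discrimination and scores 0.5 with a warning.
#'
#' @param matrix an `aki_matrix`.
#' @param selector a selector from [make_selector()].
#' @return A list with `mask`, `fit` (`NULL` if empty), `performance`
#'   (an `"aki_auc"` or the 0.5 placeholder), and `detail`.
#' @export
apparent_performance <- function(matrix, selector) {
  sel <- selector(matrix)
  if (mask_size(sel$mask) == 0) {
    warning("selector returned an empty combination; apparent AUC set to 0.5")
    return(list(mask = sel$mask, fit = NULL,
                performance = list(auc = 0.5, empty = TRUE),
                detail = sel$detail))
  }
  fit <- fit_logistic(matrix, sel$mask, warn = FALSE)
  list(mask = sel$mask, fit = fit,
       performance = adjusted_auc_of_fit(fit, matrix),
       detail = sel$detail)
}

resample_indices <- function(matrix, stratify) {
  if (stratify) {
    idx <- unlist(lapply(levels(matrix$center), function(l) {
      i <- which(matrix$center == l)
      if (length(i) == 0) integer(0) else sample(i, length(i), replace = TRUE)
    }))
    sort(idx)
  } else {
    sort(sample.int(matrix$n, matrix$n, replace = TRUE))
  }
}

#' Bootstrap optimism correction
#'
#' For each replicate: resample subjects with replacement (within center by
#' default), rerun the entire selection procedure on the resample, refit
#' the replicate-selected combination on the resample, and evaluate its
#' center-adjusted AUC on (i) the resample and (ii) the original data. The
#' replicate optimism is (i) - (ii); the mean over replicates is subtracted
#' from the apparent AUC to give the optimism-corrected AUC. Replicates
#' where selection or evaluation is undefined are skipped, counted and
#' warned about; replicates selecting the empty combination contribute AUC
#' 0.5 on both datasets (optimism 0).
#'
#' When `secondary` is supplied (a binary outcome vector aligned with the
#' matrix rows), the same replicate combinations -- selected and fit
#' against the primary outcome -- are also evaluated against the secondary
#' outcome inside the same loop, yielding a cross-outcome corrected AUC.
#'
#' @param matrix an `aki_matrix`.
#' @param selector a selector from [make_selector()].
#' @param config a [validation_config()].
#' @param secondary optional binary secondary-outcome vector.
#' @return An object of class `"validation_report"`: `apparent`
#'   (selection + performance on the full data), `per_replicate` (data
#'   frame of boot/original AUCs, optimism, selected mask and size,
#'   posterior of the selected model where available), `mean_optimism`,
#'   `corrected_auc`, `ci`, `n_skipped`, `variable_probs` (replicate-level
#'   matrix when the selector reports them), and `secondary` (same
#'   summaries for the secondary outcome, or `NULL`).
#' @export
bootstrap_optimism <- function(matrix, selector,
                               config = validation_config(),
                               secondary = NULL) {
  apparent <- suppressWarnings(apparent_performance(matrix, selector))
  apparent_auc <- apparent$performance$auc
  apparent_sec <- NULL
  if (!is.null(secondary)) {
    stopifnot(length(secondary) == matrix$n)
    if (length(unique(secondary)) < 2) stop("secondary outcome degenerate")
    apparent_sec <- if (is.null(apparent$fit)) 0.5 else
      center_adjusted_auc(combination_score(apparent$fit, matrix),
                          secondary, matrix$center)$auc
  }

  B <- config$n_boot
  rep_rows <- vector("list", B)
  vp_rows <- vector("list", B)
  n_skipped <- 0

  with_seed(config$seed, {
    for (b in seq_len(B)) {
      idx <- resample_indices(matrix, config$stratify_by_center)
      sub <- matrix_rows(matrix, idx)
      row <- tryCatch({
        sel <- selector(sub)
        if (mask_size(sel$mask) == 0) {
          r <- data.frame(boot_auc = 0.5, orig_auc = 0.5, optimism = 0,
                          mask = sel$mask, size = 0L,
                          posterior = na_or(sel$detail$posterior))
          if (!is.null(secondary)) {
            r$sec_boot <- 0.5; r$sec_orig <- 0.5; r$sec_optimism <- 0
          }
          list(row = r, vp = sel$detail$variable_probs)
        } else {
          fit_b <- fit_logistic(sub, sel$mask, warn = FALSE)
          boot_auc <- adjusted_auc_of_fit(fit_b, sub)$auc
          orig_auc <- adjusted_auc_of_fit(fit_b, matrix)$auc
          r <- data.frame(boot_auc = boot_auc, orig_auc = orig_auc,
                          optimism = boot_auc - orig_auc,
                          mask = sel$mask, size = mask_size(sel$mask),
                          posterior = na_or(sel$detail$posterior))
          if (!is.null(secondary)) {
            sc_b <- combination_score(fit_b, sub)
            sc_o <- combination_score(fit_b, matrix)
            r$sec_boot <- center_adjusted_auc(sc_b, secondary[idx],
                                              sub$center)$auc
            r$sec_orig <- center_adjusted_auc(sc_o, secondary,
                                              matrix$center)$auc
            r$sec_optimism <- r$sec_boot - r$sec_orig
          }
          list(row = r, vp = sel$detail$variable_probs)
        }
      }, error = function(e) NULL)
      if (is.null(row)) {
        n_skipped <- n_skipped + 1
      } else {
        rep_rows[[b]] <- row$row
        if (!is.null(row$vp)) vp_rows[[b]] <- row$vp
      }
    }
  })
  if (n_skipped > 0) {
    warning(n_skipped, " bootstrap replicate(s) skipped (selection or ",
            "evaluation undefined)")
  }
  per_replicate <- do.call(rbind, rep_rows[!vapply(rep_rows, is.null,
                                                   logical(1))])
  if (is.null(per_replicate) || nrow(per_replicate) == 0) {
    stop("no usable bootstrap replicates")
  }
  variable_probs <- NULL
  keep_vp <- !vapply(vp_rows, is.null, logical(1))
  if (any(keep_vp)) variable_probs <- do.call(rbind, vp_rows[keep_vp])

  mean_optimism <- mean(per_replicate$optimism)
  report <- structure(list(
    apparent = apparent,
    apparent_auc = apparent_auc,
    per_replicate = per_replicate,
    mean_optimism = mean_optimism,
    corrected_auc = apparent_auc - mean_optimism,
    n_skipped = n_skipped,
    variable_probs = variable_probs,
    config = config,
    secondary = NULL
  ), class = "validation_report")
  report$ci <- tryCatch(optimism_shifted_ci(report, config),
                        error = function(e) c(NA_real_, NA_real_))

  if (!is.null(secondary)) {
    sec_mean_opt <- mean(per_replicate$sec_optimism)
    report$secondary <- list(
      apparent_auc = apparent_sec,
      mean_optimism = sec_mean_opt,
      corrected_auc = apparent_sec - sec_mean_opt,
      ci = shift_ci(per_replicate$sec_boot, sec_mean_opt, config$ci_level)
    )
  }
  report
}

na_or <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else x

shift_ci <- function(boot_aucs, mean_optimism, level) {
  a <- (1 - level) / 2
  ci <- unname(quantile(boot_aucs, c(a, 1 - a))) - mean_optimism
  pmin(pmax(ci, 0), 1)
}

#' Optimism-shifted confidence interval
#'
#' Percentile interval of the replicate apparent (resample) AUCs -- each
#' replicate having rerun the full selection -- with both endpoints shifted
#' down by the mean optimism and clipped to \[0, 1\].
#'
#' @param report a `"validation_report"`.
#' @param config a [validation_config()] (for the level).
#' @return Numeric `c(low, high)`.
#' @export
optimism_shifted_ci <- function(report, config = report$config) {
  if (nrow(report$per_replicate) < 20) {
    stop("fewer than 20 usable replicates; CI not estimated")
  }
  shift_ci(report$per_replicate$boot_auc, report$mean_optimism,
           config$ci_level)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d replicates (%d skipped)\n",
    nrow(x$per_replicate), x$n_skipped))
  cat(sprintf(
    "  apparent AUC %.4f | mean optimism %.4f | corrected AUC %.4f (%.3f, %.3f)\n",
    x$apparent_auc, x$mean_optimism, x$corrected_auc, x$ci[1], x$ci[2]))
  if (!is.null(x$secondary)) {
    s <- x$secondary
    cat(sprintf(
      "  secondary: apparent %.4f | optimism %.4f | corrected %.4f (%.3f, %.3f)\n",
      s$apparent_auc, s$mean_optimism, s$corrected_auc, s$ci[1], s$ci[2]))
  }
  invisible(x)
}

#' Resampling diagnostics for the BMA selection
#'
#' Tabulates (a) the posterior probability of the selected combination
#' across bootstrap replicates, (b) per-candidate posterior variable
#' probabilities across replicates, (c) leave-one-out posterior variable
#' probabilities per observation, and (d) the original-data AUC of the
#' replicate-selected combinations.
#'
#' @param matrix an `aki_matrix`.
#' @param selector a BMA selector from [make_selector()].
#' @param config a [validation_config()].
#' @param bma the [bma_config()] used for the leave-one-out reruns.
#' @param loo_max cap on the number of leave-one-out reruns (default all
#'   rows).
#' @param report optionally, an existing `"validation_report"` from
#'   [bootstrap_optimism()] with the same matrix/selector, to avoid
#'   re-running the bootstrap.
#' @return A list with data frames `bootstrap` (replicate, posterior, size,
#'   auc on original data), `bootstrap_variable_probs` (replicates x
#'   candidates), and `loo_variable_probs` (observations x candidates).
#' @export
bma_diagnostics <- function(matrix, selector, config = validation_config(),
                            bma = bma_config(), loo_max = matrix$n,
                            report = NULL) {
  if (is.null(report)) {
    report <- bootstrap_optimism(matrix, selector, config)
  }
  boot <- data.frame(
    replicate = seq_len(nrow(report$per_replicate)),
    posterior = report$per_replicate$posterior,
    size = report$per_replicate$size,
    auc_original = report$per_replicate$orig_auc
  )
  n_loo <- min(matrix$n, loo_max)
  loo <- matrix(NA_real_, n_loo, ncol(matrix$x),
                dimnames = list(matrix$subject_id[seq_len(n_loo)],
                                matrix$predictor_names))
  for (i in seq_len(n_loo)) {
    res <- run_bma(matrix_rows(matrix, setdiff(seq_len(matrix$n), i)), bma)
    loo[i, ] <- res$variable_probs
  }
  list(
    bootstrap = boot,
    bootstrap_variable_probs = report$variable_probs,
    loo_variable_probs = as.data.frame(loo)
  )
}
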