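# Pooled and center-adjusted AUC for a biomarker combination score. The
# center-adjusted AUC averages within-center Mann-Whitney AUCs, weighting
# each usable center by its number of cases, so between-center differences
# in marker distributions and event rates cannot masquerade as
# discrimination.

#' Biomarker combination score
#'
#' The linear predictor over candidate-predictor columns only: center
#' indicator and intercept terms are excluded. Within-center ranks -- and
#' hence the center-adjusted AUC -- are unaffected by the excluded terms,
#' and the score remains a pure biomarker combination.
#'
#' @param fit an `"aki_fit"` (or any vector of named coefficients).
#' @param matrix an `aki_matrix` supplying the predictor columns.
#' @return Numeric score vector, one value per row of `matrix`.
#' @export
combination_score <- function(fit, matrix) {
  coefs <- if (inherits(fit, "aki_fit")) fit$coefficients else fit
  nm <- intersect(names(coefs), colnames(matrix$x))
  extra <- setdiff(names(coefs),
                   c("(Intercept)", colnames(matrix$z), colnames(matrix$x)))
  if (length(extra) > 0) {
    stop("coefficient(s) without matching predictor column: ",
         paste(extra, collapse = ", "))
  }
  if (length(nm) == 0) return(rep(0, matrix$n))
  drop(matrix$x[, nm, drop = FALSE] %*% coefs[nm])
}

#' Pooled Mann-Whitney AUC
#'
#' Fraction of case-control pairs in which the case scores higher, ties
#' counted one half (computed via midranks).
#'
#' @param score numeric score vector.
#' @param label binary outcome vector (1 = case).
#' @return AUC in \[0, 1\].
#' @export
pooled_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Center-adjusted AUC
#'
#' Within-center Mann-Whitney AUCs averaged with weights proportional to
#' the number of cases per center (`weighting = "cases"`, the default) or
#' to the number of case-control pairs (`weighting = "pairs"`). Centers
#' lacking a case or a control contribute no information about
#' within-center discrimination and are dropped with a record of the
#' reason; this arises routinely in bootstrap resamples.
#'
#' @param score numeric score vector.
#' @param label binary outcome vector.
#' @param center center labels (factor or character).
#' @param weighting `"cases"` or `"pairs"`.
#' @return An object of class `"aki_auc"`: `auc`, `per_center` (data frame
#'   with center, cases, controls, auc), `dropped_centers`, `weighting`.
#' @export
center_adjusted_auc <- function(score, label, center,
                                weighting = c("cases", "pairs")) {
  weighting <- match.arg(weighting)
  stopifnot(length(score) == length(label), length(label) == length(center))
  centers <- unique(as.character(center))
  rows <- list()
  dropped <- character(0)
  for (cc in centers) {
    i <- as.character(center) == cc
    n1 <- sum(label[i] == 1)
    n0 <- sum(label[i] == 0)
    if (n1 == 0 || n0 == 0) {
      dropped <- c(dropped, sprintf(
        "%s (%d cases, %d controls)", cc, n1, n0))
      next
    }
    rows[[cc]] <- data.frame(center = cc, cases = n1, controls = n0,
                             auc = pooled_auc(score[i], label[i]),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("no center with both cases and controls; adjusted AUC undefined")
  }
  per_center <- do.call(rbind, rows)
  rownames(per_center) <- NULL
  w <- switch(weighting,
              cases = per_center$cases,
              pairs = per_center$cases * per_center$controls)
  structure(list(
    auc = sum(w * per_center$auc) / sum(w),
    per_center = per_center,
    dropped_centers = dropped,
    weighting = weighting
  ), class = "aki_auc")
}

#' @export
print.aki_auc <- function(x, ...) {
  cat(sprintf("<aki_auc> center-adjusted AUC = %.4f (%s-weighted, %d centers)\n",
              x$auc, x$weighting, nrow(x$per_center)))
  print(x$per_center, row.names = FALSE)
  if (length(x$dropped_centers) > 0) {
    cat("  dropped:", paste(x$dropped_centers, collapse = "; "), "\n")
  }
  invisible(x)
}

# Adjusted AUC of a fitted combination on a matrix, with the empty
# combination (no biomarkers) scoring 0.5 by convention.
adjusted_auc_of_fit <- function(fit, matrix, label = matrix$y) {
  if (is.null(fit) || mask_size(fit$mask) == 0) {
    return(list(auc = 0.5, per_center = NULL,
                dropped_centers = character(0), weighting = "cases",
                empty = TRUE))
  }
  score <- combination_score(fit, matrix)
  center_adjusted_auc(score, label, matrix$center)
}
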