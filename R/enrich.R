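# Prognostic enrichment for trial design, and the secondary
# mortality-association analysis for fixed biomarker combinations.

#' Trial design parameters
#'
#' @param power target power (default 0.90).
#' @param alpha two-sided type-I error (default 0.05).
#' @param relative_risk_reduction treatment effect: relative reduction in
#'   event risk (default 0.30).
#' @return A list of class `"trial_design"`.
#' @export
trial_design <- function(power = 0.90, alpha = 0.05,
                         relative_risk_reduction = 0.30) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1,
            relative_risk_reduction >= 0, relative_risk_reduction < 1)
  structure(list(power = power, alpha = alpha,
                 relative_risk_reduction = relative_risk_reduction),
            class = "trial_design")
}

#' Number screened per eligible patient
#'
#' Enrolling only patients above the q-th percentile of a score requires
#' screening `1 / (1 - q)` patients per enrollee (reported to one decimal).
#'
#' @param q percentile threshold in \[0, 1).
#' @return `1 / (1 - q)` (exact; round for reporting).
#' @export
number_to_screen <- function(q) {
  if (any(q < 0) || any(q >= 1)) stop("q must be in [0, 1)")
  1 / (1 - q)
}

#' Event rate among screen positives
#'
#' Event proportion among subjects whose score lies strictly above the
#' empirical q-th quantile of the score. `q = 0` means no screening: the
#' overall event rate.
#'
#' @param score numeric score vector.
#' @param outcome aligned binary outcome vector.
#' @param q percentile threshold in \[0, 1).
#' @return Event proportion among screen positives.
#' @export
screen_positive_event_rate <- function(score, outcome, q) {
  stopifnot(length(score) == length(outcome), q >= 0, q < 1)
  if (q == 0) return(mean(outcome))
  thr <- unname(quantile(score, q))
  pos <- score > thr
  if (!any(pos)) stop("no screen positives above the ", q, " quantile")
  mean(outcome[pos])
}

#' Two-arm trial sample size for a binary endpoint
#'
#' Per-arm size from the two-proportion normal approximation with unpooled
#' variance, rounded up; total is twice the per-arm size (two equal arms).
#' The treated-arm rate is `p_control * (1 - relative_risk_reduction)`.
#'
#' @param p_control control-arm event probability.
#' @param design a [trial_design()].
#' @return Total trial size (integer, even).
#' @export
two_arm_sample_size <- function(p_control, design = trial_design()) {
  stopifnot(p_control > 0, p_control < 1)
  if (design$relative_risk_reduction == 0) {
    stop("relative risk reduction of 0 implies an infinite trial")
  }
  p1 <- p_control
  p2 <- p_control * (1 - design$relative_risk_reduction)
  za <- qnorm(1 - design$alpha / 2)
  zb <- qnorm(design$power)
  n_arm <- ceiling((za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) /
                     (p1 - p2)^2)
  as.integer(2 * n_arm)
}

#' Monte-Carlo power of a two-proportion trial
#'
#' Simulates trials of `n_total` subjects split into two equal arms with
#' event probabilities `p_control` and
#' `p_control * (1 - relative_risk_reduction)`, analyzed by the pooled
#' two-proportion z-test. Serves as the independent check on
#' [two_arm_sample_size()].
#'
#' @param n_total total trial size (even).
#' @param p_control control-arm event probability.
#' @param design a [trial_design()].
#' @param nsim simulated trials (default 10000).
#' @param seed integer seed.
#' @return Estimated power (rejection fraction).
#' @export
simulate_trial_power <- function(n_total, p_control,
                                 design = trial_design(),
                                 nsim = 10000L, seed = 1L) {
  n_arm <- floor(n_total / 2)
  p2 <- p_control * (1 - design$relative_risk_reduction)
  zcrit <- qnorm(1 - design$alpha / 2)
  with_seed(seed, {
    x1 <- rbinom(nsim, n_arm, p_control)
    x2 <- rbinom(nsim, n_arm, p2)
    ph1 <- x1 / n_arm
    ph2 <- x2 / n_arm
    pp <- (x1 + x2) / (2 * n_arm)
    se <- sqrt(pp * (1 - pp) * (2 / n_arm))
    z <- ifelse(se > 0, (ph1 - ph2) / se, 0)
    mean(abs(z) > zcrit)
  })
}

#' Prognostic-enrichment table
#'
#' One row per (threshold percentile, combination): the number screened per
#' eligible patient, the event rate among screen positives, and the total
#' trial size required at that event rate under the shared design --
#' preceded by the unscreened row using the overall event rate.
#'
#' @param scores named list of score vectors, one per combination.
#' @param outcome aligned binary outcome vector (e.g. severe AKI).
#' @param percentiles threshold percentiles (default 0, .25, .5, .75; 0 is
#'   reported once as the unscreened row).
#' @param design a [trial_design()].
#' @return A data frame with columns `threshold_percentile`,
#'   `number_to_screen`, `combination`, `event_rate_screen_pos`,
#'   `total_sample_size`.
#' @export
enrichment_table <- function(scores, outcome,
                             percentiles = c(0, 0.25, 0.5, 0.75),
                             design = trial_design()) {
  stopifnot(is.list(scores), length(scores) >= 1)
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- paste0("combination_", seq_along(scores))
  }
  rows <- list()
  for (q in sort(unique(percentiles))) {
    if (q == 0) {
      rate <- mean(outcome)
      rows[[length(rows) + 1]] <- data.frame(
        threshold_percentile = 0, number_to_screen = 1,
        combination = "(none)", event_rate_screen_pos = rate,
        total_sample_size = two_arm_sample_size(rate, design),
        stringsAsFactors = FALSE)
      next
    }
    for (nm in names(scores)) {
      rate <- tryCatch(screen_positive_event_rate(scores[[nm]], outcome, q),
                       error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        threshold_percentile = q,
        number_to_screen = round(number_to_screen(q), 1),
        combination = nm, event_rate_screen_pos = rate,
        total_sample_size = if (is.na(rate) || rate <= 0 || rate >= 1)
          NA_integer_ else two_arm_sample_size(rate, design),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Center-adjusted association of a fixed combination with death
#'
#' The combination score (coefficients fixed, not re-estimated) is
#' standardized to unit sample SD and entered into a logistic regression
#' for death with center-specific intercepts. Reported as the odds ratio
#' per SD of the score with a Wald confidence interval. Subjects missing
#' the score or the death outcome are excluded.
#'
#' @param score numeric combination score (may contain `NA`).
#' @param death binary death outcome (may contain `NA`).
#' @param center aligned center labels.
#' @param label name for the result (e.g. `"max-posterior"`).
#' @param ci_level confidence level (default 0.95).
#' @return A list of class `"aki_association"`: `odds_ratio_per_sd`, `ci`,
#'   `n_used`, `outcome`, `coef`, `se`.
#' @export
mortality_association <- function(score, death, center,
                                  label = "combination", ci_level = 0.95) {
  stopifnot(length(score) == length(death), length(death) == length(center))
  keep <- !is.na(score) & !is.na(death)
  score <- score[keep]; death <- as.integer(death[keep])
  center <- factor(as.character(center[keep]))
  if (length(unique(death)) < 2) stop("death outcome degenerate")
  s <- sd(score)
  if (!is.finite(s) || s == 0) stop("zero-variance combination score")
  zsc <- (score - mean(score)) / s

  levels_c <- levels(center)
  z <- matrix(0, length(zsc), max(length(levels_c) - 1, 0))
  if (length(levels_c) > 1) {
    for (j in seq_along(levels_c)[-1]) z[center == levels_c[j], j - 1] <- 1
    colnames(z) <- paste0("center", levels_c[-1])
  }
  X <- cbind(`(Intercept)` = 1, z, score_sd = zsc)
  # a center with no deaths quasi-separates its forced indicator; the
  # likelihood still stabilizes and the score coefficient is well-behaved
  f <- cpp_fit_logistic(X, as.numeric(death), 100L, 1e-8, numeric(0), TRUE)
  if (f$singular || !(f$converged || f$ll_converged) || is.null(f$cov)) {
    stop("mortality model failed to converge")
  }
  k <- ncol(X)
  est <- drop(f$coefficients)[k]
  se <- sqrt(diag(f$cov))[k]
  zc <- qnorm(1 - (1 - ci_level) / 2)
  structure(list(
    odds_ratio_per_sd = exp(est),
    ci = exp(c(est - zc * se, est + zc * se)),
    n_used = length(zsc),
    outcome = label,
    coef = est,
    se = se
  ), class = "aki_association")
}

#' @export
print.aki_association <- function(x, ...) {
  cat(sprintf(
    "<aki_association> %s: OR per SD %.3f (%.3f, %.3f), n = %d\n",
    x$outcome, x$odds_ratio_per_sd, x$ci[1], x$ci[2], x$n_used))
  invisible(x)
}
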