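# Fixtures are built in code. sim_matrix() fabricates an analysis matrix
# directly (gaussian candidates, optional center structure and planted
# logistic signal); cohort-level fixtures come from the package generator.

sim_matrix <- function(n, p, beta = rep(0, p), n_center = 2, seed = 1,
                       intercept = -2, center_outcome = rep(0, n_center),
                       center_shift = rep(0, n_center)) {
  akibma:::with_seed(seed, {
    centers <- sort(sample(seq_len(n_center), n, replace = TRUE))
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    x <- x + center_shift[centers]
    eta <- intercept + drop(x %*% beta) + center_outcome[centers]
    y <- rbinom(n, 1, plogis(eta))
    labels <- as.character(seq_len(n_center))
    center <- factor(labels[centers], levels = labels)
    if (n_center > 1) {
      z <- matrix(0, n, n_center - 1,
                  dimnames = list(NULL, paste0("center", labels[-1])))
      for (j in seq_len(n_center)[-1]) z[centers == j, j - 1] <- 1
    } else {
      z <- matrix(numeric(0), n, 0)
    }
    structure(list(
      x = x, z = z, y = y, center = center,
      subject_id = sprintf("S%04d", seq_len(n)),
      predictor_names = colnames(x),
      outcome = "y", reference_center = labels[1], n = n
    ), class = "aki_matrix")
  })
}

tiny_cohort <- function(n = 12, seed = 42, ...) {
  generate_cohort(cohort_config(n = n, preset = "tiny", seed = seed,
                                ...))$cohort
}

# glm reference fit of a candidate mask on an aki_matrix
glm_fit_mask <- function(m, mask) {
  idx <- mask_indices(mask, ncol(m$x))
  df <- data.frame(y = m$y)
  X <- cbind(m$z, m$x[, idx, drop = FALSE])
  if (ncol(X) > 0) df <- cbind(df, as.data.frame(X))
  stats::glm(y ~ ., data = df, family = stats::binomial(),
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
}
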