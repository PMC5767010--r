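test_that("exhaustive search enumerates the full model space", {
  m <- sim_matrix(80, 3, seed = 1)
  masks <- candidate_models(m, bma_config())
  expect_equal(sort(masks), 0:7)
})

test_that("equal-BIC models of equal size share the posterior evenly", {
  fits <- list(mask = c(1L, 2L), size = c(1L, 1L), loglik = c(-50, -50),
               df = c(2L, 2L), bic = c(104.6, 104.6),
               converged = c(TRUE, TRUE), coefficients = NULL,
               coef_names = NULL, n = 100)
  res <- posterior_probabilities(fits, bma_config(), p = 2,
                                 predictor_names = c("a", "b"))
  expect_equal(res$models$posterior, c(0.5, 0.5))
  # exact tie resolves to the lexicographically smaller bitmask
  expect_equal(res$max_model, 1L)
})

test_that("posteriors match brute-force enumeration with exact fits", {
  m <- sim_matrix(120, 4, beta = c(1, 0.4, 0, 0), seed = 9)
  res <- run_bma(m, bma_config(occam_ratio = Inf))
  # independent oracle: all 16 glm fits, full Bayes-factor normalization
  p <- 4
  masks <- 0:15
  bic <- vapply(masks, function(mk) BIC(glm_fit_mask(m, mk)), numeric(1))
  size <- mask_size(masks)
  w <- exp(-0.5 * (bic - min(bic))) * 0.5^size * 0.5^(p - size)
  post <- w / sum(w)
  ord <- match(res$models$mask, masks)
  expect_equal(res$models$posterior, post[ord], tolerance = 1e-10)
  vp <- vapply(seq_len(p), function(j) {
    sum(post[bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L])
  }, numeric(1))
  expect_equal(unname(res$variable_probs), vp, tolerance = 1e-10)
})

test_that("posterior bookkeeping invariants hold on a mixed-signal fit", {
  m <- sim_matrix(400, 6, beta = c(0.9, 0.5, 0.2, 0, 0, 0), seed = 30,
                  n_center = 3)
  res <- run_bma(m)
  expect_equal(sum(res$models$posterior), 1, tolerance = 1e-12)
  expect_true(all(res$variable_probs >= 0 & res$variable_probs <= 1))
  for (j in seq_len(res$p)) {
    contains <- bitwAnd(res$models$mask, bitwShiftL(1L, j - 1L)) != 0L
    if (any(contains)) {
      expect_gte(res$variable_probs[j],
                 max(res$models$posterior[contains]) - 1e-12)
    }
  }
  # Occam's window: no retained model worse than the best by > the ratio
  expect_true(all(res$models$posterior >=
                    max(res$models$posterior) / res$occam_ratio - 1e-12))
  # determinism
  res2 <- run_bma(m)
  expect_identical(res$models, res2$models)
  expect_identical(res$variable_probs, res2$variable_probs)
})

test_that("a strongly planted predictor is near-certainly included", {
  m <- sim_matrix(2000, 3, beta = c(1.2, 0, 0), seed = 8)
  res <- run_bma(m)
  expect_gt(res$variable_probs[["x1"]], 0.99)
  expect_true(bitwAnd(res$max_model, 1L) == 1L)
})

test_that("under the null the median probability model is usually empty", {
  empty <- vapply(1:20, function(s) {
    m <- sim_matrix(900, 10, seed = 400 + s, n_center = 3)
    res <- run_bma(m, bma_config(search = "leaps"))
    mask_size(select_median_probability(res)) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("selection rules read the posterior as specified", {
  m <- sim_matrix(600, 4, beta = c(1, 0.5, 0, 0), seed = 3)
  res <- run_bma(m)
  expect_equal(select_max_posterior(res), res$models$mask[1])
  med <- select_median_probability(res)
  expect_equal(med, mask_from_indices(which(res$variable_probs > 0.5)))
  # a probability of exactly 0.5 is excluded ("exceeding")
  res2 <- res
  res2$variable_probs[] <- c(1, 0.5, 0.2, 0.5)
  res2$median_model <- mask_from_indices(which(res2$variable_probs > 0.5))
  expect_equal(mask_names(res2$median_model, res2$predictor_names), "x1")
})

test_that("prior inclusion probability near 1 forces the full model", {
  m <- sim_matrix(300, 3, seed = 14)
  res <- run_bma(m, bma_config(prior_pi = 0.999))
  expect_equal(res$max_model, 7L)
  expect_true(all(res$variable_probs > 0.99))
})

test_that("posterior of the null model grows with n on null data", {
  post_null <- vapply(c(200, 2000, 20000), function(n) {
    m <- sim_matrix(n, 3, seed = 99)
    res <- run_bma(m, bma_config(occam_ratio = Inf))
    res$models$posterior[res$models$mask == 0L]
  }, numeric(1))
  expect_true(all(diff(post_null) > 0))
})

test_that("collinear duplicate candidates are dropped, not mis-fit", {
  m <- sim_matrix(200, 3, beta = c(0.8, 0, 0), seed = 6)
  m$x[, 2] <- m$x[, 1]  # exact duplicate
  expect_warning(res <- run_bma(m), "did not converge")
  # models containing both collinear columns cannot be retained
  both <- bitwAnd(res$models$mask, 3L) == 3L
  expect_false(any(both))
})
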