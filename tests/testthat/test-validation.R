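test_that("corrected AUC is exactly apparent minus mean optimism", {
  m <- sim_matrix(300, 4, beta = c(0.8, 0.4, 0, 0), seed = 51, n_center = 2)
  sel <- make_selector("bma-max", bma = bma_config())
  rep <- bootstrap_optimism(m, sel, validation_config(n_boot = 25, seed = 2))
  expect_identical(rep$corrected_auc, rep$apparent_auc - rep$mean_optimism)
  expect_equal(rep$mean_optimism, mean(rep$per_replicate$optimism))
  expect_equal(nrow(rep$per_replicate) + rep$n_skipped, 25)
  # replicate-level variable probabilities are recorded for BMA selectors
  expect_equal(dim(rep$variable_probs), c(25, 4))
})

test_that("validation is reproducible given data, config and seed", {
  m <- sim_matrix(250, 3, beta = c(0.7, 0, 0), seed = 52, n_center = 2)
  sel <- make_selector("bma-max")
  cfg <- validation_config(n_boot = 15, seed = 9)
  r1 <- bootstrap_optimism(m, sel, cfg)
  r2 <- bootstrap_optimism(m, sel, cfg)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_identical(r1$ci, r2$ci)
})

test_that("a fixed combination carries only refit optimism, which is small", {
  m <- sim_matrix(900, 5, beta = c(0.8, 0.5, 0, 0, 0), seed = 53,
                  n_center = 3)
  sel <- make_selector("fixed", mask = mask_from_indices(1:2))
  rep <- bootstrap_optimism(m, sel,
                            validation_config(n_boot = 200, seed = 3))
  expect_lt(abs(rep$mean_optimism), 0.01)
  expect_equal(rep$apparent$mask, mask_from_indices(1:2))
})

test_that("empty selections score 0.5 and do not break the bootstrap", {
  m <- sim_matrix(200, 3, seed = 54, n_center = 2)
  sel <- make_selector("fixed", mask = 0L)
  expect_warning(ap <- apparent_performance(m, sel), "empty")
  expect_equal(ap$performance$auc, 0.5)
  rep <- suppressWarnings(
    bootstrap_optimism(m, sel, validation_config(n_boot = 25, seed = 4)))
  expect_equal(rep$apparent_auc, 0.5)
  expect_true(all(rep$per_replicate$optimism == 0))
  # degenerate case: every replicate equal -> CI collapses to the point
  expect_equal(rep$ci, c(0.5, 0.5))
})

test_that("optimism-shifted CI is the shifted percentile interval", {
  m <- sim_matrix(350, 4, beta = c(0.9, 0.4, 0, 0), seed = 55, n_center = 2)
  sel <- make_selector("bma-max")
  rep <- bootstrap_optimism(m, sel, validation_config(n_boot = 40, seed = 5))
  expect_equal(rep$ci,
               pmin(pmax(unname(
                 quantile(rep$per_replicate$boot_auc, c(0.025, 0.975))) -
                   rep$mean_optimism, 0), 1))
  # endpoints bracket the corrected AUC when apparent sits inside its own CI
  if (rep$apparent_auc >= quantile(rep$per_replicate$boot_auc, 0.025) &&
      rep$apparent_auc <= quantile(rep$per_replicate$boot_auc, 0.975)) {
    expect_gte(rep$corrected_auc, rep$ci[1])
    expect_lte(rep$corrected_auc, rep$ci[2])
  }
  few <- rep
  few$per_replicate <- rep$per_replicate[1:10, ]
  expect_error(optimism_shifted_ci(few, rep$config), "20")
})

test_that("cross-outcome evaluation reuses the primary-outcome combination", {
  m <- sim_matrix(400, 4, beta = c(0.9, 0.5, 0, 0), seed = 56, n_center = 2)
  sel <- make_selector("bma-max")
  cfg <- validation_config(n_boot = 20, seed = 6)
  # secondary outcome identical to the primary -> identical AUCs throughout
  rep <- bootstrap_optimism(m, sel, cfg, secondary = m$y)
  expect_equal(rep$secondary$apparent_auc, rep$apparent_auc)
  expect_equal(rep$per_replicate$sec_boot, rep$per_replicate$boot_auc)
  expect_equal(rep$secondary$corrected_auc, rep$corrected_auc)
  expect_error(bootstrap_optimism(m, sel, cfg, secondary = rep(0, m$n)),
               "degenerate")
})

test_that("nested severe outcome tracks the mild-AKI AUC", {
  sim <- generate_cohort(cohort_config(n = 1600, seed = 57, miss_rate = 0))
  m <- build_analysis_matrix(sim$cohort)
  sev <- sim$cohort$severe_aki[!is.na(sim$cohort$mild_aki)]
  fit <- fit_logistic(m, mask_from_names(c("pntprobnp", "phfabp", "delta_cr"),
                                         m$predictor_names))
  sc <- combination_score(fit, m)
  auc_mild <- center_adjusted_auc(sc, m$y, m$center)$auc
  auc_sev <- center_adjusted_auc(sc, sev, m$center)$auc
  expect_lt(abs(auc_mild - auc_sev), 0.05)
})

test_that("diagnostics tables have the documented shapes", {
  m <- sim_matrix(60, 3, beta = c(1, 0, 0), seed = 58, n_center = 2)
  sel <- make_selector("bma-max")
  rep <- suppressWarnings(
    bootstrap_optimism(m, sel, validation_config(n_boot = 8, seed = 7)))
  diag <- bma_diagnostics(m, sel, report = rep)
  n_used <- 8 - rep$n_skipped
  expect_equal(dim(diag$bootstrap_variable_probs), c(n_used, 3))
  expect_equal(dim(diag$loo_variable_probs), c(60, 3))
  expect_equal(nrow(diag$bootstrap), n_used)
  # duplicated observation -> identical leave-one-out rows
  m2 <- matrix_rows(m, c(seq_len(m$n), 1L))
  diag2 <- bma_diagnostics(m2, sel, validation_config(n_boot = 1, seed = 7))
  expect_equal(unname(unlist(diag2$loo_variable_probs[1, ])),
               unname(unlist(diag2$loo_variable_probs[61, ])))
})
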