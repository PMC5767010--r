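test_that("number to screen is the reciprocal survivor fraction", {
  expect_equal(number_to_screen(0.75), 4)
  expect_equal(number_to_screen(0.5), 2)
  expect_equal(round(number_to_screen(0.25), 1), 1.3)
  expect_equal(number_to_screen(0), 1)
  expect_error(number_to_screen(1), "\\[0, 1\\)")
})

test_that("screen-positive event rates behave at the boundaries", {
  set.seed(71)
  outcome <- rbinom(10000, 1, 0.05)
  noise <- rnorm(10000)
  expect_equal(screen_positive_event_rate(noise, outcome, 0), mean(outcome))
  # uninformative score: screening leaves the rate unchanged
  r75 <- screen_positive_event_rate(noise, outcome, 0.75)
  expect_lt(abs(r75 - mean(outcome)), 0.02)
  # perfectly ranking score with 5% events: the top 5% are all events
  perfect <- rank(outcome, ties.method = "first")
  expect_equal(screen_positive_event_rate(perfect, outcome, 0.95), 1.0)
  expect_error(screen_positive_event_rate(rep(1, 10), rep(0:1, 5), 0.5),
               "no screen positives")
})

test_that("trial size shrinks with larger effects or higher event rates", {
  d30 <- trial_design(relative_risk_reduction = 0.30)
  d50 <- trial_design(relative_risk_reduction = 0.50)
  expect_lt(two_arm_sample_size(0.047, d50), two_arm_sample_size(0.047, d30))
  expect_lt(two_arm_sample_size(0.08, d30), two_arm_sample_size(0.047, d30))
  expect_equal(two_arm_sample_size(0.047, d30) %% 2, 0)
  expect_error(two_arm_sample_size(0.047,
                                   trial_design(relative_risk_reduction = 0)),
               "infinite")
})

test_that("computed sizes deliver close to nominal Monte-Carlo power", {
  des <- trial_design()
  n <- two_arm_sample_size(0.047, des)
  pw <- simulate_trial_power(n, 0.047, des, nsim = 4000, seed = 8)
  expect_gt(pw, 0.87)
  expect_lt(pw, 0.93)
})

test_that("enrichment tables are internally consistent and monotone", {
  set.seed(72)
  n <- 8000
  score <- rnorm(n)
  outcome <- rbinom(n, 1, plogis(-3.3 + 1.2 * score))
  tab <- enrichment_table(list(combo = score), outcome)
  expect_equal(tab$number_to_screen[tab$threshold_percentile == 0], 1)
  expect_equal(tab$combination[tab$threshold_percentile == 0], "(none)")
  expect_equal(tab$number_to_screen,
               round(1 / (1 - tab$threshold_percentile), 1))
  expect_true(all(diff(tab$event_rate_screen_pos) > 0))
  expect_true(all(diff(tab$total_sample_size) < 0))
  # row-level consistency: size recomputed from the row's own event rate
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$total_sample_size[i],
                 two_arm_sample_size(tab$event_rate_screen_pos[i]))
  }
  # degenerate constant score: flagged rows, not an error
  tab2 <- enrichment_table(list(flat = rep(1, n)), outcome)
  expect_true(all(is.na(tab2$event_rate_screen_pos[
    tab2$threshold_percentile > 0])))
  expect_false(anyNA(tab2$event_rate_screen_pos[
    tab2$threshold_percentile == 0]))
})

test_that("mortality association is standardized and scale invariant", {
  set.seed(73)
  n <- 5000
  center <- sample(c("A", "B", "C"), n, replace = TRUE)
  score <- rnorm(n) + 0.5 * (center == "B")
  gamma <- log(1.6)  # log-odds per SD of score
  zsc <- (score - mean(score)) / sd(score)
  death <- rbinom(n, 1, plogis(-3 + gamma * zsc + 0.4 * (center == "C")))
  est <- mortality_association(score, death, center)
  expect_gt(est$ci[2], est$odds_ratio_per_sd)
  expect_lt(est$ci[1], est$odds_ratio_per_sd)
  expect_lt(abs(est$coef - gamma), 3 * est$se)
  # positive rescaling leaves the per-SD odds ratio unchanged
  est3 <- mortality_association(3 * score, death, center)
  expect_equal(est3$odds_ratio_per_sd, est$odds_ratio_per_sd,
               tolerance = 1e-8)
  # missing scores and outcomes are excluded, not propagated
  score2 <- score; score2[1:100] <- NA
  death2 <- death; death2[101:150] <- NA
  est2 <- mortality_association(score2, death2, center)
  expect_equal(est2$n_used, n - 150)
  expect_error(mortality_association(rep(2, n), death, center),
               "zero-variance")
  expect_error(mortality_association(score, rep(0, n), center),
               "degenerate")
})

test_that("null-score confidence intervals cover an odds ratio of one", {
  covered <- vapply(1:40, function(s) {
    akibma:::with_seed(7000 + s, {
      n <- 1500
      center <- sample(c("A", "B"), n, replace = TRUE)
      score <- rnorm(n)
      death <- rbinom(n, 1, 0.08)
      est <- mortality_association(score, death, center)
      est$ci[1] <= 1 && 1 <= est$ci[2]
    })
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
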