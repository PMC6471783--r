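test_that("null model reproduces the baseline event rate", {
  d <- generate_design(10, 9, 2, seed = 3)
  p0 <- 0.01
  cells <- simulate_trial(d, sim_params(
    baseline_event_rate = p0, treatment_log_or = 0, centre_effect_sd = 0,
    centre_trend_sd = 0, deliveries_mean = 2000,
    deliveries_cluster_cv = 0), seed = 4)
  n <- sum(cells$deliveries)
  rate <- sum(cells$events) / n
  mc_se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(rate - p0), 3 * mc_se)
})

test_that("simulated tables are reproducible and structurally valid", {
  d <- generate_design(8, 4, 2, seed = 5)
  p <- sim_params(baseline_event_rate = 0.005, treatment_log_or = -0.2)
  c1 <- simulate_trial(d, p, seed = 11)
  c2 <- simulate_trial(d, p, seed = 11)
  expect_identical(c1, c2)
  for (seed in 1:5)
    expect_silent(validate_cluster_periods(simulate_trial(d, p, seed = seed)))
})

test_that("zero-delivery cells carry zero events", {
  d <- generate_design(6, 3, 1, seed = 2)
  cells <- simulate_trial(d, sim_params(
    baseline_event_rate = 0.4, deliveries_mean = 1,
    deliveries_cluster_cv = 0), seed = 9)
  expect_gt(sum(cells$deliveries == 0), 0) # Poisson(1) produces empty cells
  expect_true(all(cells$events[cells$deliveries == 0] == 0))
})

test_that("realised event rate matches the design-weighted mean cell probability", {
  d <- generate_design(10, 5, 2, seed = 6)
  cells <- simulate_trial(d, sim_params(
    baseline_event_rate = 0.02, treatment_log_or = log(0.7),
    centre_effect_sd = 0.4, centre_trend_sd = 0.01,
    deliveries_mean = 3000), seed = 13)
  p <- attr(cells, "truth")$cell_prob
  expected <- sum(cells$deliveries * p) / sum(cells$deliveries)
  observed <- sum(cells$events) / sum(cells$deliveries)
  mc_se <- sqrt(sum(cells$deliveries * p * (1 - p))) / sum(cells$deliveries)
  expect_lt(abs(observed - expected), 3 * mc_se)
})

test_that("cluster-period invariant violations are caught", {
  cells <- flat_cells()
  bad <- cells; bad$events[1] <- bad$deliveries[1] + 1
  expect_error(validate_cluster_periods(bad), "events exceed")
  bad <- cells; bad$treated <- rev(bad$treated)
  expect_error(validate_cluster_periods(bad), "reverts")
  bad <- cells; bad$deliveries[2] <- -1
  expect_error(validate_cluster_periods(bad), "non-negative")
})

test_that("implementation measures are seed-stable and decoupled at zero coupling", {
  d <- generate_design(10, 9, 2, seed = 1)
  lo <- log(seq(0.4, 1.2, length.out = 10))
  m1 <- simulate_implementation(d, lo, coupling = 0, noise_sd = 0.2, seed = 8)
  m2 <- simulate_implementation(d, lo, coupling = 0, noise_sd = 0.2, seed = 8)
  expect_identical(m1, m2)
  # at zero coupling the values do not depend on the true effects at all
  m3 <- simulate_implementation(d, rev(lo), coupling = 0, noise_sd = 0.2,
                                seed = 8)
  expect_identical(m1$value, m3$value)
})

test_that("noiseless coupled measures order clusters by benefit", {
  d <- generate_design(10, 9, 2, seed = 1)
  lo <- log(seq(0.4, 1.2, length.out = 10)) # cluster 1 most protective
  m <- simulate_implementation(d, lo, coupling = 1, noise_sd = 0,
                               seed = 2, censor_adoption = FALSE)
  sc <- composite_scores(m)
  benefit <- -lo[match(sc$cluster_id, d$cluster_id)]
  expect_identical(order(sc$composite), order(benefit))
})

test_that("adoption is right-censored for the latest-crossing clusters by default", {
  d <- generate_design(10, 9, 2, seed = 1)
  m <- simulate_implementation(d, 0, seed = 3)
  late <- d$cluster_id[d$step > d$n_steps - 2L]
  adopt <- m[m$measure_name == "adoption_6m_pct", ]
  expect_true(all(is.na(adopt$value[adopt$cluster_id %in% late])))
  expect_true(all(!is.na(adopt$value[!adopt$cluster_id %in% late])))
})

test_that("treatment null with no trends keeps the Wald test at its nominal size", {
  # correctly specified fixed-centre-effects model, model-based SE
  set.seed(101)
  n_rep <- 500
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- generate_design(10, 9, 2, seed = 1000 + r)
    cells <- simulate_trial(d, sim_params(
      baseline_event_rate = 0.01, treatment_log_or = 0,
      centre_effect_sd = 0.3, centre_trend_sd = 0,
      deliveries_mean = 500, deliveries_cluster_cv = 0.3), seed = 2000 + r)
    fit <- fit_logistic(cells, per_centre_trends = FALSE)
    z <- fit$coefficients["treated"] /
      sqrt(fit$vcov_model["treated", "treated"])
    rej[r] <- abs(z) > qnorm(0.975)
  }
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
})
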