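test_that("a flat event rate yields a null treatment effect and the right intercept", {
  cells <- flat_cells(p = 0.05, deliveries = 1000)
  fit <- fit_logistic(cells, per_site = TRUE)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["treated"]), 0, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["(Intercept)"]), qlogis(0.05),
               tolerance = 1e-8)
})

test_that("a saturated two-cell fit equals the closed-form log odds ratio", {
  # intercept + treatment on one control and one treated cell
  a <- 30; b <- 470; c <- 12; d <- 488
  X <- cbind(`(Intercept)` = 1, treated = c(0, 1))
  fit <- swpeval:::irls_binom(X, events = c(c, a), deliveries = c(c + d, a + b))
  expect_equal(unname(fit$coefficients["treated"]),
               log((a * d) / (b * c)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov_model))["treated"]),
               sqrt(1 / a + 1 / b + 1 / c + 1 / d), tolerance = 1e-6)
})

test_that("IRLS matches brute-force likelihood maximisation and glm on a 3-parameter site", {
  set.seed(31)
  period <- 0:19
  treated <- as.integer(period >= 8)
  eta <- qlogis(0.02) - 0.01 * period + log(0.7) * treated
  cells <- data.frame(cluster_id = "S1", period = period, treated = treated,
                      deliveries = 2000,
                      events = rbinom(20, 2000, plogis(eta)))
  fit <- fit_logistic(cells, per_site = TRUE)
  expect_true(fit$converged)
  # within 3 SE of the generating effect
  se <- sqrt(fit$vcov_model["treated", "treated"])
  expect_lt(abs(coef(fit)["treated"] - log(0.7)), 3 * se)
  # independent brute-force coordinate search on the same likelihood
  bf <- brute_force_logit(fit$X, cells$events, cells$deliveries)
  expect_equal(unname(coef(fit)), bf, tolerance = 1e-4)
  # and glm as a second independent reference
  g <- glm(cbind(events, deliveries - events) ~ I(period - mean(period)) +
             treated, binomial, data = cells)
  expect_equal(unname(coef(fit)["treated"]), unname(coef(g)["treated"]),
               tolerance = 1e-8)
})

test_that("the multi-site fit with centre effects and trends matches glm", {
  d <- generate_design(6, 3, 2, seed = 2)
  cells <- simulate_trial(d, sim_params(
    baseline_event_rate = 0.02, treatment_log_or = -0.3,
    deliveries_mean = 500), seed = 5)
  fit <- fit_logistic(cells)
  g <- glm(cbind(events, deliveries - events) ~ 0 + factor(cluster_id) +
             factor(cluster_id):I(period - mean(period)) + treated,
           binomial, data = cells)
  expect_equal(sort(unname(coef(fit))), sort(unname(coef(g))),
               tolerance = 1e-8)
})

test_that("treatment coefficient is invariant to period recentring", {
  d <- generate_design(5, 2, 2, seed = 4)
  cells <- simulate_trial(d, sim_params(baseline_event_rate = 0.05,
                                        deliveries_mean = 400), seed = 6)
  b0 <- coef(fit_logistic(cells))["treated"]
  shifted <- cells
  shifted$period <- shifted$period + 7L
  expect_equal(coef(fit_logistic(shifted))["treated"], b0, tolerance = 1e-7)
})

test_that("adding events only to treated cells raises the treatment coefficient", {
  d <- generate_design(6, 3, 2, seed = 8)
  cells <- simulate_trial(d, sim_params(baseline_event_rate = 0.03,
                                        deliveries_mean = 600), seed = 9)
  b0 <- coef(fit_logistic(cells))["treated"]
  bumped <- cells
  sel <- bumped$treated == 1 & bumped$deliveries > bumped$events + 2
  bumped$events[sel] <- bumped$events[sel] + 2L
  expect_gt(coef(fit_logistic(bumped))["treated"], b0)
})

test_that("separation is flagged as non-convergence, not silent output", {
  cells <- flat_cells(p = 0.05, deliveries = 200)
  cells$events[cells$treated == 1] <- 0
  cells$events[cells$treated == 0] <- 50
  expect_warning(fit <- fit_logistic(cells, per_site = TRUE),
                 "converge")
  expect_false(fit$converged)
  expect_error(cluster_robust_cov(fit), "converged")
})

test_that("duplicating every cluster shrinks robust SEs by the exact small-sample law", {
  d <- generate_design(8, 4, 2, seed = 12)
  cells <- simulate_trial(d, sim_params(baseline_event_rate = 0.03,
                                        deliveries_mean = 800), seed = 13)
  fit <- fit_logistic(cells, per_site = TRUE) # common model across clusters
  se1 <- sqrt(cluster_robust_cov(fit)["treated", "treated"])
  dup <- cells
  dup$cluster_id <- paste0(dup$cluster_id, "_copy")
  both <- rbind(cells, dup)
  fit2 <- fit_logistic(both, per_site = TRUE)
  se2 <- sqrt(cluster_robust_cov(fit2)["treated", "treated"])
  G <- length(unique(cells$cluster_id))
  # bread halves, meat doubles, correction G/(G-1) -> (2G)/(2G-1)
  exact <- sqrt(((2 * G / (2 * G - 1)) / 2) * ((G - 1) / G))
  expect_equal(se2 / se1, exact, tolerance = 1e-8)
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.05)
})

test_that("robust and model SEs agree on a well-specified independent-cluster design", {
  set.seed(14)
  G <- 60
  treated <- rep(c(0L, 1L), each = G / 2)
  cells <- data.frame(cluster_id = sprintf("K%02d", 1:G), period = 0:1,
                      treated = treated, deliveries = 5000)
  eta <- qlogis(0.04) + 0.3 * cells$treated
  cells$events <- rbinom(G, cells$deliveries, plogis(eta))
  fit <- fit_logistic(cells, per_site = TRUE)
  se_m <- sqrt(fit$vcov_model["treated", "treated"])
  se_r <- sqrt(cluster_robust_cov(fit)["treated", "treated"])
  expect_lt(abs(se_r / se_m - 1), 0.1)
})

test_that("robust confidence intervals attain nominal coverage over replicates", {
  set.seed(21)
  n_rep <- 500
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    G <- 40
    treated_cl <- rep(c(0L, 1L), each = G / 2)
    u <- rnorm(G, 0, 0.3)                  # cluster heterogeneity
    cells <- data.frame(
      cluster_id = rep(sprintf("K%02d", 1:G), each = 2),
      period = rep(0:1, G),
      treated = rep(treated_cl, each = 2),
      deliveries = 400)
    eta <- qlogis(0.05) + rep(u, each = 2) + log(0.7) * cells$treated
    cells$events <- rbinom(nrow(cells), cells$deliveries, plogis(eta))
    fit <- fit_logistic(cells, per_site = TRUE)
    se_r <- sqrt(cluster_robust_cov(fit)["treated", "treated"])
    b <- coef(fit)["treated"]
    cover[r] <- b - qnorm(0.975) * se_r <= log(0.7) &&
      log(0.7) <= b + qnorm(0.975) * se_r
  }
  half <- qnorm(0.995) * sqrt(0.95 * 0.05 / n_rep)
  expect_gt(mean(cover), 0.95 - half)
  expect_lt(mean(cover), 0.95 + half)
})

test_that("site effects require both arms and feed the meta layer", {
  d <- generate_design(4, 2, 2, seed = 15)
  cells <- simulate_trial(d, sim_params(baseline_event_rate = 0.05,
                                        deliveries_mean = 1000), seed = 16)
  eff <- site_effects(cells)
  expect_equal(nrow(eff), 4L)
  expect_true(all(eff$se > 0))
  one <- cells[cells$cluster_id == "C01", ]
  e <- site_effect(one)
  expect_s3_class(e, "effect_estimate")
  expect_equal(e$label, "C01")
  pre_only <- one[one$treated == 0, ]
  expect_error(site_effect(pre_only), "control or intervention")
  expect_error(site_effect(cells), "single cluster")
})

test_that("a trend-adjusted site fit removes secular-trend bias that the raw 2x2 keeps", {
  set.seed(23)
  n_rep <- 120
  adj <- raw <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    period <- 0:19
    treated <- as.integer(period >= 10)
    eta <- qlogis(0.02) + 0.06 * period   # strong rising trend, null effect
    deliveries <- rep(1500L, 20)
    events <- rbinom(20, deliveries, plogis(eta))
    cells <- data.frame(cluster_id = "S", period = period, treated = treated,
                        deliveries = deliveries, events = events)
    adj[r] <- suppressWarnings(site_effect(cells)$log_effect)
    a <- sum(events[treated == 1]); b <- sum(deliveries[treated == 1]) - a
    cc <- sum(events[treated == 0]); dd <- sum(deliveries[treated == 0]) - cc
    raw[r] <- odds_ratio(a, b, cc, dd)$log_effect
  }
  expect_gt(mean(raw), 0.5)                       # heavily biased upward
  expect_lt(abs(mean(adj)), 3 * sd(adj) / sqrt(n_rep)) # centred on the null
})

test_that("single-site fixture coefficients are bit-stable across runs", {
  cells <- data.frame(cluster_id = "F", period = 0:9,
                      treated = as.integer(0:9 >= 4),
                      deliveries = c(520, 480, 515, 502, 498, 510, 505,
                                     490, 500, 512),
                      events = c(12, 9, 14, 11, 8, 7, 9, 6, 8, 5))
  f1 <- fit_logistic(cells, per_site = TRUE)
  f2 <- fit_logistic(cells, per_site = TRUE)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(unname(f1$coefficients["treated"]),
               brute_force_logit(f1$X, cells$events, cells$deliveries)[3],
               tolerance = 1e-4)
})
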