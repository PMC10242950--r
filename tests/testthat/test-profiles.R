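test_that("logistic-normal marginal probability is exact in limits and symmetric", {
  expect_equal(marginal_aon_probability(0, 0), 0.5)
  expect_equal(marginal_aon_probability(0, 3.96), 0.5)
  ## heterogeneity shrinks marginals towards 1/2
  expect_gt(marginal_aon_probability(-1, 3.96), plogis(-1))
  expect_lt(marginal_aon_probability(1, 3.96), plogis(1))
})

test_that("quadrature marginal matches a Monte-Carlo oracle", {
  set.seed(21)
  u <- rnorm(1e6, 0, sqrt(3.96))
  mc <- mean(plogis(-1 + u))
  expect_equal(marginal_aon_probability(-1, 3.96), mc, tolerance = 2e-3)
})

test_that("intercept inversion solves the marginal equation", {
  for (p in c(0.05, 0.3, 0.5, 0.64, 0.95)) {
    b <- aon_intercept(p, 3.96)
    expect_equal(marginal_aon_probability(b, 3.96), p, tolerance = 1e-9)
  }
  expect_equal(aon_intercept(0.5, 3.96), 0, tolerance = 1e-9)
  expect_error(aon_intercept(1.2, 3.96), "domain error")
})

test_that("calibration solves the continuous moment system to 1e-6", {
  p <- calibrate_profile("TD", p_comp = 0.6411, mean_s = 0.36,
                         prop_s_below_half = 0.80, tau00 = 3.96,
                         accuracy_median = 0.67, accuracy_cv = 0.25)
  m <- p$beta_a / (p$beta_a + p$beta_b)
  Fh <- pbeta(0.5, p$beta_a, p$beta_b)
  expect_equal(p$p_copy + p$p_comp * m, 0.36, tolerance = 1e-6)
  expect_equal(p$p_stay + p$p_comp * Fh, 0.80, tolerance = 1e-6)
  expect_equal(p$p_stay + p$p_copy + p$p_comp, 1, tolerance = 1e-12)
  expect_true(p$beta_a > 0 && p$beta_b > 0)
})

test_that("pure-compromise limit pins the Beta moments directly", {
  p <- calibrate_profile("TD", p_comp = 1, mean_s = 0.4,
                         prop_s_below_half = 0.75, tau00 = 0,
                         accuracy_median = 0.67, accuracy_cv = 0.25)
  expect_equal(p$p_stay, 0)
  expect_equal(p$p_copy, 0)
  expect_equal(p$beta_a / (p$beta_a + p$beta_b), 0.4, tolerance = 1e-9)
  expect_equal(pbeta(0.5, p$beta_a, p$beta_b), 0.75, tolerance = 1e-6)
})

test_that("infeasible targets raise a calibration error", {
  ## mean_s larger than its maximum p_copy + p_comp * 1
  expect_error(
    calibrate_profile("TD", p_comp = 0.2, mean_s = 0.95,
                      prop_s_below_half = 0.9, tau00 = 1,
                      accuracy_median = 0.67, accuracy_cv = 0.25),
    "calibration error")
})

test_that("simulation is deterministic and respects degenerate profiles", {
  prof <- strategy_profile("TD", p_stay = 1, p_copy = 0, p_comp = 0,
                           beta_a = 2, beta_b = 2, tau00 = 0,
                           accuracy_median = 0.67, accuracy_cv = 0.25)
  cfg <- simulation_config(group_sizes = c(TD = 40L),
                           profiles = list(TD = prof), seed = 5L,
                           simulate_covariates = FALSE)
  co <- score_cohort(simulate_cohort(cfg))
  expect_true(all(co$rounds$label == "stay"))
  expect_true(all(co$rounds$s == 0))

  ## same seed, same cohort; different seed, different cohort
  co2 <- simulate_cohort(cfg)
  expect_identical(co2$rounds, simulate_cohort(cfg)$rounds)
  cfg3 <- simulation_config(group_sizes = c(TD = 40L),
                            profiles = list(TD = prof), seed = 6L,
                            simulate_covariates = FALSE)
  expect_false(identical(simulate_cohort(cfg3)$rounds$e1, co2$rounds$e1))

  ## the caller's RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("seed is mandatory for simulation configs", {
  prof <- fixed_profile()
  expect_error(simulation_config(group_sizes = c(TD = 5L),
                                 profiles = list(TD = prof)),
               "seed")
})

test_that("intended compromises are always classified as compromises", {
  ## clamping to the open interval prevents label leakage from rounding
  prof <- fixed_profile(p_stay = 0, p_copy = 0, p_comp = 1)
  cfg <- simulation_config(group_sizes = c(TD = 2000L),
                           profiles = list(TD = prof), seed = 7L,
                           simulate_covariates = FALSE)
  co <- score_cohort(simulate_cohort(cfg))
  expect_true(all(co$rounds$label == "compromise"))
})

test_that("realized strategy shares converge to the profile marginals", {
  prof <- fixed_profile()  # known p_stay/p_copy/p_comp, tau00 = 3.96
  n_part <- 6000L
  cfg <- simulation_config(group_sizes = c(TD = n_part),
                           profiles = list(TD = prof), seed = 8L,
                           simulate_covariates = FALSE)
  co <- score_cohort(simulate_cohort(cfg))
  v <- co$rounds[co$rounds$is_valid, ]
  shares <- c(mean(v$label == "stay"), mean(v$label == "copy"),
              mean(v$label == "compromise"))
  ## cluster-robust standard errors (rounds within participant correlate)
  pshare <- function(lab) {
    tapply(v$label == lab, v$participant_id, mean)
  }
  for (i in seq_along(c("stay", "copy", "compromise"))) {
    lab <- c("stay", "copy", "compromise")[i]
    se <- sd(pshare(lab)) / sqrt(n_part)
    target <- c(prof$p_stay, prof$p_copy, prof$p_comp)[i]
    expect_lt(abs(shares[i] - target), 3.5 * se + 0.003)
  }
})

test_that("realized first-estimate accuracy matches the lognormal model", {
  prof <- fixed_profile()
  cfg <- simulation_config(group_sizes = c(TD = 20000L),
                           profiles = list(TD = prof), seed = 9L,
                           simulate_covariates = FALSE)
  co <- simulate_cohort(cfg)
  acc <- mean(co$rounds$e1 / co$rounds$true_count)
  expect_equal(acc, prof$accuracy_median * exp(prof$accuracy_cv^2 / 2),
               tolerance = 0.01)
})

test_that("invalid-round injection exercises the exclusion filter", {
  prof <- fixed_profile()
  cfg <- simulation_config(group_sizes = c(TD = 300L),
                           profiles = list(TD = prof), seed = 10L,
                           invalid_rate = 0.5, simulate_covariates = FALSE)
  co <- score_cohort(simulate_cohort(cfg))
  expect_gt(sum(!co$rounds$is_valid), 0)
  res <- filter_participants(co)
  expect_gt(res$report$n_excluded, 0)
})

test_that("packaged reference profiles carry the published targets", {
  t <- beast_reference_targets()
  expect_equal(t$TD$p_comp, 0.6411)
  expect_equal(t$CP_LCU$p_comp, 0.3586)
  expect_equal(t$TD$prop_s_below_half, 0.80)
  expect_equal(t$CP_LCU$mean_s, 0.32)
  expect_equal(t$TD$tau00, 3.96)
})
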