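## larger simulated cohort shared across fitting tests
sim_cohort_3groups <- function(seed = 31L, n = c(TD = 60L, CP_LCU = 50L,
                                                 CP_HCU = 50L)) {
  profs <- list(
    TD = fixed_profile("TD", 0.17, 0.19, 0.64),
    CP_LCU = fixed_profile("CP_LCU", 0.45, 0.19, 0.36),
    CP_HCU = fixed_profile("CP_HCU", 0.31, 0.19, 0.50))
  cfg <- simulation_config(group_sizes = n, profiles = profs, seed = seed,
                           simulate_covariates = TRUE)
  filter_participants(score_cohort(simulate_cohort(cfg)))$retained
}

test_that("variance-component arithmetic matches closed forms", {
  expect_equal(icc_from_components(3.96, 3.29), 3.96 / 7.25)
  expect_equal(round(icc_from_components(3.96, 3.29), 2), 0.55)
  expect_equal(icc_from_components(0, 2), 0)
  expect_gt(icc_from_components(3.96, 1e-9), 0.999)
  expect_error(icc_from_components(0, 0), "undefined")

  r2 <- nakagawa_r2(0, 3.96, 3.29)
  expect_equal(unname(r2["marginal"]), 0)
  expect_equal(unname(r2["conditional"]), icc_from_components(3.96, 3.29))

  ## marginal <= conditional for random nonnegative components
  set.seed(32)
  for (i in 1:50) {
    v <- runif(3, 0, 5)
    r <- nakagawa_r2(v[1], v[2], v[3] + 0.01)
    expect_lte(r["marginal"], r["conditional"])
    expect_lte(r["conditional"], 1)
  }
})

test_that("accuracy ANOVA reproduces hand-computed F and eta-squared", {
  sm <- data.frame(group = rep(c("TD", "CP_LCU"), each = 3),
                   accuracy_ratio = c(1, 2, 3, 4, 5, 6))
  a <- anova_accuracy(sm)
  expect_equal(a$F, 13.5)
  expect_equal(a$eta_squared, 13.5 / 17.5, tolerance = 1e-12)
  expect_equal(c(a$df1, a$df2), c(1, 4))

  sm3 <- data.frame(group = rep(c("TD", "CP_LCU", "CP_HCU"), each = 3),
                    accuracy_ratio = rep(c(1, 2, 3), 3))
  a3 <- anova_accuracy(sm3)
  expect_equal(a3$F, 0)
  expect_equal(a3$eta_squared, 0)
  expect_equal(c(a3$df1, a3$df2), c(2, 6))

  expect_error(anova_accuracy(data.frame(group = c("TD", "CP_LCU"),
                                         accuracy_ratio = c(1, 1))),
               "constant")
})

test_that("adjustment model recovers the round-level mean of a single group", {
  prof <- calibrate_profile("TD", p_comp = 0.6411, mean_s = 0.36,
                            prop_s_below_half = 0.80, tau00 = 3.96,
                            accuracy_median = 0.67, accuracy_cv = 0.25,
                            refine = TRUE)
  cfg <- simulation_config(group_sizes = c(TD = 400L),
                           profiles = list(TD = prof), seed = 33L,
                           simulate_covariates = FALSE)
  co <- filter_participants(score_cohort(simulate_cohort(cfg)))$retained
  fit <- fit_adjustment_model(co)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0.36, tolerance = 0.02)
  expect_equal(fit$n_observations, sum(co$rounds$is_valid))
  expect_true(fit$icc >= 0 && fit$icc <= 1)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
})

test_that("three-group fits report components, contrasts and LR test", {
  co <- sim_cohort_3groups()
  fit <- fit_strategy_model(co, coding = "aon_vs_comp")
  expect_s3_class(fit, "beast_fit")
  expect_equal(fit$sigma2, pi^2 / 3)
  expect_equal(fit$n_participants, 160L)
  expect_true(all(c("odds_ratio", "or_lo", "or_hi") %in%
                    names(fit$fixed_effects)))
  expect_false(fit$fallback)
  expect_true(fit$lrt$chisq >= 0)
  expect_equal(fit$lrt$df, 2)

  ## contrast table properties
  ct <- fit$contrasts
  expect_equal(nrow(ct), 3L)
  expect_true(all(ct$p_adjusted >= ct$p_unadjusted - 1e-12))
  ## antisymmetry: reversing a contrast flips its sign
  i <- match("CP_LCU - TD", ct$contrast)
  expect_equal(ct$estimate[i],
               coef(fit)[["groupCP_LCU"]], tolerance = 1e-9)

  ## summary/print methods render
  expect_output(print(fit), "logistic mixed model")
  expect_output(summary(fit), "Tukey-adjusted")
  expect_equal(unname(confint(fit)[, 1]), fit$fixed_effects$ci_lo)

  ## tidy table carries model-level metadata
  tab <- fit_table(fit)
  expect_true(all(c("model_id", "tau00", "icc", "n_observations") %in%
                    names(tab)))
})

test_that("strategy GLMM nests ordinary logistic regression at tau00 = 0", {
  co <- sim_cohort_3groups(seed = 34L)
  d <- co$rounds[co$rounds$is_valid, ]
  d$y <- as.integer(d$label %in% c("stay", "copy"))
  ## scramble participant structure so the true tau00 is 0
  set.seed(35)
  d$participant_id <- sample(d$participant_id)
  glm_fit <- glm(y ~ group, binomial, data = d)
  glmm <- lme4::glmer(y ~ group + (1 | participant_id), binomial,
                      data = d, nAGQ = 25L)
  expect_equal(as.numeric(logLik(glmm)) / nrow(d),
               as.numeric(logLik(glm_fit)) / nrow(d), tolerance = 1e-6)
})

test_that("covariate-adjusted fits accept age and iq and reject others", {
  co <- sim_cohort_3groups(seed = 36L)
  fit <- fit_strategy_model(co, coding = "aon_vs_comp",
                            covariates = c("age", "iq"))
  expect_true(all(c("age_c", "iq_c") %in% fit$fixed_effects$term))
  expect_error(fit_strategy_model(co, covariates = "height"),
               "unknown covariate")

  ## group effect is similar with and without covariates (covariates are
  ## independent of strategy in the generator)
  fit0 <- fit_strategy_model(co, coding = "aon_vs_comp")
  expect_equal(coef(fit)[["groupCP_LCU"]], coef(fit0)[["groupCP_LCU"]],
               tolerance = 0.15)
})

test_that("constant outcomes trigger the penalized fallback", {
  ## all-stay cohort: stay_vs_rest outcome is constant 1
  prof <- strategy_profile("TD", 1, 0, 0, 2, 2, 0,
                           accuracy_median = 0.67, accuracy_cv = 0.25)
  prof2 <- strategy_profile("CP_LCU", 1, 0, 0, 2, 2, 0,
                            accuracy_median = 0.67, accuracy_cv = 0.25)
  cfg <- simulation_config(group_sizes = c(TD = 20L, CP_LCU = 20L),
                           profiles = list(TD = prof, CP_LCU = prof2),
                           seed = 37L, simulate_covariates = FALSE)
  co <- score_cohort(simulate_cohort(cfg))
  expect_warning(fit <- fit_strategy_model(co, coding = "stay_vs_rest"),
                 "Firth")
  expect_true(fit$fallback)
  expect_true(is.na(fit$tau00))
  ## Firth estimates stay finite under separation
  expect_true(all(is.finite(fit$fixed_effects$estimate)))
})

test_that("null simulations keep group effects near zero", {
  ## identical profiles in all groups: every group effect should be small
  ## and the Tukey-adjusted p-values non-significant in most replicates
  profs <- list(TD = fixed_profile("TD"),
                CP_LCU = fixed_profile("CP_LCU"),
                CP_HCU = fixed_profile("CP_HCU"))
  hits <- 0L
  for (r in 1:5) {
    cfg <- simulation_config(group_sizes = c(TD = 80L, CP_LCU = 80L,
                                             CP_HCU = 80L),
                             profiles = profs, seed = 40L + r,
                             simulate_covariates = FALSE)
    co <- filter_participants(score_cohort(simulate_cohort(cfg)))$retained
    fit <- fit_adjustment_model(co)
    ci <- confint(fit)
    for (tm in c("groupCP_LCU", "groupCP_HCU")) {
      if (ci[tm, 1] <= 0 && 0 <= ci[tm, 2]) hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)  # 10 intervals, 95% nominal coverage
})

test_that("replicate recovery returns per-replicate estimates near truth", {
  beta <- c(log(0.42), log(5.78), log(2.20))
  rec <- recover_strategy_glmm(
    beta, tau00 = 3.96,
    group_sizes = c(TD = 45L, CP_LCU = 31L, CP_HCU = 32L),
    n_replicates = 12L, seed = 42L)
  expect_equal(ncol(rec), 4L)
  expect_gte(nrow(rec), 10L)
  ## medians of a dozen replicates are already in the right region
  expect_lt(abs(median(rec$effect_CP_LCU) - log(5.78)), 0.8)
  expect_lt(abs(median(rec$intercept) - log(0.42)), 0.6)
})
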