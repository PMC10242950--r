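## Inference layer: random-intercept linear model of round-level s,
## random-intercept logistic models of strategy choice, Tukey contrasts,
## latent-scale ICC, Nakagawa R-squared, accuracy ANOVA, and the replicate
## parameter-recovery harness.

STRATEGY_CODINGS <- c("aon_vs_comp", "stay_vs_rest", "copy_vs_rest")

## ---- variance-component arithmetic -------------------------------------

#' Intraclass correlation from variance components
#'
#' `ICC = tau00 / (tau00 + sigma2)`. For logistic models `sigma2` is the
#' latent-scale distribution variance `pi^2 / 3`.
#'
#' @param tau00 random-intercept variance, `>= 0`.
#' @param sigma2 residual / distribution-specific variance, `> 0`.
#' @return Proportion in `[0, 1)`.
#' @examples
#' icc_from_components(3.96, 3.29)  # 0.546
#' @export
icc_from_components <- function(tau00, sigma2) {
  stopifnot(tau00 >= 0)
  if (tau00 == 0 && sigma2 == 0) {
    stop("undefined: both variance components are zero", call. = FALSE)
  }
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  tau00 / (tau00 + sigma2)
}

#' Nakagawa marginal and conditional R-squared
#'
#' `marginal = Vf / (Vf + tau00 + sigma2)`;
#' `conditional = (Vf + tau00) / (Vf + tau00 + sigma2)`, where `Vf` is the
#' variance of the fixed-effect linear predictor over the estimation sample.
#'
#' @param fixed_effect_variance `Vf >= 0`.
#' @param tau00 random-intercept variance.
#' @param sigma2 residual (or latent-scale) variance.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fixed_effect_variance, tau00, sigma2) {
  stopifnot(fixed_effect_variance >= 0, tau00 >= 0, sigma2 >= 0)
  tot <- fixed_effect_variance + tau00 + sigma2
  if (tot == 0) stop("undefined: zero total variance", call. = FALSE)
  c(marginal = fixed_effect_variance / tot,
    conditional = (fixed_effect_variance + tau00) / tot)
}

#' Conditional R-squared implied by a marginal R-squared
#'
#' Inverts the Nakagawa marginal formula for the fixed-effect variance
#' `Vf = marginal * (tau00 + sigma2) / (1 - marginal)` and returns the
#' implied conditional R-squared — an internal-consistency check on
#' published variance components.
#'
#' @param marginal marginal R-squared in `[0, 1)`.
#' @inheritParams nakagawa_r2
#' @return Conditional R-squared.
#' @examples
#' nakagawa_conditional_from_marginal(0.068, 3.96, 3.29)  # 0.577
#' @export
nakagawa_conditional_from_marginal <- function(marginal, tau00, sigma2) {
  stopifnot(marginal >= 0, marginal < 1)
  vf <- marginal * (tau00 + sigma2) / (1 - marginal)
  unname(nakagawa_r2(vf, tau00, sigma2)["conditional"])
}

## ---- model data preparation --------------------------------------------

## valid rounds of a scored cohort, with centered covariates when requested
model_data <- function(cohort, covariates = NULL) {
  stopifnot(inherits(cohort, "beast_cohort"))
  if (!"label" %in% names(cohort$rounds)) cohort <- score_cohort(cohort)
  d <- cohort$rounds[cohort$rounds$is_valid, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid rounds to model", call. = FALSE)
  d$participant_id <- factor(d$participant_id)
  d$group <- droplevels(factor(d$group, levels = BEAST_GROUPS))
  covariates <- validate_covariates(covariates)
  for (cv in covariates) {
    if (!cv %in% names(d) || all(is.na(d[[cv]]))) {
      stop(sprintf("covariate '%s' not available in the cohort", cv),
           call. = FALSE)
    }
    d[[paste0(cv, "_c")]] <- d[[cv]] - mean(d[[cv]])  # centered
  }
  attr(d, "covariates") <- covariates
  d
}

validate_covariates <- function(covariates) {
  if (is.null(covariates) || length(covariates) == 0L) return(character(0))
  bad <- setdiff(covariates, c("age", "iq"))
  if (length(bad) > 0L) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  covariates
}

fixed_formula_terms <- function(d, covariates) {
  terms <- character(0)
  if (nlevels(d$group) >= 2L) terms <- "group"
  if (length(covariates) > 0L) terms <- c(terms, paste0(covariates, "_c"))
  terms
}

## variance of the fixed-effect linear predictor over the estimation sample
fixed_effect_variance <- function(fit) {
  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  pred <- as.numeric(X %*% beta)
  mean((pred - mean(pred))^2)  # population variance of the predictor
}

wald_table <- function(est, se, level = 0.95, exponentiate = FALSE) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se),
                    ci_lo = unname(est - z * se),
                    ci_hi = unname(est + z * se),
                    p = unname(2 * pnorm(-abs(est / se))),
                    stringsAsFactors = FALSE)
  if (exponentiate) {
    out$odds_ratio <- exp(out$estimate)
    out$or_lo <- exp(out$ci_lo)
    out$or_hi <- exp(out$ci_hi)
  }
  out
}

## ---- fitting ------------------------------------------------------------

#' Linear mixed model of round-level adjustment
#'
#' Fits `s ~ group (+ centered covariates) + (1 | participant)` by REML to
#' the valid rounds (TD is the reference level). Reports Wald confidence
#' intervals and p-values, variance components, ICC, Nakagawa R-squared,
#' a likelihood-ratio chi-squared for the group factor (ML refits), and
#' Tukey-adjusted pairwise group contrasts when three or more groups are
#' present. A singular fit (`tau00 -> 0`) sets a warning flag rather than
#' failing.
#'
#' @param cohort a scored, filtered [beast_cohort()].
#' @param covariates optional subset of `c("age", "iq")`; covariates are
#'   mean-centered so the intercept stays interpretable as the reference
#'   group mean.
#' @return A `beast_fit` object.
#' @export
fit_adjustment_model <- function(cohort, covariates = NULL) {
  d <- model_data(cohort, covariates)
  covariates <- attr(d, "covariates")
  rhs_fixed <- fixed_formula_terms(d, covariates)
  rhs <- paste(c(rhs_fixed, "(1 | participant_id)"), collapse = " + ")
  if (length(rhs_fixed) == 0L) rhs <- paste("1 +", rhs)
  form <- as.formula(paste("s ~", rhs))

  fit <- lme4::lmer(form, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "participant_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vf <- fixed_effect_variance(fit)
  r2 <- nakagawa_r2(vf, tau00, sigma2)

  lrt <- group_lrt(form, d, family = NULL)

  out <- new_beast_fit(
    model_id = "adjustment",
    fixed_effects = wald_table(est, se),
    sigma2 = sigma2, tau00 = tau00,
    icc = icc_from_components(tau00, sigma2),
    r2_marginal = unname(r2["marginal"]),
    r2_conditional = unname(r2["conditional"]),
    n_participants = nlevels(d$participant_id),
    n_observations = nrow(d),
    lrt = lrt,
    singular = lme4::isSingular(fit),
    fallback = FALSE,
    covariates = covariates,
    fit = fit, data = d)
  out$contrasts <- if (nlevels(d$group) >= 2L) tukey_contrasts(out) else NULL
  out
}

#' Random-intercept logistic model of strategy choice
#'
#' Fits a logit-link mixed model of a binary strategy coding on group (TD
#' reference) with a participant random intercept, by maximum likelihood
#' with adaptive Gauss-Hermite quadrature (`nAGQ = 10`). Codings:
#' * `aon_vs_comp`: all-or-nothing (stay/copy, coded 1) vs compromise (0) —
#'   the primary strategy model;
#' * `stay_vs_rest`: stay vs copy/compromise;
#' * `copy_vs_rest`: copy vs stay/compromise.
#'
#' Reports conditional (subject-specific) log-odds, odds ratios with Wald
#' intervals, `tau00`, latent-scale `sigma2 = pi^2/3`, ICC, Nakagawa
#' R-squared, a likelihood-ratio chi-squared for the group factor and Tukey
#' contrasts. A constant outcome or complete separation triggers a
#' Firth-penalized plain-logistic fallback (warning flag; `tau00` reported
#' `NA`).
#'
#' @inheritParams fit_adjustment_model
#' @param coding one of `"aon_vs_comp"`, `"stay_vs_rest"`, `"copy_vs_rest"`.
#' @param nAGQ adaptive quadrature order (default 10).
#' @return A `beast_fit` object.
#' @export
fit_strategy_model <- function(cohort, coding = "aon_vs_comp",
                               covariates = NULL, nAGQ = 10L) {
  coding <- match.arg(coding, STRATEGY_CODINGS)
  d <- model_data(cohort, covariates)
  covariates <- attr(d, "covariates")
  d$y <- switch(coding,
                aon_vs_comp = as.integer(d$label %in% c("stay", "copy")),
                stay_vs_rest = as.integer(d$label == "stay"),
                copy_vs_rest = as.integer(d$label == "copy"))
  rhs_fixed <- fixed_formula_terms(d, covariates)
  sigma2 <- pi^2 / 3

  constant <- length(unique(d$y)) == 1L
  fit <- NULL
  separated <- FALSE
  if (!constant) {
    rhs <- paste(c(rhs_fixed, "(1 | participant_id)"), collapse = " + ")
    form <- as.formula(paste("y ~", rhs))
    fit <- suppressMessages(try(
      lme4::glmer(form, data = d, family = binomial, nAGQ = nAGQ),
      silent = TRUE))
    if (inherits(fit, "try-error") ||
        any(abs(lme4::fixef(fit)) > 15)) {
      separated <- TRUE
    }
  }

  if (constant || separated) {
    warning("constant outcome or separation: Firth-penalized logistic fallback",
            call. = FALSE)
    Xf <- stats::model.matrix(
      as.formula(paste("~", paste(c("1", rhs_fixed), collapse = " + "))), d)
    fl <- firth_logistic(Xf, d$y)
    tab <- wald_table(setNames(fl$coef, colnames(Xf)), fl$se,
                      exponentiate = TRUE)
    vf <- {
      pred <- as.numeric(Xf %*% fl$coef)
      mean((pred - mean(pred))^2)
    }
    r2 <- nakagawa_r2(vf, 0, sigma2)
    out <- new_beast_fit(
      model_id = coding,
      fixed_effects = tab,
      sigma2 = sigma2, tau00 = NA_real_, icc = NA_real_,
      r2_marginal = unname(r2["marginal"]),
      r2_conditional = unname(r2["conditional"]),
      n_participants = nlevels(d$participant_id),
      n_observations = nrow(d),
      lrt = NULL, singular = NA, fallback = TRUE,
      covariates = covariates, fit = NULL, data = d)
    return(out)
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "participant_id"]
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vf <- fixed_effect_variance(fit)
  r2 <- nakagawa_r2(vf, tau00, sigma2)
  lrt <- group_lrt(form, d, family = binomial, nAGQ = nAGQ)

  out <- new_beast_fit(
    model_id = coding,
    fixed_effects = wald_table(est, se, exponentiate = TRUE),
    sigma2 = sigma2, tau00 = tau00,
    icc = icc_from_components(tau00, sigma2),
    r2_marginal = unname(r2["marginal"]),
    r2_conditional = unname(r2["conditional"]),
    n_participants = nlevels(d$participant_id),
    n_observations = nrow(d),
    lrt = lrt,
    singular = lme4::isSingular(fit),
    fallback = FALSE,
    covariates = covariates,
    fit = fit, data = d)
  out$contrasts <- if (nlevels(d$group) >= 2L) tukey_contrasts(out) else NULL
  out
}

## likelihood-ratio test for the group factor (ML fits of nested models);
## invariant to the reference level by construction
group_lrt <- function(form, d, family = NULL, nAGQ = 10L) {
  if (nlevels(d$group) < 2L) return(NULL)
  null_form <- stats::update.formula(form, . ~ . - group)
  if (is.null(family)) {
    full <- lme4::lmer(form, data = d, REML = FALSE)
    null <- lme4::lmer(null_form, data = d, REML = FALSE)
  } else {
    full <- suppressMessages(lme4::glmer(form, data = d, family = family,
                                         nAGQ = nAGQ))
    null <- suppressMessages(lme4::glmer(null_form, data = d,
                                         family = family, nAGQ = nAGQ))
  }
  chisq <- as.numeric(2 * (logLik(full) - logLik(null)))
  df <- attr(logLik(full), "df") - attr(logLik(null), "df")
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

## Firth-penalized logistic regression (Jeffreys-prior score correction):
## score U* = X'(y - mu + h (1/2 - mu)) with h the hat diagonal. Used as the
## separation fallback; handles constant outcomes, where the MLE diverges.
firth_logistic <- function(X, y, max_iter = 200L, tol = 1e-10) {
  b <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- as.numeric(info_inv %*% U)
    ## damp long steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% b)
  w <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  list(coef = b, se = se, iterations = i)
}

#' Tukey-adjusted pairwise group contrasts
#'
#' All pairwise group contrasts on the link scale with single-step
#' (multivariate-normal) multiplicity adjustment, via [multcomp::glht()].
#' With two groups the table reduces to the unadjusted Wald test. Adjusted
#' p-values are computed under a fixed local RNG seed so pipeline output is
#' deterministic.
#'
#' @param fit a `beast_fit` from [fit_adjustment_model()] or
#'   [fit_strategy_model()] (not a fallback fit).
#' @return data.frame with columns `contrast`, `estimate`, `se`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
tukey_contrasts <- function(fit) {
  stopifnot(inherits(fit, "beast_fit"))
  if (is.null(fit$fit)) {
    stop("contrasts unavailable for a fallback (penalized) fit",
         call. = FALSE)
  }
  d <- fit$data
  if (nlevels(d$group) < 2L) stop("need >= 2 groups", call. = FALSE)
  gl <- multcomp::glht(fit$fit, linfct = multcomp::mcp(group = "Tukey"))
  with_preserved_seed(20061L, {
    sm_adj <- summary(gl, test = multcomp::adjusted("single-step"))
    sm_raw <- summary(gl, test = multcomp::adjusted("none"))
    data.frame(
      contrast = names(sm_adj$test$coefficients),
      estimate = unname(sm_adj$test$coefficients),
      se = unname(sm_adj$test$sigma),
      z = unname(sm_adj$test$tstat),
      p_unadjusted = unname(sm_raw$test$pvalues),
      p_adjusted = if (nlevels(d$group) == 2L) {
        unname(sm_raw$test$pvalues)
      } else {
        unname(sm_adj$test$pvalues)
      },
      stringsAsFactors = FALSE)
  })
}

#' One-way ANOVA of first-estimate accuracy
#'
#' Tests whether groups differ in initial-estimate accuracy
#' (`mean(E1 / true_count)` per participant), with effect size
#' `eta^2 = SS_between / SS_total`.
#'
#' @param summaries participant summaries from [summarize_participants()].
#' @return List with `F`, `df1`, `df2`, `p`, `eta_squared`.
#' @export
anova_accuracy <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("accuracy_ratio", "group") %in% names(summaries)))
  summaries$group <- droplevels(factor(summaries$group))
  if (nlevels(summaries$group) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (var(summaries$accuracy_ratio) == 0) {
    stop("undefined F: accuracy is constant", call. = FALSE)
  }
  fit <- aov(accuracy_ratio ~ group, data = summaries)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  list(F = tab[["F value"]][1L],
       df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
       p = tab[["Pr(>F)"]][1L],
       eta_squared = ss[1L] / sum(ss))
}

## ---- parameter recovery -------------------------------------------------

#' Replicate parameter recovery for the strategy GLMM
#'
#' Simulates binary all-or-nothing outcomes directly from the
#' random-intercept logistic model (given conditional fixed-effect
#' log-odds and `tau00`), refits [lme4::glmer()] per replicate, and
#' returns per-replicate estimates — the standard check that the fitting
#' machinery recovers known generating parameters at a given design size.
#'
#' @param beta named numeric of conditional log-odds: intercept (TD
#'   reference) and group offsets, in the order of `group_sizes`.
#' @param tau00 generating random-intercept variance.
#' @param group_sizes named integer vector of participants per group.
#' @param n_rounds rounds per participant (default 5).
#' @param n_replicates number of simulated cohorts.
#' @param seed RNG seed (caller's RNG state preserved).
#' @param nAGQ quadrature order for refitting.
#' @return data.frame with one row per replicate: fitted log-odds per term
#'   and fitted `tau00`.
#' @export
recover_strategy_glmm <- function(beta, tau00, group_sizes,
                                  n_rounds = 5L, n_replicates = 100L,
                                  seed = 1L, nAGQ = 10L) {
  stopifnot(length(beta) == length(group_sizes),
            !is.null(names(group_sizes)))
  groups <- names(group_sizes)
  with_preserved_seed(seed, {
    res <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      g <- factor(rep(groups, group_sizes), levels = groups)
      n <- length(g)
      u <- rnorm(n, 0, sqrt(tau00))
      id <- factor(rep(seq_len(n), each = n_rounds))
      gr <- rep(g, each = n_rounds)
      eta <- beta[1L] + rep(u, each = n_rounds)
      for (j in seq_along(groups)[-1L]) {
        eta <- eta + beta[j] * (gr == groups[j])
      }
      y <- rbinom(length(eta), 1L, plogis(eta))
      fit <- suppressMessages(try(
        lme4::glmer(y ~ gr + (1 | id), family = binomial, nAGQ = nAGQ),
        silent = TRUE))
      if (inherits(fit, "try-error")) next
      est <- lme4::fixef(fit)
      vc <- as.data.frame(lme4::VarCorr(fit))
      res[[r]] <- c(est, tau00_hat = vc$vcov[1L])
    }
    res <- res[!vapply(res, is.null, logical(1))]
    out <- as.data.frame(do.call(rbind, res))
    names(out) <- c("intercept", paste0("effect_", groups[-1L]), "tau00_hat")
    out
  })
}

## ---- beast_fit class ----------------------------------------------------

new_beast_fit <- function(...) {
  structure(list(...), class = "beast_fit")
}

#' @method print beast_fit
#' @export
print.beast_fit <- function(x, digits = 3, ...) {
  logit <- "odds_ratio" %in% names(x$fixed_effects)
  cat(sprintf("<beast_fit> %s (%s mixed model%s)\n", x$model_id,
              if (logit) "logistic" else "linear",
              if (isTRUE(x$fallback)) ", Firth fallback" else ""))
  fe <- x$fixed_effects
  if (logit) {
    tab <- data.frame(term = fe$term,
                      OR = round(fe$odds_ratio, digits),
                      CI = sprintf("%.2f-%.2f", fe$or_lo, fe$or_hi),
                      p = signif(fe$p, 2))
  } else {
    tab <- data.frame(term = fe$term,
                      estimate = round(fe$estimate, digits),
                      CI = sprintf("%.2f-%.2f", fe$ci_lo, fe$ci_hi),
                      p = signif(fe$p, 2))
  }
  print(tab, row.names = FALSE)
  cat(sprintf("sigma2 = %.2f, tau00 = %.2f, ICC = %.2f\n",
              x$sigma2, x$tau00, x$icc))
  cat(sprintf("N = %d participants, %d observations; R2 = %.3f / %.3f (marginal/conditional)\n",
              x$n_participants, x$n_observations,
              x$r2_marginal, x$r2_conditional))
  if (!is.null(x$lrt)) {
    cat(sprintf("group LR test: chisq(%d) = %.2f, p = %.3g\n",
                x$lrt$df, x$lrt$chisq, x$lrt$p))
  }
  invisible(x)
}

#' @method summary beast_fit
#' @export
summary.beast_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$contrasts)) {
    cat("Tukey-adjusted pairwise contrasts:\n")
    ct <- object$contrasts
    ct$estimate <- round(ct$estimate, 3)
    ct$se <- round(ct$se, 3)
    ct$z <- round(ct$z, 2)
    ct$p_unadjusted <- signif(ct$p_unadjusted, 3)
    ct$p_adjusted <- signif(ct$p_adjusted, 3)
    print(ct, row.names = FALSE)
  }
  invisible(object)
}

#' @method coef beast_fit
#' @export
coef.beast_fit <- function(object, ...) {
  setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @method confint beast_fit
#' @export
confint.beast_fit <- function(object, ...) {
  m <- as.matrix(object$fixed_effects[, c("ci_lo", "ci_hi")])
  rownames(m) <- object$fixed_effects$term
  colnames(m) <- c("2.5 %", "97.5 %")
  m
}

#' Tidy term-level table of a fit
#'
#' @param fit a `beast_fit`.
#' @return data.frame of terms with estimates, intervals and p-values plus
#'   model-level columns (`model_id`, variance components, R-squared, N).
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "beast_fit"))
  fe <- fit$fixed_effects
  fe$model_id <- fit$model_id
  fe$sigma2 <- fit$sigma2
  fe$tau00 <- fit$tau00
  fe$icc <- fit$icc
  fe$r2_marginal <- fit$r2_marginal
  fe$r2_conditional <- fit$r2_conditional
  fe$n_participants <- fit$n_participants
  fe$n_observations <- fit$n_observations
  fe
}
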