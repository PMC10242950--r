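## Agent-based cohort generator. One random intercept per participant on
## the all-or-nothing propensity; stay-vs-copy split and Beta compromise
## weights homogeneous within group; lognormal multiplicative
## underestimation for first estimates; social information from the
## calibrated task engine. Fully vectorized over rounds.

#' Simulation configuration
#'
#' @param group_sizes named integer vector of participants per group.
#'   Defaults to the study's post-exclusion sizes (TD 45, CP/LCU 31,
#'   CP/HCU 32).
#' @param profiles named list of [strategy_profile()] objects covering every
#'   group in `group_sizes`. Defaults to [paper_profiles()].
#' @param task a [task_config()].
#' @param seed integer RNG seed; mandatory (no wall-clock default), so every
#'   simulated cohort is reproducible.
#' @param invalid_rate probability that a round's second estimate is
#'   replaced by an out-of-range response (overshoot or negative-weight,
#'   equally likely), exercising the exclusion filter. Default 0: the
#'   mechanism behind real participants' invalid rounds is unknown and none
#'   are claimed.
#' @param simulate_covariates logical; draw per-participant age and IQ from
#'   the profiles' covariate moments.
#' @return A list of class `beast_simconfig`.
#' @export
simulation_config <- function(group_sizes = c(TD = 45L, CP_LCU = 31L,
                                              CP_HCU = 32L),
                              profiles = NULL,
                              task = task_config(),
                              seed,
                              invalid_rate = 0,
                              simulate_covariates = TRUE) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory in a simulation config", call. = FALSE)
  }
  if (is.null(profiles)) profiles <- paper_profiles(task = task)
  stopifnot(length(group_sizes) >= 1L, all(group_sizes >= 1L),
            !is.null(names(group_sizes)),
            all(names(group_sizes) %in% BEAST_GROUPS),
            all(names(group_sizes) %in% names(profiles)),
            invalid_rate >= 0, invalid_rate < 1)
  structure(list(group_sizes = group_sizes,
                 profiles = profiles[names(group_sizes)],
                 task = task, seed = as.integer(seed),
                 invalid_rate = invalid_rate,
                 simulate_covariates = isTRUE(simulate_covariates)),
            class = "beast_simconfig")
}

#' Simulate a cohort
#'
#' Per participant, a heterogeneity draw `u ~ Normal(0, tau00)`; per round,
#' the true count comes from the fixed stimulus schedule,
#' `E1 = max(1, round(true * exp(Normal(log(accuracy_median), cv))))`,
#' `X` from [generate_social_info()], and the strategy from a two-stage
#' draw: all-or-nothing with probability `plogis(c_g + u)` where the
#' conditional intercept `c_g` is solved from the profile's marginal
#' all-or-nothing share via [aon_intercept()]; all-or-nothing rounds split
#' stay vs copy with odds `p_stay : p_copy`; compromise rounds draw
#' `w ~ Beta(a, b)` and set `E2 = round(E1 + w (X - E1))` clamped to the
#' open integer interval between `E1` and `X`, so an intended compromise is
#' always classified as one.
#'
#' Deterministic given `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config a [simulation_config()].
#' @return An unscored [beast_cohort()].
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "beast_simconfig"))
  with_preserved_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  task <- config$task
  counts <- task$true_counts
  n_rounds <- length(counts)
  parts <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    prof <- config$profiles[[g]]
    ids <- sprintf("%s_%04d", g, seq_len(n))

    u <- rnorm(n, 0, sqrt(prof$tau00))

    id_col <- rep(ids, each = n_rounds)
    round_col <- rep(seq_len(n_rounds), times = n)
    true_col <- rep(counts, times = n)
    N <- n * n_rounds

    e1 <- pmax(1L, as.integer(round(true_col *
      exp(rnorm(N, log(prof$accuracy_median), prof$accuracy_cv)))))
    x <- generate_social_info(e1, round_col, task)

    ## all-or-nothing draw; degenerate mixtures bypass the logistic model
    aon <- if (prof$p_comp <= 0) {
      rep(TRUE, N)
    } else if (prof$p_comp >= 1) {
      rep(FALSE, N)
    } else {
      c_g <- aon_intercept(1 - prof$p_comp, prof$tau00)
      rbinom(N, 1L, plogis(c_g + rep(u, each = n_rounds))) == 1L
    }
    p_copy_given_aon <- if (prof$p_stay + prof$p_copy > 0) {
      prof$p_copy / (prof$p_stay + prof$p_copy)
    } else 0.5  # unused when p_comp = 1
    copy <- rbinom(N, 1L, p_copy_given_aon) == 1L

    e2 <- ifelse(copy, x, e1)  # stay/copy defaults
    comp <- !aon
    if (any(comp)) {
      w <- rbeta(sum(comp), prof$beta_a, prof$beta_b)
      e1c <- e1[comp]; xc <- x[comp]
      raw <- as.integer(round(e1c + w * (xc - e1c)))
      lo <- pmin(e1c, xc) + 1L
      hi <- pmax(e1c, xc) - 1L
      e2[comp] <- pmin(pmax(raw, lo), hi)
    }

    if (config$invalid_rate > 0) {
      bad <- runif(N) < config$invalid_rate
      if (any(bad)) {
        over <- runif(sum(bad)) < 0.5
        d <- (x - e1)[bad]
        e2b <- ifelse(over, x[bad] + d, e1[bad] - d)  # s = 2 or s = -1
        e2[bad] <- pmax(1L, as.integer(e2b))
      }
    }

    df <- data.frame(participant_id = id_col, group = g,
                     round = round_col, true_count = true_col,
                     e1 = e1, x = x, e2 = as.integer(e2),
                     stringsAsFactors = FALSE)
    if (config$simulate_covariates && is.finite(prof$age_mean)) {
      age <- round(rnorm(n, prof$age_mean, prof$age_sd), 1)
      iq <- round(rnorm(n, prof$iq_mean, prof$iq_sd))
      df$age <- rep(pmax(11, age), each = n_rounds)
      df$iq <- rep(pmax(70, iq), each = n_rounds)
    }
    df
  })
  beast_cohort(do.call(rbind, parts))
}
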