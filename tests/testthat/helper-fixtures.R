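## Fixtures built in code: small hand-constructed cohorts and a random
## cohort generator independent of the package's simulator (used for
## round-trip and filtering properties).

make_rounds <- function(id, group, e1, x, e2,
                        true_count = c(43L, 58L, 34L, 44L, 39L)) {
  data.frame(participant_id = id, group = group,
             round = seq_along(e1), true_count = true_count[seq_along(e1)],
             e1 = as.integer(e1), x = as.integer(x), e2 = as.integer(e2),
             stringsAsFactors = FALSE)
}

## random raw cohort: integer estimates, arbitrary (possibly invalid) e2
random_cohort <- function(n_participants = 4L, with_covariates = FALSE) {
  parts <- lapply(seq_len(n_participants), function(i) {
    g <- sample(c("TD", "CP_LCU", "CP_HCU"), 1L)
    e1 <- sample(10:60, 5L, replace = TRUE)
    x <- e1 + sample(c(-8:-2, 2:8), 5L, replace = TRUE)
    x <- pmax(1L, x)
    e2 <- pmax(1L, e1 + sample(-12:12, 5L, replace = TRUE))
    df <- make_rounds(sprintf("p%03d", i), g, e1, x, e2)
    if (with_covariates) {
      df$age <- round(runif(1, 11, 16), 1)
      df$iq <- round(runif(1, 75, 115))
    }
    df
  })
  beast_cohort(do.call(rbind, parts))
}

## deterministic two-participant, five-round well-formed cohort
tiny_cohort <- function() {
  beast_cohort(rbind(
    make_rounds("a1", "TD", e1 = c(30, 40, 25, 31, 28),
                x = c(36, 48, 30, 26, 34), e2 = c(33, 48, 25, 29, 30)),
    make_rounds("b2", "CP_LCU", e1 = c(28, 39, 22, 30, 27),
                x = c(34, 47, 27, 25, 33), e2 = c(28, 39, 27, 30, 33))))
}

## small simulated cohort from a fixed, known profile (no calibration)
fixed_profile <- function(group = "TD", p_stay = 0.2, p_copy = 0.15,
                          p_comp = 0.65, beta_a = 8, beta_b = 14,
                          tau00 = 3.96) {
  strategy_profile(group, p_stay, p_copy, p_comp, beta_a, beta_b, tau00,
                   accuracy_median = 0.67, accuracy_cv = 0.25,
                   age_mean = 14, age_sd = 1.3, iq_mean = 90, iq_sd = 10)
}
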