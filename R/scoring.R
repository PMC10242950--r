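## Scoring: adjustment weight s, strategy classification, round validity and
## participant exclusion. Classification is done in exact integer arithmetic
## (the task records integer keyboard entries), so s = 0, s = 1 and the
## strict interval bounds involve no floating-point tie-breaking.

#' Adjustment weight (weight of advice)
#'
#' `s = (E2 - E1) / (X - E1)` measures the relative distance moved towards
#' the social information: the second estimate decomposes as
#' `E2 = (1 - s) * E1 + s * X`. Undefined (`NA`) when `X = E1`.
#'
#' @param e1,x,e2 positive integer vectors: first estimate, social
#'   information, second estimate.
#' @return Numeric vector of adjustment weights; `NA` where `x == e1`.
#'   The numerator/denominator pair is exact; the returned double is the
#'   IEEE quotient of the two integers.
#' @examples
#' adjustment_weight(40, 50, 45)  # 0.5
#' adjustment_weight(40, 50, 40)  # 0 (stay)
#' adjustment_weight(40, 50, 55)  # 1.5 (overshoot, invalid downstream)
#' @export
adjustment_weight <- function(e1, x, e2) {
  if (any(e1 < 1 | x < 1 | e2 < 1)) {
    stop("domain error: estimates must be positive", call. = FALSE)
  }
  n <- max(length(e1), length(x), length(e2))
  e1 <- rep_len(as.numeric(e1), n)
  x <- rep_len(as.numeric(x), n)
  e2 <- rep_len(as.numeric(e2), n)
  s <- (e2 - e1) / (x - e1)
  s[x == e1] <- NA_real_
  s
}

#' Classify a round's strategy
#'
#' Integer-exact classification of one or more rounds:
#' * `stay`: `E2 = E1` (`s = 0`)
#' * `copy`: `E2 = X != E1` (`s = 1`)
#' * `compromise`: `E2` strictly between `E1` and `X` (`0 < s < 1`)
#' * `invalid_negative`: adjustment away from `X` (`s < 0`)
#' * `invalid_overshoot`: past `X` (`s > 1`)
#' * `undefined_zero_distance`: `X = E1`, `s` undefined
#'
#' `stay`, `copy` and `compromise` are exactly the rounds with
#' `0 <= s <= 1`; `stay` and `copy` jointly form the "all-or-nothing"
#' strategies.
#'
#' @inheritParams adjustment_weight
#' @return Factor with levels `stay, copy, compromise, invalid_negative,
#'   invalid_overshoot, undefined_zero_distance`.
#' @examples
#' classify_round(40, 50, 44)  # compromise
#' classify_round(40, 50, 38)  # invalid_negative
#' @export
classify_round <- function(e1, x, e2) {
  if (any(e1 < 1 | x < 1 | e2 < 1)) {
    stop("domain error: estimates must be positive", call. = FALSE)
  }
  n <- max(length(e1), length(x), length(e2))
  e1 <- rep_len(as.integer(e1), n)
  x <- rep_len(as.integer(x), n)
  e2 <- rep_len(as.integer(e2), n)

  num <- e2 - e1          # s numerator
  den <- x - e1           # s denominator
  lab <- character(n)
  zero <- den == 0L
  lab[zero] <- "undefined_zero_distance"
  lab[!zero & num == 0L] <- "stay"
  lab[!zero & e2 == x] <- "copy"
  ## remaining: compare sign and magnitude of num vs den, all integers
  rest <- !zero & num != 0L & e2 != x
  opposite <- rest & (sign(num) != sign(den))
  lab[opposite] <- "invalid_negative"
  beyond <- rest & !opposite & (abs(num) > abs(den))
  lab[beyond] <- "invalid_overshoot"
  lab[rest & !opposite & !beyond] <- "compromise"
  factor(lab, levels = ROUND_LABELS)
}

#' Score a cohort
#'
#' Adds the adjustment weight `s`, the strategy `label` and a round-validity
#' flag `is_valid` (label in stay/copy/compromise) to every round.
#'
#' @param cohort a [beast_cohort()].
#' @return The cohort with scored rounds (class `beast_cohort`).
#' @export
score_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "beast_cohort"))
  r <- cohort$rounds
  r$s <- adjustment_weight(r$e1, r$x, r$e2)
  r$label <- classify_round(r$e1, r$x, r$e2)
  r$is_valid <- r$label %in% VALID_LABELS
  cohort$rounds <- r
  cohort
}

#' Apply the participant-exclusion rule
#'
#' Rounds with `s < 0`, `s > 1` or undefined `s` are qualitatively different
#' from expected task behaviour and are dropped from modelling. Participants
#' with three or more such rounds (of five) are excluded entirely and logged
#' with reason `too_many_invalid_rounds`.
#'
#' @param cohort a scored [beast_cohort()] (see [score_cohort()]).
#' @param max_invalid maximum tolerated invalid rounds per participant
#'   (default 2; three or more excludes).
#' @return A list with elements
#'   \describe{
#'     \item{retained}{the filtered `beast_cohort`, exclusions appended to
#'       its log;}
#'     \item{report}{a list with `n_excluded`, `excluded_ids`, counts of
#'       invalid rounds by type (`invalid_counts`), the total number of
#'       rounds scored (`n_rounds`) and of valid rounds retained
#'       (`n_valid_rounds`). Raw counts are reported with their explicit
#'       denominator.}
#'   }
#' @export
filter_participants <- function(cohort, max_invalid = 2L) {
  stopifnot(inherits(cohort, "beast_cohort"))
  if (!"label" %in% names(cohort$rounds)) cohort <- score_cohort(cohort)
  r <- cohort$rounds
  inval <- !r$is_valid
  n_inval <- tapply(inval, r$participant_id, sum)
  excluded_ids <- names(n_inval)[n_inval > max_invalid]

  keep <- !(r$participant_id %in% excluded_ids)
  retained <- cohort
  retained$rounds <- r[keep, , drop = FALSE]
  rownames(retained$rounds) <- NULL
  if (length(excluded_ids) > 0L) {
    retained$exclusion_log <- rbind(
      retained$exclusion_log,
      data.frame(participant_id = excluded_ids,
                 reason = "too_many_invalid_rounds",
                 stringsAsFactors = FALSE))
  }

  inv_tab <- table(r$label[inval])
  report <- list(
    n_excluded = length(excluded_ids),
    excluded_ids = excluded_ids,
    invalid_counts = inv_tab[intersect(names(inv_tab), setdiff(ROUND_LABELS, VALID_LABELS))],
    n_rounds = nrow(r),
    n_valid_rounds = sum(retained$rounds$is_valid))
  list(retained = retained, report = report)
}

#' Per-participant summaries
#'
#' For retained participants: mean adjustment over valid rounds, proportion
#' of valid rounds with `s < 0.5`, strategy counts, and first-estimate
#' accuracy `mean(E1 / true_count)` over all five rounds (validity concerns
#' `E2` only, so accuracy uses every round).
#'
#' @param cohort a scored, filtered [beast_cohort()].
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `age`/`iq` when present, `n_valid_rounds`, `mean_s`,
#'   `prop_s_below_half`, `n_stay`, `n_copy`, `n_compromise`,
#'   `accuracy_ratio`.
#' @export
summarize_participants <- function(cohort) {
  stopifnot(inherits(cohort, "beast_cohort"))
  if (!"label" %in% names(cohort$rounds)) cohort <- score_cohort(cohort)
  r <- cohort$rounds
  ids <- unique(r$participant_id)
  out <- lapply(ids, function(id) {
    ri <- r[r$participant_id == id, , drop = FALSE]
    v <- ri[ri$is_valid, , drop = FALSE]
    if (nrow(v) == 0L) {
      stop(sprintf("undefined summary: participant '%s' has zero valid rounds", id),
           call. = FALSE)
    }
    data.frame(
      participant_id = id,
      group = ri$group[1L],
      age = if ("age" %in% names(ri)) ri$age[1L] else NA_real_,
      iq = if ("iq" %in% names(ri)) ri$iq[1L] else NA_real_,
      n_valid_rounds = nrow(v),
      mean_s = mean(v$s),
      prop_s_below_half = mean(v$s < 0.5),
      n_stay = sum(v$label == "stay"),
      n_copy = sum(v$label == "copy"),
      n_compromise = sum(v$label == "compromise"),
      accuracy_ratio = mean(ri$e1 / ri$true_count),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Round-level strategy frequencies by group
#'
#' Counts and shares of stay/copy/compromise among valid rounds, by group --
#' the tabular analogue of the study's strategy-frequency figure. Raw counts
#' accompany every percentage.
#'
#' @param cohort a scored [beast_cohort()].
#' @return data.frame with columns `group`, `label`, `n`, `n_valid`, `pct`.
#' @export
strategy_frequencies <- function(cohort) {
  stopifnot(inherits(cohort, "beast_cohort"))
  if (!"label" %in% names(cohort$rounds)) cohort <- score_cohort(cohort)
  r <- cohort$rounds[cohort$rounds$is_valid, , drop = FALSE]
  tab <- table(r$group, factor(r$label, levels = VALID_LABELS))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("group", "label", "n")
  tot <- rowSums(tab)
  df$n_valid <- as.integer(tot[df$group])
  df$pct <- ifelse(df$n_valid > 0, 100 * df$n / df$n_valid, NA_real_)
  df[order(df$group, df$label), c("group", "label", "n", "n_valid", "pct")]
}
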