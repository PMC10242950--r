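## Task engine: fixed stimulus schedule and the calibrated social-information
## rule. X is placed a roughly constant *relative* distance from E1, which
## holds the scope for adjustment constant across estimate magnitudes and
## controls away distance-weighting effects.

#' Task configuration
#'
#' The task shows five animal images in a fixed order (43, 58, 34, 44, 39
#' animals), chosen for similar difficulty. The social information `X` shown
#' after the first estimate is calibrated to `E1`: a multiplicative offset
#' whose magnitude is uniform on `delta_band` and whose sign follows a
#' balanced per-round schedule, so adjustments upward and downward are both
#' probed.
#'
#' @param true_counts stimulus animal counts, in presentation order.
#' @param delta_band length-2 numeric, lower/upper bound of the relative
#'   offset magnitude `|X - E1| / E1` (default 15-25%).
#' @param sign_schedule integer vector of +1/-1 per round; must contain at
#'   least two of each sign over five rounds.
#' @param min_distance minimum integer distance `|X - E1|` (default 2, so an
#'   interior integer exists and a compromise is always representable).
#' @return A list of class `beast_task`.
#' @export
task_config <- function(true_counts = c(43L, 58L, 34L, 44L, 39L),
                        delta_band = c(0.15, 0.25),
                        sign_schedule = c(1L, -1L, 1L, -1L, 1L),
                        min_distance = 2L) {
  stopifnot(length(delta_band) == 2L,
            delta_band[1L] > 0, delta_band[1L] < delta_band[2L],
            delta_band[2L] < 1)
  stopifnot(all(sign_schedule %in% c(-1L, 1L)),
            length(sign_schedule) == length(true_counts))
  if (sum(sign_schedule == 1L) < 2L || sum(sign_schedule == -1L) < 2L) {
    stop("sign_schedule must contain at least two of each sign",
         call. = FALSE)
  }
  stopifnot(all(true_counts >= 1), min_distance >= 1)
  structure(list(true_counts = as.integer(true_counts),
                 delta_band = as.numeric(delta_band),
                 sign_schedule = as.integer(sign_schedule),
                 min_distance = as.integer(min_distance)),
            class = "beast_task")
}

#' Stimulus schedule
#'
#' @param config a [task_config()].
#' @return The five true animal counts in fixed presentation order.
#' @export
stimulus_sequence <- function(config = task_config()) {
  config$true_counts
}

#' Generate calibrated social information
#'
#' Draws `X = round(E1 * (1 + sign * delta))` with `delta` uniform on the
#' configured band and the sign taken from the round's slot in the sign
#' schedule. If the rounded offset falls below `min_distance` (possible for
#' small `E1`), `delta` is redrawn up to 100 times; as a last resort
#' `X = E1 + sign * min_distance`, with the sign flipped upward when the
#' fallback would leave `X < 1`. Consequently `X != E1` always, so the
#' adjustment weight is defined on every generated round.
#'
#' Uses the current R random number stream; seed with [set.seed()] for
#' reproducibility. Vectorized over `e1` and `round_index`.
#'
#' @param e1 positive integer first estimate(s).
#' @param round_index round number(s) in 1..5, selecting the schedule sign.
#' @param config a [task_config()].
#' @return Integer vector of social information values `X`.
#' @export
generate_social_info <- function(e1, round_index, config = task_config()) {
  e1 <- as.integer(e1)
  if (any(e1 < 1L)) stop("domain error: e1 must be >= 1", call. = FALSE)
  n <- max(length(e1), length(round_index))
  e1 <- rep_len(e1, n)
  round_index <- rep_len(as.integer(round_index), n)
  stopifnot(all(round_index >= 1L),
            all(round_index <= length(config$sign_schedule)))
  sgn <- config$sign_schedule[round_index]
  lo <- config$delta_band[1L]; hi <- config$delta_band[2L]
  md <- config$min_distance

  delta <- runif(n, lo, hi)
  x <- as.integer(round(e1 * (1 + sgn * delta)))
  bad <- which(abs(x - e1) < md | x < 1L)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    delta_b <- runif(length(bad), lo, hi)
    x[bad] <- as.integer(round(e1[bad] * (1 + sgn[bad] * delta_b)))
    bad <- bad[abs(x[bad] - e1[bad]) < md | x[bad] < 1L]
    tries <- tries + 1L
  }
  if (length(bad) > 0L) {
    xf <- e1[bad] + sgn[bad] * md
    flip <- xf < 1L
    xf[flip] <- e1[bad][flip] + md
    x[bad] <- as.integer(xf)
  }
  x
}
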