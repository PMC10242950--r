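## Core cohort container: round-level trial table + exclusion log.

#' @keywords internal
BEAST_GROUPS <- c("TD", "CP_LCU", "CP_HCU")

#' @keywords internal
ROUND_LABELS <- c("stay", "copy", "compromise",
                  "invalid_negative", "invalid_overshoot",
                  "undefined_zero_distance")

#' @keywords internal
VALID_LABELS <- c("stay", "copy", "compromise")

#' Construct a BEAST cohort object
#'
#' A cohort is the round-level trial table of a study sample together with an
#' exclusion log. Each row of `rounds` is one task round: participant id,
#' group label, round index (1-5), true animal count, first estimate `e1`,
#' social information `x`, and second estimate `e2`. Estimates are keyboard
#' entries and therefore positive integers.
#'
#' @param rounds data.frame with columns `participant_id`, `group`, `round`,
#'   `true_count`, `e1`, `x`, `e2`; optional numeric `age` and `iq` columns
#'   (constant within participant).
#' @param exclusion_log data.frame with columns `participant_id`, `reason`,
#'   one row per excluded participant. Defaults to an empty log.
#' @return An object of class `beast_cohort`: a list with elements `rounds`
#'   and `exclusion_log`.
#' @examples
#' rounds <- data.frame(
#'   participant_id = rep("p1", 5), group = "TD", round = 1:5,
#'   true_count = c(43L, 58L, 34L, 44L, 39L),
#'   e1 = c(30L, 40L, 25L, 31L, 28L),
#'   x  = c(36L, 48L, 30L, 26L, 34L),
#'   e2 = c(33L, 48L, 25L, 29L, 30L))
#' beast_cohort(rounds)
#' @export
beast_cohort <- function(rounds, exclusion_log = NULL) {
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(participant_id = character(0),
                                reason = character(0),
                                stringsAsFactors = FALSE)
  }
  rounds <- validate_rounds(rounds)
  stopifnot(is.data.frame(exclusion_log),
            all(c("participant_id", "reason") %in% names(exclusion_log)))
  exclusion_log$participant_id <- as.character(exclusion_log$participant_id)
  exclusion_log$reason <- as.character(exclusion_log$reason)
  structure(list(rounds = rounds, exclusion_log = exclusion_log),
            class = "beast_cohort")
}

## Schema + integrity validation shared by the constructor and load_cohort().
## `origin_rows` maps data rows to source-file rows for error messages.
validate_rounds <- function(rounds, origin_rows = NULL) {
  required <- c("participant_id", "group", "round", "true_count",
                "e1", "x", "e2")
  missing <- setdiff(required, names(rounds))
  if (length(missing) > 0L) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(origin_rows)) origin_rows <- seq_len(nrow(rounds))

  rounds$participant_id <- as.character(rounds$participant_id)

  grp <- as.character(rounds$group)
  bad_grp <- which(!grp %in% BEAST_GROUPS)
  if (length(bad_grp) > 0L) {
    stop(sprintf("value error: unknown group '%s' at row %d (expected %s)",
                 grp[bad_grp[1L]], origin_rows[bad_grp[1L]],
                 paste(BEAST_GROUPS, collapse = "/")), call. = FALSE)
  }
  rounds$group <- factor(grp, levels = BEAST_GROUPS)

  for (col in c("round", "true_count", "e1", "x", "e2")) {
    v <- rounds[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
    } else {
      num <- as.numeric(v)
    }
    bad <- which(is.na(num) | num != round(num))
    if (length(bad) > 0L) {
      stop(sprintf("value error: column '%s' has non-integer value '%s' at row %d",
                   col, as.character(v[bad[1L]]), origin_rows[bad[1L]]),
           call. = FALSE)
    }
    rounds[[col]] <- as.integer(num)
  }

  low <- which(rounds$true_count < 1L | rounds$e1 < 1L |
                 rounds$x < 1L | rounds$e2 < 1L)
  if (length(low) > 0L) {
    stop(sprintf("value error: non-positive count/estimate at row %d",
                 origin_rows[low[1L]]), call. = FALSE)
  }
  bad_round <- which(rounds$round < 1L | rounds$round > 5L)
  if (length(bad_round) > 0L) {
    stop(sprintf("value error: round index out of 1..5 at row %d",
                 origin_rows[bad_round[1L]]), call. = FALSE)
  }

  key <- paste(rounds$participant_id, rounds$round, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("integrity error: duplicated (participant, round) = ('%s', %d) at row %d",
                 rounds$participant_id[dup[1L]], rounds$round[dup[1L]],
                 origin_rows[dup[1L]]), call. = FALSE)
  }

  ## one group (and age/iq, when present) per participant
  for (col in intersect(c("group", "age", "iq"), names(rounds))) {
    n_per <- tapply(rounds[[col]], rounds$participant_id,
                    function(z) length(unique(z)))
    if (any(n_per > 1L)) {
      stop(sprintf("integrity error: participant '%s' has inconsistent '%s'",
                   names(n_per)[which(n_per > 1L)[1L]], col), call. = FALSE)
    }
  }

  for (col in intersect(c("age", "iq"), names(rounds))) {
    rounds[[col]] <- as.numeric(rounds[[col]])
  }

  ord <- order(rounds$participant_id, rounds$round)
  rounds <- rounds[ord, , drop = FALSE]
  rownames(rounds) <- NULL
  rounds
}

#' Read a round-level cohort CSV
#'
#' Expects a comma-separated, UTF-8, header-row file with columns
#' `participant_id, group, round, true_count, e1, x, e2` (optional `age`,
#' `iq`). Estimates must be positive integers; schema violations are
#' reported with the offending file row (header = row 1).
#'
#' @param path path to a CSV file.
#' @return A [beast_cohort()] with an empty exclusion log.
#' @seealso [write_cohort()]
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = TRUE,
                  fileEncoding = "UTF-8")
  ## file row numbers: header occupies row 1
  beast_cohort(validate_rounds(raw, origin_rows = seq_len(nrow(raw)) + 1L))
}

#' Write a cohort to CSV
#'
#' The written file round-trips: `load_cohort(write_cohort(c, f))`
#' reproduces `c` field for field (the exclusion log is written separately,
#' see [write_exclusion_log()]).
#'
#' @param cohort a [beast_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "beast_cohort"))
  out <- cohort$rounds
  out$group <- as.character(out$group)
  ## drop derived scoring columns so the file is always the raw schema
  keep <- intersect(c("participant_id", "group", "round", "true_count",
                      "e1", "x", "e2", "age", "iq"), names(out))
  write.csv(out[keep], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the exclusion log to CSV
#'
#' @param cohort a [beast_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  stopifnot(inherits(cohort, "beast_cohort"))
  write.csv(cohort$exclusion_log, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @method print beast_cohort
#' @export
print.beast_cohort <- function(x, ...) {
  n_part <- length(unique(x$rounds$participant_id))
  cat(sprintf("<beast_cohort> %d participants, %d rounds\n",
              n_part, nrow(x$rounds)))
  tab <- table(x$rounds$group[!duplicated(x$rounds$participant_id)])
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (nrow(x$exclusion_log) > 0L) {
    cat(sprintf("  exclusions logged: %d\n", nrow(x$exclusion_log)))
  }
  if ("label" %in% names(x$rounds)) {
    cat("  scored: yes\n")
  }
  invisible(x)
}

#' @method summary beast_cohort
#' @export
summary.beast_cohort <- function(object, ...) {
  r <- object$rounds
  by_grp <- table(r$group[!duplicated(r$participant_id)])
  out <- list(n_participants = sum(by_grp), by_group = by_grp,
              n_rounds = nrow(r),
              n_excluded = nrow(object$exclusion_log),
              scored = "label" %in% names(r))
  if (out$scored) out$label_table <- table(r$label)
  class(out) <- "summary.beast_cohort"
  out
}

#' @method print summary.beast_cohort
#' @export
print.summary.beast_cohort <- function(x, ...) {
  cat(sprintf("BEAST cohort: %d participants (%s), %d rounds, %d excluded\n",
              x$n_participants,
              paste(sprintf("%s %d", names(x$by_group), x$by_group),
                    collapse = ", "),
              x$n_rounds, x$n_excluded))
  if (isTRUE(x$scored)) {
    cat("round labels:\n")
    print(x$label_table)
  }
  invisible(x)
}
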