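## End-to-end pipeline: simulate -> score -> filter -> summarize -> fit ->
## report bundle. Deterministic given (config, seed); every stage logged.

#' Pipeline configuration
#'
#' @param simulation a [simulation_config()].
#' @param codings strategy-model codings to fit (subset of
#'   `aon_vs_comp`, `stay_vs_rest`, `copy_vs_rest`).
#' @param covariate_sets list of covariate vectors; each strategy and
#'   adjustment model is re-fit once per set (default: none, then
#'   age + IQ).
#' @param n_replicates when `> 1`, a replicate parameter-recovery run of
#'   the primary strategy model is added to the bundle.
#' @param output_dir directory for the report bundle; created if absent.
#' @param log_level `"info"` (stage messages to stderr) or `"quiet"`.
#' @return A list of class `beast_pipeconfig`. Validation happens here,
#'   before any computation: unknown codings or covariates fail
#'   immediately.
#' @export
pipeline_config <- function(simulation,
                            codings = c("aon_vs_comp", "stay_vs_rest",
                                        "copy_vs_rest"),
                            covariate_sets = list(character(0),
                                                  c("age", "iq")),
                            n_replicates = 1L,
                            output_dir = tempfile("beast_run_"),
                            log_level = c("info", "quiet")) {
  stopifnot(inherits(simulation, "beast_simconfig"))
  bad <- setdiff(codings, STRATEGY_CODINGS)
  if (length(bad) > 0L) {
    stop("validation error: unknown coding(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (cs in covariate_sets) validate_covariates(cs)
  stopifnot(n_replicates >= 1L)
  log_level <- match.arg(log_level)
  structure(list(simulation = simulation, codings = codings,
                 covariate_sets = covariate_sets,
                 n_replicates = as.integer(n_replicates),
                 output_dir = output_dir, log_level = log_level),
            class = "beast_pipeconfig")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a configuration such as the packaged
#' `system.file("extdata", "paper_defaults.yaml", package = "beastr")`,
#' which embeds the published calibration targets, group sizes, task
#' settings and a mandatory seed.
#'
#' @param path YAML file path.
#' @param output_dir overrides the config's output directory when given.
#' @param seed overrides the config's seed when given.
#' @param refine_profiles logical; discretization-aware calibration
#'   refinement (default `TRUE`).
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path, output_dir = NULL, seed = NULL,
                                 refine_profiles = TRUE) {
  cfg <- yaml::read_yaml(path)
  tk <- cfg$task
  task <- task_config(
    true_counts = as.integer(tk$true_counts),
    delta_band = as.numeric(tk$delta_band),
    sign_schedule = as.integer(tk$sign_schedule),
    min_distance = as.integer(tk$min_distance))

  profs <- lapply(names(cfg$groups), function(g) {
    p <- cfg$groups[[g]]
    calibrate_profile(
      group = g, p_comp = p$p_comp, mean_s = p$mean_s,
      prop_s_below_half = p$prop_s_below_half, tau00 = p$tau00,
      accuracy_median = p$accuracy_mean / exp(p$accuracy_cv^2 / 2),
      accuracy_cv = p$accuracy_cv,
      refine = refine_profiles, task = task,
      age_mean = p$age_mean, age_sd = p$age_sd,
      iq_mean = p$iq_mean, iq_sd = p$iq_sd)
  })
  names(profs) <- names(cfg$groups)

  sizes <- vapply(cfg$groups, function(p) as.integer(p$n_participants), integer(1))
  if (is.null(seed)) seed <- cfg$seed
  sim <- simulation_config(
    group_sizes = sizes, profiles = profs, task = task, seed = seed,
    invalid_rate = if (is.null(cfg$invalid_rate)) 0 else cfg$invalid_rate,
    simulate_covariates = !isFALSE(cfg$simulate_covariates))

  pipeline_config(
    simulation = sim,
    codings = if (is.null(cfg$codings)) STRATEGY_CODINGS else cfg$codings,
    covariate_sets = if (is.null(cfg$covariate_sets)) {
      list(character(0), c("age", "iq"))
    } else lapply(cfg$covariate_sets, as.character),
    n_replicates = if (is.null(cfg$n_replicates)) 1L else cfg$n_replicates,
    output_dir = if (is.null(output_dir)) {
      if (is.null(cfg$output_dir)) tempfile("beast_run_") else cfg$output_dir
    } else output_dir)
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[beastr] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, scores and filters it, summarizes participants, fits
#' the adjustment model and the requested strategy models under each
#' covariate set, and writes a report bundle to the configured output
#' directory: `scored.csv`, `exclusions.csv`, `summaries.csv`,
#' `strategy_frequencies.csv`, `model_table.md`, `accuracy_anova.csv` and,
#' when `n_replicates > 1`, `recovery.csv` with per-parameter recovery
#' bias. Any stage failure aborts with the stage name; outputs of completed
#' stages remain on disk.
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [load_pipeline_config()]).
#' @return Invisibly, the bundle as a list: `cohort`, `scored`, `retained`,
#'   `filter_report`, `summaries`, `fits` (named by
#'   `coding[+covariates]`), `adjustment fits`, `anova`, `frequencies`,
#'   `recovery`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "beast_pipeconfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(output_dir = config$output_dir)

  stage <- function(name, expr) {
    pipe_log(config, "stage %s (seed %d)", name, config$simulation$seed)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  out$cohort <- stage("simulate", simulate_cohort(config$simulation))
  out$scored <- stage("score", score_cohort(out$cohort))
  flt <- stage("filter", filter_participants(out$scored))
  out$retained <- flt$retained
  out$filter_report <- flt$report
  out$summaries <- stage("summarize", summarize_participants(out$retained))
  out$frequencies <- stage("frequencies", strategy_frequencies(out$retained))

  write_cohort(out$scored, file.path(config$output_dir, "cohort.csv"))
  scored_csv <- out$scored$rounds
  scored_csv$group <- as.character(scored_csv$group)
  write.csv(scored_csv, file.path(config$output_dir, "scored.csv"),
            row.names = FALSE, quote = FALSE)
  write_exclusion_log(out$retained,
                      file.path(config$output_dir, "exclusions.csv"))
  write.csv(out$summaries, file.path(config$output_dir, "summaries.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(out$frequencies,
            file.path(config$output_dir, "strategy_frequencies.csv"),
            row.names = FALSE, quote = FALSE)

  out$fits <- list()
  for (cs in config$covariate_sets) {
    tag <- if (length(cs) == 0L) "" else paste0("+", paste(cs, collapse = "_"))
    out$fits[[paste0("adjustment", tag)]] <-
      stage(paste0("fit adjustment", tag),
            fit_adjustment_model(out$retained, covariates = cs))
    for (cd in config$codings) {
      out$fits[[paste0(cd, tag)]] <-
        stage(paste0("fit ", cd, tag),
              fit_strategy_model(out$retained, coding = cd,
                                 covariates = cs))
    }
  }
  out$anova <- stage("accuracy anova", anova_accuracy(out$summaries))
  write.csv(as.data.frame(out$anova),
            file.path(config$output_dir, "accuracy_anova.csv"),
            row.names = FALSE, quote = FALSE)

  writeLines(report_markdown(out),
             file.path(config$output_dir, "model_table.md"))

  if (config$n_replicates > 1L) {
    out$recovery <- stage("recovery", {
      primary <- out$fits[["aon_vs_comp"]]
      beta <- coef(primary)[seq_len(nlevels(out$retained$rounds$group))]
      rec <- recover_strategy_glmm(
        beta = beta, tau00 = primary$tau00,
        group_sizes = config$simulation$group_sizes,
        n_replicates = config$n_replicates,
        seed = config$simulation$seed + 1L)
      truth <- c(beta, primary$tau00)
      med <- apply(rec, 2, median)
      data.frame(parameter = names(med), generating = truth,
                 median_fitted = unname(med),
                 bias = unname(med) - truth)
    })
    write.csv(out$recovery, file.path(config$output_dir, "recovery.csv"),
              row.names = FALSE, quote = FALSE)
  }
  pipe_log(config, "bundle written to %s", config$output_dir)
  invisible(out)
}

## Markdown report table mirroring the two-model layout of the study:
## estimates / ORs with CIs and p per model column, then variance
## components, ICC, N, observations and R2. Raw counts accompany the
## strategy percentages.
report_markdown <- function(bundle) {
  f1 <- bundle$fits[["adjustment"]]
  f2 <- bundle$fits[["aon_vs_comp"]]
  fmt_lin <- function(fe, term) {
    i <- match(term, fe$term)
    if (is.na(i)) return("--")
    sprintf("%.2f (%.2f to %.2f), p=%.3f",
            fe$estimate[i], fe$ci_lo[i], fe$ci_hi[i], fe$p[i])
  }
  fmt_or <- function(fe, term) {
    i <- match(term, fe$term)
    if (is.na(i)) return("--")
    sprintf("%.2f (%.2f to %.2f), p=%.3f",
            fe$odds_ratio[i], fe$or_lo[i], fe$or_hi[i], fe$p[i])
  }
  terms <- unique(c(f1$fixed_effects$term, f2$fixed_effects$term))
  lines <- c(
    "| Predictors | Adjustment (estimates) | All-or-nothing vs compromise (odds ratios) |",
    "|---|---|---|",
    vapply(terms, function(tm) {
      sprintf("| %s | %s | %s |", tm,
              fmt_lin(f1$fixed_effects, tm), fmt_or(f2$fixed_effects, tm))
    }, character(1)),
    sprintf("| sigma2 | %.2f | %.2f |", f1$sigma2, f2$sigma2),
    sprintf("| tau00 | %.2f | %.2f |", f1$tau00, f2$tau00),
    sprintf("| ICC | %.2f | %.2f |", f1$icc, f2$icc),
    sprintf("| N participants | %d | %d |",
            f1$n_participants, f2$n_participants),
    sprintf("| Observations | %d | %d |",
            f1$n_observations, f2$n_observations),
    sprintf("| Marginal R2 / conditional R2 | %.3f / %.3f | %.3f / %.3f |",
            f1$r2_marginal, f1$r2_conditional,
            f2$r2_marginal, f2$r2_conditional),
    "",
    "Strategy frequencies by group (valid rounds):",
    "",
    "| group | label | n | n_valid | pct |",
    "|---|---|---|---|---|",
    with(bundle$frequencies,
         sprintf("| %s | %s | %d | %d | %.2f |",
                 group, label, n, n_valid, pct)))
  lines
}

#' Strategy-frequency bar chart
#'
#' Simple base-graphics analogue of the study's strategy-frequency figure:
#' relative frequency of stay/copy/compromise by group among valid rounds.
#'
#' @param cohort a scored [beast_cohort()].
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the group-by-label percentage matrix.
#' @export
plot_strategy_frequencies <- function(cohort, ...) {
  fr <- strategy_frequencies(cohort)
  m <- matrix(fr$pct, nrow = length(VALID_LABELS),
              dimnames = list(unique(fr$label), unique(fr$group)))
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "% of valid rounds", ...)
  invisible(m)
}
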