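#' Pipeline configuration
#'
#' Assembles the configuration for \code{\link{run_pipeline}}. Two presets
#' are provided: \code{"paper"}, the full study design (19 adolescent + 17
#' adult RSAV agents at the group-mean parameters, 2 runs of 60 trials), and
#' \code{"tiny"}, a seconds-scale smoke configuration (2 subjects per group,
#' 2 runs of 10 trials, few optimizer restarts) that still exercises every
#' stage.
#'
#' @param preset \code{"paper"} or \code{"tiny"}.
#' @param seed master seed for every stage.
#' @param n_starts optimizer restarts per fit (preset default when NULL).
#' @param mc_samples Monte-Carlo samples for exceedance probabilities.
#' @return a list of class \code{"pipeline_config"} with sections
#'   \code{task}, \code{cohort} (two \code{\link{group_spec}}s),
#'   \code{fitting}, and \code{selection}.
#' @export
pipeline_config <- function(preset = c("paper", "tiny"), seed = 1L,
                            n_starts = NULL, mc_samples = 1e6) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    cfg <- list(preset = preset,
                task = task_config(),
                cohort = list(adolescent = adolescent_spec(),
                              adult = adult_spec()),
                fitting = list(n_starts = if (is.null(n_starts)) 16L
                               else as.integer(n_starts), seed = as.integer(seed)),
                selection = list(prior_alpha = 1, mc_samples = mc_samples,
                                 tol = 1e-6))
  } else {
    cfg <- list(preset = preset,
                task = task_config(trials_per_run = 10L),
                cohort = list(adolescent = adolescent_spec(2L),
                              adult = adult_spec(2L)),
                fitting = list(n_starts = if (is.null(n_starts)) 4L
                               else as.integer(n_starts), seed = as.integer(seed)),
                selection = list(prior_alpha = 1, mc_samples = 1e4,
                                 tol = 1e-6))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full model-based analysis pipeline
#'
#' End-to-end orchestration on a synthetic cohort: simulate the two-group
#' cohort, fit all three models to every subject, build a model-comparison
#' table (mean logL, per-trial AIC, and group-BMS exceedance probability per
#' model, per group and overall), fit the canonical RSAV parameter set
#' pooled over all subjects, compare the fitted RSAV parameters between
#' groups, and derive canonical-parameter RPE traces with tertile bins and
#' a group summary of the bin boundaries. When \code{output_dir} is given,
#' the cohort TSVs, per-subject fits, events/regressor files and a
#' machine-readable \code{results.json} are written there.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param output_dir optional output directory.
#' @return a list of class \code{"pipeline_result"}; see Details.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config("tiny", seed = 42))
#' res$model_table
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- lapply(c("rw", "rs", "rsav"), model_spec)

  cohort <- generate_cohort(config$cohort$adolescent, config$cohort$adult,
                            config = config$task,
                            master_seed = config$seed)
  records <- cohort$records
  groups <- cohort$truth$group

  settings <- fit_settings(config$fitting$n_starts, seed = config$fitting$seed)
  fits <- lapply(records, function(rec)
    lapply(models, function(m) fit_subject(rec, m, settings)))

  evidence <- aic_evidence(fits)
  sel <- config$selection
  bms_for <- function(rows) bms_group(evidence[rows, , drop = FALSE],
                                      prior_alpha = sel$prior_alpha,
                                      tol = sel$tol,
                                      n_samples = sel$mc_samples,
                                      seed = config$seed)
  bms <- list(all = bms_for(seq_along(records)))
  for (g in unique(groups)) bms[[g]] <- bms_for(which(groups == g))

  model_table <- do.call(rbind, lapply(seq_along(models), function(mi) {
    rows <- lapply(c(list(all = seq_along(records)),
                     lapply(stats::setNames(nm = unique(groups)),
                            function(g) which(groups == g))),
                   function(idx) {
                     ll <- vapply(fits[idx], function(f) f[[mi]]$logL, numeric(1))
                     aic <- vapply(fits[idx], function(f) f[[mi]]$AIC, numeric(1))
                     c(logL = mean(ll), logL_sd = sd(ll),
                       AIC = mean(aic), AIC_sd = sd(aic))
                   })
    out <- data.frame(model = models[[mi]]$name,
                      cohort = names(rows),
                      do.call(rbind, rows))
    out$p_exceedance <- vapply(out$cohort, function(co)
      unname(bms[[co]]$exceedance_prob[models[[mi]]$name]), numeric(1))
    out
  }))
  rownames(model_table) <- NULL

  canonical <- fit_canonical(records, model_spec("rsav"), settings)

  rsav_params <- do.call(rbind, lapply(fits, function(f) {
    as.data.frame(unclass(f[[3]]$params))
  }))
  rsav_params <- cbind(subject_id = names(records), group = groups, rsav_params)
  rownames(rsav_params) <- NULL
  group_tests <- if (min(table(groups)) >= 2L && length(unique(groups)) == 2L)
    compare_groups_parameters(rsav_params) else NULL

  traces <- lapply(records, compute_rpe_trace,
                   model = model_spec("rsav"), params = canonical$params)
  bins <- lapply(traces, bin_rpes)
  bound <- t(vapply(bins, function(b) b$boundaries, numeric(2)))
  boundary_summary <- do.call(rbind, lapply(unique(groups), function(g) {
    m <- bound[groups == g, , drop = FALSE]
    data.frame(group = g,
               lower_mean = mean(m[, "lower"]),
               lower_sem = sd(m[, "lower"]) / sqrt(nrow(m)),
               upper_mean = mean(m[, "upper"]),
               upper_sem = sd(m[, "upper"]) / sqrt(nrow(m)))
  }))

  behavior <- do.call(rbind, lapply(names(records), function(sid) {
    s <- summarize_behavior(records[[sid]])
    data.frame(subject_id = sid, group = groups[names(records) == sid][1],
               percent_correct = s$percent_correct,
               n_switches = s$n_switches,
               punishments_before_switch = s$mean_punishments_before_switch)
  }))

  result <- structure(list(config = config, cohort = cohort, fits = fits,
                           model_table = model_table, bms = bms,
                           canonical = canonical,
                           rsav_params = rsav_params,
                           group_tests = group_tests,
                           traces = traces, bins = bins,
                           boundary_summary = boundary_summary,
                           behavior = behavior,
                           seed = config$seed,
                           version = as.character(utils::packageVersion("flexrl"))),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(output_dir, "cohort"))
  ev_dir <- file.path(output_dir, "events")
  dir.create(ev_dir, showWarnings = FALSE)
  trial_s <- 9  # nominal trial duration in seconds; feedback mid-trial
  for (sid in names(result$traces)) {
    tr <- result$traces[[sid]]
    onsets <- list(cue = (tr$trial - 1) * trial_s,
                   feedback = (tr$trial - 1) * trial_s + 4.5)
    export_regressors(tr, result$bins[[sid]], onsets,
                      file = file.path(ev_dir, paste0(sid, "_events.tsv")))
  }
  json <- list(schema_version = "1.0",
               seed = result$seed,
               package_version = result$version,
               preset = result$config$preset,
               model_table = result$model_table,
               exceedance = lapply(result$bms, function(b)
                 as.list(b$exceedance_prob)),
               canonical_parameters = unclass(result$canonical$params),
               group_tests = if (!is.null(result$group_tests))
                 list(anova = result$group_tests$anova,
                      t_tests = result$group_tests$t_tests) else NULL,
               boundary_summary = result$boundary_summary,
               behavior = result$behavior)
  jsonlite::write_json(json, file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Reversal-learning pipeline (preset ", x$config$preset, ", seed ",
      x$seed, ")\n\nModel comparison:\n", sep = "")
  print(within(x$model_table, {
    logL <- round(logL, 3); logL_sd <- round(logL_sd, 3)
    AIC <- round(AIC, 3); AIC_sd <- round(AIC_sd, 3)
    p_exceedance <- round(p_exceedance, 4)
  }))
  cat("\nCanonical RSAV parameters:\n")
  print(round(x$canonical$par, 4))
  if (!is.null(x$group_tests)) {
    cat("\nGroup comparison of fitted RSAV parameters:\n")
    print(x$group_tests$t_tests)
  }
  invisible(x)
}
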