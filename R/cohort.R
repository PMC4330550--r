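#' Group specification for synthetic cohorts
#'
#' Describes a population of artificial subjects: group size and, per RSAV
#' parameter, the population mean and the published standard error of the
#' mean. Subject-level parameters are drawn from independent truncated
#' normals with SD recovered as \code{SEM * sqrt(n_subjects)}; learning rates
#' are truncated to [0, 1] and tau to [0.01, 10].
#'
#' \code{adolescent_spec()} and \code{adult_spec()} are the study presets:
#' 19 adolescents with group means (alpha_c+ = .62, alpha_c- = .69,
#' alpha_u+ = .78, alpha_u- = .63, tau = 1.9) and 17 adults with
#' (.45, .49, .72, .58, 2.4), with the corresponding published SEMs.
#'
#' @param label group label.
#' @param n_subjects group size (>= 1).
#' @param mean named numeric vector of parameter means (names
#'   \code{alpha_c_pos}, \code{alpha_c_neg}, \code{alpha_u_pos},
#'   \code{alpha_u_neg}, \code{tau}).
#' @param sem named numeric vector of standard errors (same names);
#'   zero gives a point mass at the mean.
#' @return an object of class \code{"group_spec"}.
#' @export
group_spec <- function(label, n_subjects, mean, sem) {
  par_names <- c("alpha_c_pos", "alpha_c_neg", "alpha_u_pos", "alpha_u_neg", "tau")
  stopifnot(n_subjects >= 1,
            all(par_names %in% names(mean)), all(par_names %in% names(sem)),
            all(sem[par_names] >= 0))
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 mean = mean[par_names], sem = sem[par_names],
                 sd = sem[par_names] * sqrt(n_subjects)),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
adolescent_spec <- function(n_subjects = 19L) {
  group_spec("adolescent", n_subjects,
             mean = c(alpha_c_pos = 0.62, alpha_c_neg = 0.69,
                      alpha_u_pos = 0.78, alpha_u_neg = 0.63, tau = 1.9),
             sem = c(alpha_c_pos = 0.07, alpha_c_neg = 0.05,
                     alpha_u_pos = 0.07, alpha_u_neg = 0.04, tau = 0.2))
}

#' @rdname group_spec
#' @export
adult_spec <- function(n_subjects = 17L) {
  group_spec("adult", n_subjects,
             mean = c(alpha_c_pos = 0.45, alpha_c_neg = 0.49,
                      alpha_u_pos = 0.72, alpha_u_neg = 0.58, tau = 2.4),
             sem = c(alpha_c_pos = 0.10, alpha_c_neg = 0.05,
                     alpha_u_pos = 0.08, alpha_u_neg = 0.06, tau = 0.2))
}

# inverse-CDF truncated normal draw; deterministic given the RNG stream
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  x <- qnorm(pl + runif(n) * (pu - pl), mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Draw subject-level parameters from a group specification
#'
#' Independent truncated-normal draws per parameter, using the current RNG
#' stream.
#'
#' @param spec a \code{\link{group_spec}}.
#' @return a \code{\link{subject_parameters}} object.
#' @export
sample_subject_parameters <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  lo <- c(0, 0, 0, 0, 0.01)
  hi <- c(1, 1, 1, 1, 10)
  draws <- mapply(function(m, s, l, h) rtruncnorm(1L, m, s, l, h),
                  spec$mean, spec$sd, lo, hi)
  subject_parameters(draws[["alpha_c_pos"]], draws[["alpha_c_neg"]],
                     draws[["alpha_u_pos"]], draws[["alpha_u_neg"]],
                     draws[["tau"]])
}

#' Generate a synthetic two-group cohort
#'
#' Reproduces the study design in silico: two groups of RSAV (by default)
#' agents with subject-level parameters drawn around the group means, each
#' playing a full session of the reversal-learning task. Ground-truth
#' parameters are retained for parameter-recovery scoring. Each subject gets
#' its own seed derived from the master seed, so records regenerate
#' bit-identically and per-subject simulation order cannot change results.
#'
#' @param adolescent,adult \code{\link{group_spec}}s for the two groups
#'   (either may be \code{NULL} to generate a single-group cohort).
#' @param config a \code{\link{task_config}}.
#' @param model generating \code{\link{model_spec}} (default RSAV).
#' @param master_seed integer master seed.
#' @return an object of class \code{"cohort"}: list with \code{records}
#'   (named list of \code{"behavioral_record"}s), \code{truth} (data.frame of
#'   generating parameters with \code{subject_id} and \code{group}),
#'   \code{model}, \code{config} and \code{master_seed}.
#' @examples
#' co <- generate_cohort(adolescent_spec(2), adult_spec(2), master_seed = 11)
#' names(co$records)
#' @export
generate_cohort <- function(adolescent = adolescent_spec(),
                            adult = adult_spec(),
                            config = task_config(),
                            model = model_spec("rsav"),
                            master_seed = 1L) {
  specs <- Filter(Negate(is.null), list(adolescent, adult))
  stopifnot(length(specs) >= 1L)
  n_total <- sum(vapply(specs, function(s) s$n_subjects, integer(1)))
  subject_seeds <- withr::with_seed(master_seed,
                                    sample.int(.Machine$integer.max, n_total))
  records <- list()
  truth <- vector("list", n_total)
  i <- 0L
  for (spec in specs) {
    for (j in seq_len(spec$n_subjects)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", spec$label, j)
      rec_par <- withr::with_seed(subject_seeds[i], {
        pars <- sample_subject_parameters(spec)
        rec <- simulate_agent(model, pars, config,
                              subject_id = sid, group = spec$label)
        list(pars = pars, rec = rec)
      })
      records[[sid]] <- rec_par$rec
      truth[[i]] <- data.frame(subject_id = sid, group = spec$label,
                               as.data.frame(unclass(rec_par$pars)),
                               seed = subject_seeds[i],
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records, truth = do.call(rbind, truth),
                 model = model$name, config = config,
                 master_seed = as.integer(master_seed)),
            class = "cohort")
}

#' Write a cohort to disk
#'
#' Writes one TSV per subject plus a ground-truth JSON manifest
#' (\code{manifest.json}) holding the generating parameters, model, master
#' seed and task configuration.
#'
#' @param cohort a \code{"cohort"} from \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$records))
    write_behavioral_record(cohort$records[[sid]],
                            file.path(dir, paste0(sid, ".tsv")))
  manifest <- list(model = cohort$model,
                   master_seed = cohort$master_seed,
                   task = unclass(cohort$config),
                   truth = cohort$truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir cohort directory.
#' @return a \code{"cohort"} (task config restored from the manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  truth <- manifest$truth
  records <- lapply(truth$subject_id, function(sid)
    read_behavioral_record(file.path(dir, paste0(sid, ".tsv"))))
  names(records) <- truth$subject_id
  cfg <- manifest$task
  config <- task_config(cfg$n_runs, cfg$trials_per_run, cfg$p_reward_correct,
                        cfg$p_reward_incorrect, cfg$reversal_min_correct,
                        cfg$reversal_max_correct,
                        cfg$consecutive_correct_required,
                        cfg$reward_magnitude, cfg$punishment_magnitude,
                        cfg$miss_penalty, cfg$miss_probability)
  structure(list(records = records, truth = truth, model = manifest$model,
                 config = config, master_seed = manifest$master_seed),
            class = "cohort")
}

#' Parameter-recovery study for one group specification
#'
#' Repeatedly simulates a cohort from a group specification, fits the
#' generating model to every subject by maximum likelihood, and reports the
#' cohort-mean fitted parameters per replication, alongside the generating
#' group means. The headline recovery quantity is the cohort-mean fitted
#' \code{alpha_c_neg} (the learning rate for negative RPEs of chosen
#' options), averaged over replications.
#'
#' @param spec a \code{\link{group_spec}}.
#' @param n_replications number of independently seeded cohorts.
#' @param seed master seed; replication r uses \code{seed + r - 1}.
#' @param config a \code{\link{task_config}}.
#' @param model fitted and generating \code{\link{model_spec}}.
#' @param settings a \code{\link{fit_settings}} for the per-subject fits.
#' @return a list with \code{per_replication} (data.frame of cohort-mean
#'   fitted parameters), \code{recovered_mean} (named vector averaged over
#'   replications) and \code{generating_mean}.
#' @export
recover_parameters <- function(spec, n_replications = 10L, seed = 1L,
                               config = task_config(),
                               model = model_spec("rsav"),
                               settings = fit_settings()) {
  stopifnot(inherits(spec, "group_spec"), n_replications >= 1)
  per_rep <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    rep_seed <- (seed + r - 1L) %% .Machine$integer.max
    co <- if (spec$label == "adult")
      generate_cohort(adolescent = NULL, adult = spec, config = config,
                      model = model, master_seed = rep_seed)
    else
      generate_cohort(adolescent = spec, adult = NULL, config = config,
                      model = model, master_seed = rep_seed)
    fits <- lapply(co$records, function(rec)
      fit_subject(rec, model, fit_settings(settings$n_starts,
                                           seed = rep_seed, v0 = settings$v0)))
    est <- t(vapply(fits, function(f)
      unlist(unclass(f$params)), numeric(5L)))
    per_rep[[r]] <- data.frame(replication = r, t(colMeans(est)))
  }
  per_rep <- do.call(rbind, per_rep)
  recovered <- colMeans(per_rep[, -1, drop = FALSE])
  list(per_replication = per_rep,
       recovered_mean = recovered,
       generating_mean = spec$mean)
}
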