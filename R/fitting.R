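#' Switch/stay log-likelihood of a behavioral record under a model
#'
#' Replays the observed choices and outcomes through the model and scores,
#' for every trial with a defined predecessor, the probability the softmax
#' policy assigns to the observed action (repeating versus changing the
#' previous non-missed choice; with two stimuli this equals the probability
#' of the observed choice). The first non-missed trial of the session has no
#' predecessor and contributes no term; missed trials contribute neither a
#' term nor a value update. The returned value is the \emph{mean} log
#' probability per evaluated trial, matching the per-trial AIC convention of
#' \code{\link{compute_aic}}.
#'
#' @param record a \code{"behavioral_record"} for a single subject.
#' @param model a \code{\link{model_spec}}.
#' @param params a \code{\link{subject_parameters}}.
#' @param v0 initial stimulus values.
#' @return mean per-trial log-likelihood (<= 0).
#' @export
log_likelihood <- function(record, model, params, v0 = c(0, 0)) {
  if (nrow(record) == 0L) stop("empty behavioral record")
  rep_out <- replay_record(record, model, params, v0)
  if (rep_out$n_eval == 0L)
    stop("record has no trial with a defined predecessor")
  rep_out$loglik_sum / rep_out$n_eval
}

#' Per-trial Akaike information criterion
#'
#' \code{AIC = -2 logL + 2 M / N}, where \code{logL} is the mean per-trial
#' log-likelihood, \code{M} the number of free parameters and \code{N} the
#' number of evaluated trials. Everything is on the per-trial scale, so
#' values are comparable across subjects with different trial counts.
#'
#' @param logL mean per-trial log-likelihood.
#' @param M number of free parameters.
#' @param N number of trials.
#' @return the per-trial AIC.
#' @examples
#' compute_aic(log(0.5), 2, 120)
#' @export
compute_aic <- function(logL, M, N) {
  stopifnot(N > 0)
  -2 * logL + 2 * M / N
}

#' Optimizer settings for maximum-likelihood fitting
#'
#' Fitting uses a seeded global-then-local search: \code{n_starts} uniform
#' random starting points inside the box bounds (plus the box midpoint),
#' each refined with bounded quasi-Newton local optimization
#' (\code{\link[stats]{nlminb}}). Ties in likelihood are broken by the
#' smallest tau, then lexicographically over the learning rates, so fits are
#' deterministic given the seed.
#'
#' @param n_starts number of random restarts.
#' @param seed integer seed for the restart draws.
#' @param v0 initial stimulus values used during replay.
#' @return a list of class \code{"fit_settings"}.
#' @export
fit_settings <- function(n_starts = 16L, seed = 1L, v0 = c(0, 0)) {
  stopifnot(n_starts >= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 v0 = v0),
            class = "fit_settings")
}

# shared multi-start driver over an objective on the model's box bounds;
# objective = negative mean log-likelihood
multistart_minimize <- function(obj, model, settings) {
  k <- model$n_free
  lower <- model$lower
  upper <- model$upper
  starts <- withr::with_seed(settings$seed, {
    m <- matrix(runif(settings$n_starts * k), ncol = k)
    sweep(sweep(m, 2, upper - lower, "*"), 2, lower, "+")
  })
  starts <- rbind(starts, (lower + upper) / 2)
  best <- NULL
  n_conv <- 0L
  tau_i <- k  # tau is always the last free parameter
  for (s in seq_len(nrow(starts))) {
    f <- tryCatch(nlminb(starts[s, ], obj, lower = lower, upper = upper),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (f$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best)) { best <- f; next }
    d <- f$objective - best$objective
    if (d < -1e-9) {
      best <- f
    } else if (abs(d) <= 1e-9) {
      # tie-break: smallest tau, then lexicographic learning rates
      cand <- c(f$par[tau_i], f$par[-tau_i])
      inc <- c(best$par[tau_i], best$par[-tau_i])
      cmp <- cand - inc
      nz <- which(abs(cmp) > 0)
      if (length(nz) && cmp[nz[1]] < 0) best <- f
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(par = best$par, objective = best$objective,
       converged = n_conv > 0L, n_converged = n_conv)
}

#' Fit a model to one subject by maximum likelihood
#'
#' Maximizes the switch/stay log-likelihood (\code{\link{log_likelihood}})
#' over the model's free parameters, inside the box bounds (learning rates in
#' [0, 1], tau in [0.01, 10]), by seeded multi-start bounded optimization.
#'
#' @param record a \code{"behavioral_record"} for a single subject.
#' @param model a \code{\link{model_spec}}.
#' @param settings a \code{\link{fit_settings}}.
#' @return an object of class \code{"fit_result"}: list with \code{model}
#'   (name), \code{par} (named free-parameter vector), \code{params} (full
#'   \code{\link{subject_parameters}}), \code{logL} (mean per-trial),
#'   \code{AIC} (per-trial), \code{n_trials} (evaluated trials N),
#'   \code{M}, \code{converged}, \code{n_starts}, \code{seed} and
#'   \code{subject_id}.
#' @export
fit_subject <- function(record, model, settings = fit_settings()) {
  stopifnot(inherits(model, "model_spec"), inherits(settings, "fit_settings"))
  arrays <- record_arrays(record)
  obj <- function(p) -loglik_par(arrays, model, p, settings$v0)$mean
  opt <- multistart_minimize(obj, model, settings)
  par <- stats::setNames(opt$par, model$par_names)
  ll <- loglik_par(arrays, model, opt$par, settings$v0)
  structure(list(model = model$name,
                 par = par,
                 params = model$expand(opt$par),
                 logL = ll$mean,
                 AIC = compute_aic(ll$mean, model$n_free, ll$n_eval),
                 n_trials = ll$n_eval,
                 M = model$n_free,
                 converged = opt$converged,
                 n_starts = settings$n_starts,
                 seed = settings$seed,
                 subject_id = record$subject_id[1]),
            class = "fit_result")
}

#' Fit one canonical parameter set pooled over all subjects
#'
#' Maximizes the unweighted mean, over subjects, of each subject's mean
#' per-trial switch/stay log-likelihood, over a single shared parameter
#' vector. Used to derive common RPE regressors that do not build behavioral
#' differences into downstream analyses.
#'
#' @param records list of \code{"behavioral_record"}s (>= 2 subjects).
#' @param model a \code{\link{model_spec}}.
#' @param settings a \code{\link{fit_settings}}.
#' @return a \code{"fit_result"} whose \code{logL} is the pooled mean
#'   per-trial log-likelihood; \code{n_trials} is the total evaluated trials.
#' @export
fit_canonical <- function(records, model, settings = fit_settings()) {
  stopifnot(length(records) >= 2L)
  arrays_list <- lapply(records, record_arrays)
  obj <- function(p) {
    -mean(vapply(arrays_list,
                 function(a) loglik_par(a, model, p, settings$v0)$mean,
                 numeric(1)))
  }
  opt <- multistart_minimize(obj, model, settings)
  lls <- vapply(arrays_list,
                function(a) loglik_par(a, model, opt$par, settings$v0)$mean,
                numeric(1))
  n_eval <- sum(vapply(arrays_list,
                       function(a) loglik_par(a, model, opt$par, settings$v0)$n_eval,
                       numeric(1)))
  structure(list(model = model$name,
                 par = stats::setNames(opt$par, model$par_names),
                 params = model$expand(opt$par),
                 logL = mean(lls),
                 AIC = compute_aic(mean(lls), model$n_free,
                                   n_eval / length(records)),
                 n_trials = n_eval,
                 M = model$n_free,
                 converged = opt$converged,
                 n_starts = settings$n_starts,
                 seed = settings$seed,
                 subject_id = NA_character_),
            class = "fit_result")
}

# pre-extracted arrays for fast repeated likelihood evaluation
record_arrays <- function(record) {
  if (nrow(record) == 0L) stop("empty behavioral record")
  choice <- match(record$choice, c("A", "B"))
  missed <- record$missed == 1L | is.na(record$choice)
  choice[is.na(choice)] <- 1L
  outcome <- record$outcome
  outcome[missed] <- 0
  list(choice = as.integer(choice), outcome = as.numeric(outcome),
       missed = missed)
}

loglik_par <- function(arrays, model, p, v0 = c(0, 0)) {
  full <- model$expand(p)
  out <- replay_cpp(arrays$choice, arrays$outcome, arrays$missed,
                    full$alpha_c_pos, full$alpha_c_neg,
                    full$alpha_u_pos, full$alpha_u_neg,
                    full$tau, v0[1], v0[2],
                    if (identical(model$unchosen_rule, "fictive")) 1L else 0L)
  if (out$n_eval == 0L) stop("record has no trial with a defined predecessor")
  list(mean = out$loglik_sum / out$n_eval, n_eval = out$n_eval)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model ", x$model, " fit: logL = ", format(x$logL, digits = 4),
      ", AIC = ", format(x$AIC, digits = 4), " (per trial, N = ", x$n_trials,
      ")\n", sep = "")
  print(round(x$par, 4))
  invisible(x)
}
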