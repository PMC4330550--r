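#' Reinforcement-learning model specifications
#'
#' Three nested models of trial-and-error learning in the two-stimulus
#' reversal task:
#' \describe{
#'   \item{\code{"rw"}}{Rescorla-Wagner: a single learning rate; only the
#'     chosen stimulus value is updated. 2 free parameters (alpha, tau).}
#'   \item{\code{"rs"}}{risk-sensitive: separate learning rates for positive
#'     and negative reward prediction errors (RPEs) of the chosen stimulus.
#'     3 free parameters (alpha+, alpha-, tau).}
#'   \item{\code{"rsav"}}{risk-sensitive with anticorrelated valuation: in
#'     addition, the unchosen stimulus value is pushed in the opposite
#'     direction of the chosen-stimulus RPE, with its own positive/negative
#'     rates; the sign branch is taken on the chosen-stimulus RPE. 5 free
#'     parameters (alpha_c+, alpha_c-, alpha_u+, alpha_u-, tau).}
#' }
#' All models select actions through the same softmax policy with
#' temperature tau.
#'
#' For the RSAV model two readings of the anticorrelated update are
#' available. The default, \code{unchosen_rule = "prediction_error"}, is the
#' difference equation as printed: \code{V_u <- V_u - alpha_u * RPE}. With
#' separate chosen/unchosen rates this update does not preserve the
#' \code{[-1, 1]} value range and unchosen values can grow without bound,
#' which destabilizes behavior at high learning rates (see the package
#' vignette). The alternative, \code{unchosen_rule = "fictive"}, updates the
#' unchosen value toward the opposite outcome,
#' \code{V_u <- V_u + alpha_u * (-R - V_u)}; the two rules coincide exactly
#' whenever \code{V_u = -V_c} (perfect anticorrelation, e.g. under the
#' symmetric Rescorla-Wagner special case), and the fictive form keeps all
#' values bounded. In both rules the positive/negative learning-rate branch
#' is taken on the sign of the chosen-stimulus RPE.
#'
#' @param name one of \code{"rw"}, \code{"rs"}, \code{"rsav"}.
#' @param unchosen_rule RSAV only: \code{"prediction_error"} (default) or
#'   \code{"fictive"}; see Details.
#' @return an object of class \code{"model_spec"}: list with \code{name},
#'   \code{label}, \code{n_free} (M, the number of free parameters),
#'   \code{par_names}, box bounds \code{lower}/\code{upper} used in fitting,
#'   and \code{expand}, mapping a free-parameter vector to a full
#'   \code{\link{subject_parameters}} object.
#' @examples
#' model_spec("rsav")$n_free
#' @export
model_spec <- function(name = c("rw", "rs", "rsav"),
                       unchosen_rule = c("prediction_error", "fictive")) {
  name <- match.arg(name)
  unchosen_rule <- match.arg(unchosen_rule)
  out <- switch(name,
    rw = list(name = "rw", label = "Rescorla-Wagner", n_free = 2L,
              par_names = c("alpha", "tau"),
              lower = c(0, 0.01), upper = c(1, 10),
              expand = function(p) subject_parameters(p[1], p[1], 0, 0, p[2])),
    rs = list(name = "rs", label = "Risk-sensitive", n_free = 3L,
              par_names = c("alpha_pos", "alpha_neg", "tau"),
              lower = c(0, 0, 0.01), upper = c(1, 1, 10),
              expand = function(p) subject_parameters(p[1], p[2], 0, 0, p[3])),
    rsav = list(name = "rsav", label = "RSAV", n_free = 5L,
                par_names = c("alpha_c_pos", "alpha_c_neg",
                              "alpha_u_pos", "alpha_u_neg", "tau"),
                lower = c(0, 0, 0, 0, 0.01), upper = c(1, 1, 1, 1, 10),
                expand = function(p) subject_parameters(p[1], p[2], p[3], p[4], p[5])))
  out$unchosen_rule <- if (name == "rsav") unchosen_rule else "prediction_error"
  structure(out, class = "model_spec")
}

#' Subject-level model parameters
#'
#' The full parameter set of the RSAV model; the simpler models are the
#' special cases with tied chosen rates (Rescorla-Wagner) and/or zero
#' unchosen rates.
#'
#' @param alpha_c_pos,alpha_c_neg learning rates in [0, 1] for positive and
#'   negative RPEs of the chosen stimulus.
#' @param alpha_u_pos,alpha_u_neg learning rates in [0, 1] for the
#'   anticorrelated update of the unchosen stimulus.
#' @param tau softmax temperature, > 0.
#' @return an object of class \code{"subject_parameters"}.
#' @export
subject_parameters <- function(alpha_c_pos, alpha_c_neg,
                               alpha_u_pos = 0, alpha_u_neg = 0, tau = 1) {
  p <- list(alpha_c_pos = unname(alpha_c_pos), alpha_c_neg = unname(alpha_c_neg),
            alpha_u_pos = unname(alpha_u_pos), alpha_u_neg = unname(alpha_u_neg),
            tau = unname(tau))
  rates <- unlist(p[1:4])
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("learning rates must lie in [0, 1]")
  if (!is.finite(tau) || tau <= 0)
    stop("tau must be positive")
  structure(p, class = "subject_parameters")
}

#' Reward prediction error
#'
#' The difference between the received and the expected outcome on a trial:
#' positive when the outcome is better than expected.
#'
#' @param outcome the received reinforcement signal R (+1 reward, -1
#'   punishment).
#' @param chosen_value the current value of the chosen stimulus.
#' @return \code{outcome - chosen_value}.
#' @export
compute_rpe <- function(outcome, chosen_value) {
  stopifnot(is.finite(outcome), is.finite(chosen_value))
  outcome - chosen_value
}

#' Single-trial value update
#'
#' Applies one model-specific learning step to the stimulus values. For the
#' Rescorla-Wagner model only the chosen value moves, by alpha times the RPE.
#' The risk-sensitive model picks the positive- or negative-RPE learning rate
#' by the sign of the RPE (an RPE of exactly zero takes the positive branch).
#' The RSAV model additionally moves the unchosen value in the opposite
#' direction, with the sign branch taken on the same chosen-stimulus RPE.
#'
#' @param model a \code{\link{model_spec}}.
#' @param params a \code{\link{subject_parameters}}.
#' @param values named numeric vector \code{c(A = ..., B = ...)}.
#' @param choice \code{"A"} or \code{"B"}.
#' @param outcome the reinforcement signal (+1/-1).
#' @return the updated value vector.
#' @examples
#' update_values(model_spec("rw"), subject_parameters(0.5, 0.5),
#'               c(A = 0, B = 0), "A", 1)
#' @export
update_values <- function(model, params, values, choice, outcome) {
  stopifnot(inherits(model, "model_spec"), choice %in% c("A", "B"))
  other <- if (choice == "A") "B" else "A"
  rpe <- compute_rpe(outcome, values[[choice]])
  if (model$name == "rw") {
    values[[choice]] <- values[[choice]] + params$alpha_c_pos * rpe
  } else if (model$name == "rs") {
    a <- if (rpe >= 0) params$alpha_c_pos else params$alpha_c_neg
    values[[choice]] <- values[[choice]] + a * rpe
  } else {
    pos <- rpe >= 0
    a_c <- if (pos) params$alpha_c_pos else params$alpha_c_neg
    a_u <- if (pos) params$alpha_u_pos else params$alpha_u_neg
    values[[choice]] <- values[[choice]] + a_c * rpe
    if (identical(model$unchosen_rule, "fictive")) {
      values[[other]] <- values[[other]] + a_u * (-outcome - values[[other]])
    } else {
      values[[other]] <- values[[other]] - a_u * rpe
    }
  }
  values
}

#' Softmax action probabilities
#'
#' Logistic choice rule over the two stimulus values:
#' \code{p_A = 1 / (1 + exp(-(V_A - V_B) / tau))}, \code{p_B = 1 - p_A}.
#' Small temperatures make choice nearly deterministic toward the
#' higher-valued stimulus; large temperatures approach indifference.
#'
#' @param values named numeric vector \code{c(A = ..., B = ...)}.
#' @param tau softmax temperature, > 0.
#' @return numeric vector \code{c(A = p_A, B = p_B)}.
#' @export
softmax_choice_probabilities <- function(values, tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  p_a <- 1 / (1 + exp(-(values[["A"]] - values[["B"]]) / tau))
  c(A = p_a, B = 1 - p_a)
}

#' Simulate an artificial subject on the reversal-learning task
#'
#' Plays a full session of the task with choices sampled from the model's
#' softmax policy and values updated trial by trial from the sampled
#' outcomes. Uses the current RNG stream.
#'
#' @param model a \code{\link{model_spec}}.
#' @param params a \code{\link{subject_parameters}}.
#' @param config a \code{\link{task_config}}.
#' @param subject_id,group labels copied into the record.
#' @param v0 initial values, default \code{c(0, 0)} for both stimuli.
#' @return a \code{"behavioral_record"}, see \code{\link{run_session}}.
#' @examples
#' set.seed(7)
#' rec <- simulate_agent(model_spec("rw"), subject_parameters(0.4, 0.4, tau = 0.5),
#'                       task_config())
#' mean(rec$choice == rec$correct_stimulus)
#' @export
simulate_agent <- function(model, params, config, subject_id = "s1",
                           group = NA_character_, v0 = c(0, 0)) {
  stopifnot(inherits(params, "subject_parameters"))
  V <- c(A = v0[1], B = v0[2])
  prev_my_choice <- NA_character_
  agent <- function(info) {
    if (!is.na(prev_my_choice) && !is.na(info$prev_outcome)) {
      V <<- update_values(model, params, V, prev_my_choice, info$prev_outcome)
    }
    p <- softmax_choice_probabilities(V, params$tau)
    ch <- if (runif(1L) < p[["A"]]) "A" else "B"
    prev_my_choice <<- ch
    ch
  }
  run_session(config, agent, subject_id = subject_id, group = group)
}

replay_record <- function(record, model, params, v0 = c(0, 0)) {
  stopifnot(inherits(params, "subject_parameters"))
  choice <- match(record$choice, c("A", "B"))
  missed <- record$missed == 1L | is.na(record$choice)
  if (any(is.na(choice) & !missed))
    stop("record contains choices other than A/B on non-missed trials")
  choice[is.na(choice)] <- 1L  # placeholder, skipped via the miss flag
  outcome <- record$outcome
  outcome[missed] <- 0
  replay_cpp(choice, outcome, missed,
             params$alpha_c_pos, params$alpha_c_neg,
             params$alpha_u_pos, params$alpha_u_neg,
             params$tau, v0[1], v0[2],
             if (identical(model$unchosen_rule, "fictive")) 1L else 0L)
}

#' Replay observed behavior through a model to extract RPE and value traces
#'
#' Deterministically replays a subject's observed choices and outcomes
#' through a model with fixed parameters, emitting the trial-wise reward
#' prediction error, the chosen-stimulus value at choice time, and the
#' softmax probability of the observed choice. Missed trials are skipped
#' without a value update and excluded from the trace.
#'
#' @inheritParams simulate_agent
#' @param record a \code{"behavioral_record"} for a single subject.
#' @return a \code{data.frame} of class \code{"rpe_trace"} with one row per
#'   non-missed trial: \code{trial} (global index), \code{run},
#'   \code{choice}, \code{outcome}, \code{rpe}, \code{chosen_value},
#'   \code{choice_prob} and \code{p_stay} (probability of repeating the
#'   previous choice; \code{NA} on the first trial of the session).
#' @export
compute_rpe_trace <- function(record, model, params, v0 = c(0, 0)) {
  rep_out <- replay_record(record, model, params, v0)
  keep <- !(record$missed == 1L | is.na(record$choice))
  trace <- data.frame(trial = seq_len(nrow(record))[keep],
                      run = record$run[keep],
                      choice = record$choice[keep],
                      outcome = record$outcome[keep],
                      rpe = rep_out$rpe[keep],
                      chosen_value = rep_out$chosen_value[keep],
                      choice_prob = rep_out$choice_prob[keep],
                      p_stay = rep_out$p_stay[keep],
                      stringsAsFactors = FALSE)
  class(trace) <- c("rpe_trace", "data.frame")
  trace
}

#' Write an RPE trace as a TSV regressor-building table
#'
#' @param trace an \code{"rpe_trace"} from \code{\link{compute_rpe_trace}}.
#' @param file path to a TSV file.
#' @param onsets optional onset times (seconds) per trace row; a zero-based
#'   placeholder sequence is written when omitted.
#' @return \code{file}, invisibly.
#' @export
write_rpe_trace <- function(trace, file, onsets = NULL) {
  if (is.null(onsets)) onsets <- seq_len(nrow(trace)) - 1
  stopifnot(length(onsets) == nrow(trace))
  out <- data.frame(trial = trace$trial, onset = onsets, rpe = trace$rpe,
                    chosen_value = trace$chosen_value,
                    choice_prob = trace$choice_prob)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
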