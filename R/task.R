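#' Task configuration for the probabilistic reversal-learning task
#'
#' Defines the generative environment: two stimuli, one of which is currently
#' "correct" and rewarded with probability \code{p_reward_correct} while the
#' other is rewarded with probability \code{p_reward_incorrect} (and punished
#' otherwise). After the subject has made at least
#' \code{reversal_min_correct} correct choices since the last reversal (the
#' exact criterion is drawn uniformly between \code{reversal_min_correct} and
#' \code{reversal_max_correct} per block), of which at least
#' \code{consecutive_correct_required} were consecutive, the contingencies
#' reverse covertly.
#'
#' Outcomes used for learning are coded on the unit scale (+1 reward,
#' -1 punishment); the monetary magnitudes are carried along as labels only.
#'
#' @param n_runs number of runs per session.
#' @param trials_per_run decision trials per run.
#' @param p_reward_correct reward probability of the currently correct stimulus.
#' @param p_reward_incorrect reward probability of the incorrect stimulus.
#' @param reversal_min_correct minimum correct choices before a reversal.
#' @param reversal_max_correct maximum correct choices before a reversal.
#' @param consecutive_correct_required consecutive correct choices required
#'   before a reversal can fire.
#' @param reward_magnitude,punishment_magnitude,miss_penalty payoff labels in
#'   monetary units (centimes); not used for learning.
#' @param miss_probability probability that a trial is missed (no response);
#'   missed trials carry no outcome and do not advance the reversal counters.
#' @return an object of class \code{"task_config"}.
#' @examples
#' cfg <- task_config()
#' cfg$trials_per_run
#' @export
task_config <- function(n_runs = 2L, trials_per_run = 60L,
                        p_reward_correct = 0.8, p_reward_incorrect = 0.2,
                        reversal_min_correct = 6L, reversal_max_correct = 10L,
                        consecutive_correct_required = 3L,
                        reward_magnitude = 50, punishment_magnitude = -50,
                        miss_penalty = -100, miss_probability = 0) {
  stopifnot(n_runs >= 1, trials_per_run >= 1,
            p_reward_incorrect >= 0, p_reward_correct <= 1,
            p_reward_incorrect < p_reward_correct,
            reversal_min_correct <= reversal_max_correct,
            consecutive_correct_required <= reversal_min_correct,
            miss_probability >= 0, miss_probability < 1)
  structure(list(n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 p_reward_correct = p_reward_correct,
                 p_reward_incorrect = p_reward_incorrect,
                 reversal_min_correct = as.integer(reversal_min_correct),
                 reversal_max_correct = as.integer(reversal_max_correct),
                 consecutive_correct_required = as.integer(consecutive_correct_required),
                 reward_magnitude = reward_magnitude,
                 punishment_magnitude = punishment_magnitude,
                 miss_penalty = miss_penalty,
                 miss_probability = miss_probability),
            class = "task_config")
}

#' Draw the reversal criterion for a new block
#'
#' The number of correct choices after which the contingencies reverse is
#' drawn uniformly on \code{[reversal_min_correct, reversal_max_correct]}
#' (inclusive) at the start of each block, using the current RNG stream.
#'
#' @param config a \code{\link{task_config}}.
#' @return an integer criterion.
#' @export
draw_reversal_criterion <- function(config) {
  stopifnot(inherits(config, "task_config"))
  lo <- config$reversal_min_correct
  hi <- config$reversal_max_correct
  if (lo == hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Initialise the task state
#'
#' @param config a \code{\link{task_config}}.
#' @param correct_stimulus starting correct stimulus, \code{"A"} or \code{"B"};
#'   drawn at random when \code{NULL}.
#' @return an object of class \code{"task_state"}.
#' @export
init_task_state <- function(config, correct_stimulus = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(correct_stimulus))
    correct_stimulus <- sample(c("A", "B"), 1L)
  stopifnot(correct_stimulus %in% c("A", "B"))
  structure(list(correct_stimulus = correct_stimulus,
                 correct_count = 0L,
                 consecutive_correct = 0L,
                 reversal_criterion = draw_reversal_criterion(config),
                 trial_index = 0L),
            class = "task_state")
}

#' Play one trial of the reversal-learning task
#'
#' Samples the outcome of a single choice under the current contingencies,
#' updates the reversal counters, and triggers a covert reversal (correct
#' stimulus flips, counters reset, new criterion drawn) when both the
#' per-block criterion and the consecutive-correct condition are met. A
#' reversal takes effect from the next trial; the trial that completed the
#' criterion is flagged with \code{reversal_after}.
#'
#' @param state a \code{"task_state"} from \code{\link{init_task_state}}.
#' @param config a \code{\link{task_config}}.
#' @param choice \code{"A"} or \code{"B"}.
#' @return a list with elements \code{outcome} (a list: \code{choice},
#'   \code{correct}, \code{rewarded}, \code{value} in {+1, -1},
#'   \code{reversal_after}) and \code{state} (the updated task state).
#' @export
step_trial <- function(state, config, choice) {
  stopifnot(inherits(state, "task_state"), inherits(config, "task_config"))
  if (length(choice) != 1L || !choice %in% c("A", "B"))
    stop("invalid stimulus id: ", deparse(choice), " (must be \"A\" or \"B\")")
  correct <- choice == state$correct_stimulus
  p_rew <- if (correct) config$p_reward_correct else config$p_reward_incorrect
  rewarded <- runif(1L) < p_rew
  if (correct) {
    state$correct_count <- state$correct_count + 1L
    state$consecutive_correct <- state$consecutive_correct + 1L
  } else {
    state$consecutive_correct <- 0L
  }
  reversal <- state$correct_count >= state$reversal_criterion &&
    state$consecutive_correct >= config$consecutive_correct_required
  if (reversal) {
    state$correct_stimulus <- if (state$correct_stimulus == "A") "B" else "A"
    state$correct_count <- 0L
    state$consecutive_correct <- 0L
    state$reversal_criterion <- draw_reversal_criterion(config)
  }
  state$trial_index <- state$trial_index + 1L
  list(outcome = list(choice = choice, correct = correct, rewarded = rewarded,
                      value = if (rewarded) 1 else -1,
                      reversal_after = reversal),
       state = state)
}

#' Run a full task session for one agent
#'
#' Plays \code{n_runs * trials_per_run} trials. Task state (including the
#' identity of the correct stimulus and the reversal counters) persists
#' across runs. The agent is a callback \code{function(info)} returning
#' \code{"A"} or \code{"B"}; \code{info} is a list with fields \code{trial}
#' (global 1-based index), \code{run}, \code{prev_choice} and
#' \code{prev_outcome} (the agent's previous non-missed choice and its coded
#' outcome, \code{NA} on the first trial), and \code{correct_stimulus} (the
#' currently correct stimulus — intended for oracle/probe agents only; a
#' model of subject behavior must not read it).
#'
#' Missed trials are injected with probability \code{miss_probability}; the
#' agent is not consulted, no outcome is delivered, and the reversal counters
#' do not advance.
#'
#' @param config a \code{\link{task_config}}.
#' @param agent choice-policy callback, see Details.
#' @param subject_id,group labels copied into the record.
#' @param correct_stimulus optional starting correct stimulus.
#' @return a \code{data.frame} of class \code{"behavioral_record"} with
#'   columns \code{subject_id}, \code{group}, \code{run}, \code{trial}
#'   (within-run index), \code{choice}, \code{correct_stimulus},
#'   \code{outcome} (+1/-1, \code{NA} when missed), \code{missed} (0/1) and
#'   \code{reversal_after} (0/1).
#' @examples
#' set.seed(1)
#' rec <- run_session(task_config(), agent_random())
#' nrow(rec)
#' @export
run_session <- function(config, agent, subject_id = "s1", group = NA_character_,
                        correct_stimulus = NULL) {
  stopifnot(inherits(config, "task_config"), is.function(agent))
  state <- init_task_state(config, correct_stimulus)
  n_total <- config$n_runs * config$trials_per_run
  run <- integer(n_total); trial <- integer(n_total)
  choice <- character(n_total); corr <- character(n_total)
  outcome <- rep(NA_real_, n_total); missed <- integer(n_total)
  rev_after <- integer(n_total)
  prev_choice <- NA_character_; prev_outcome <- NA_real_
  i <- 0L
  for (r in seq_len(config$n_runs)) {
    for (t in seq_len(config$trials_per_run)) {
      i <- i + 1L
      run[i] <- r; trial[i] <- t
      corr[i] <- state$correct_stimulus
      if (config$miss_probability > 0 && runif(1L) < config$miss_probability) {
        choice[i] <- NA_character_; missed[i] <- 1L
        next
      }
      ch <- agent(list(trial = i, run = r,
                       prev_choice = prev_choice, prev_outcome = prev_outcome,
                       correct_stimulus = state$correct_stimulus))
      if (length(ch) != 1L || is.na(ch) || !ch %in% c("A", "B"))
        stop("agent returned invalid stimulus id at trial ", i, ": ",
             deparse(ch))
      res <- step_trial(state, config, ch)
      state <- res$state
      choice[i] <- ch
      outcome[i] <- res$outcome$value
      rev_after[i] <- as.integer(res$outcome$reversal_after)
      prev_choice <- ch; prev_outcome <- res$outcome$value
    }
  }
  rec <- data.frame(subject_id = subject_id, group = group, run = run,
                    trial = trial, choice = choice, correct_stimulus = corr,
                    outcome = outcome, missed = missed,
                    reversal_after = rev_after, stringsAsFactors = FALSE)
  class(rec) <- c("behavioral_record", "data.frame")
  rec
}

#' Built-in probe agents
#'
#' \code{agent_random} chooses uniformly at random; \code{agent_perfect}
#' always chooses the currently correct stimulus (an oracle, used to probe
#' the task contingencies); \code{agent_perverse} always chooses the
#' currently incorrect stimulus.
#'
#' @return a choice-policy callback suitable for \code{\link{run_session}}.
#' @export
agent_random <- function() function(info) if (runif(1L) < 0.5) "A" else "B"

#' @rdname agent_random
#' @export
agent_perfect <- function() function(info) info$correct_stimulus

#' @rdname agent_random
#' @export
agent_perverse <- function() {
  function(info) if (info$correct_stimulus == "A") "B" else "A"
}

#' Read and write behavioral records as TSV
#'
#' The on-disk format is a tab-separated table with the columns documented in
#' \code{\link{run_session}}.
#'
#' @param record a \code{"behavioral_record"} (or a data.frame with the same
#'   columns; multiple subjects may be row-bound).
#' @param file path to a TSV file.
#' @return \code{read_behavioral_record} returns a \code{"behavioral_record"};
#'   \code{write_behavioral_record} returns \code{file} invisibly.
#' @export
write_behavioral_record <- function(record, file) {
  write.table(record, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_behavioral_record
#' @export
read_behavioral_record <- function(file) {
  rec <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "run", "trial", "choice",
              "correct_stimulus", "outcome", "missed", "reversal_after")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols))
    stop("missing columns in behavioral record: ",
         paste(missing_cols, collapse = ", "))
  rec$choice <- as.character(rec$choice)
  class(rec) <- c("behavioral_record", "data.frame")
  rec
}
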