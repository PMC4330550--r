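# build a minimal behavioral record from explicit choice/outcome sequences
make_record <- function(choices, outcomes, missed = NULL, run = NULL,
                        subject_id = "toy", group = NA_character_,
                        correct_stimulus = "A") {
  n <- length(choices)
  if (is.null(missed)) missed <- rep(0L, n)
  if (is.null(run)) run <- rep(1L, n)
  rec <- data.frame(subject_id = subject_id, group = group, run = run,
                    trial = stats::ave(seq_len(n), run, FUN = seq_along),
                    choice = choices,
                    correct_stimulus = rep_len(correct_stimulus, n),
                    outcome = outcomes, missed = missed,
                    reversal_after = 0L, stringsAsFactors = FALSE)
  class(rec) <- c("behavioral_record", "data.frame")
  rec
}

# independent hand-unrolled oracle for the switch/stay likelihood and value
# recursion, written directly from the model equations with no calls into the
# package: values start at v0, the chosen value moves by the signed learning
# rate times RPE, the unchosen by the anticorrelated term, and each trial
# after the first non-missed one contributes log P(observed choice) under the
# logistic policy evaluated at the pre-update values.
oracle_loglik <- function(choices, outcomes, acp, acn, aup, aun, tau,
                          missed = rep(FALSE, length(choices)),
                          v0 = c(0, 0), fictive = FALSE) {
  V <- v0
  ll <- c()
  prev <- NA_integer_
  for (t in seq_along(choices)) {
    if (missed[t]) next
    ci <- if (choices[t] == "A") 1L else 2L
    p_a <- 1 / (1 + exp(-(V[1] - V[2]) / tau))
    p_obs <- if (ci == 1L) p_a else 1 - p_a
    if (!is.na(prev)) ll <- c(ll, log(p_obs))
    rpe <- outcomes[t] - V[ci]
    a_c <- if (rpe >= 0) acp else acn
    a_u <- if (rpe >= 0) aup else aun
    V[ci] <- V[ci] + a_c * rpe
    if (fictive) {
      V[3 - ci] <- V[3 - ci] + a_u * (-outcomes[t] - V[3 - ci])
    } else {
      V[3 - ci] <- V[3 - ci] - a_u * rpe
    }
    prev <- ci
  }
  mean(ll)
}

# deterministic pseudo-random choice/outcome sequences for property tests
random_sequences <- function(n_seq, len, seed) {
  withr::with_seed(seed, lapply(seq_len(n_seq), function(i) {
    list(choices = sample(c("A", "B"), len, replace = TRUE),
         outcomes = sample(c(1, -1), len, replace = TRUE))
  }))
}
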