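test_that("the reward prediction error is received minus expected outcome", {
  expect_identical(compute_rpe(1, 0), 1)
  expect_identical(compute_rpe(-1, -1), 0)
  expect_equal(compute_rpe(1, 0.6), 0.4)
})

test_that("single-trial value updates match hand-computed examples", {
  rw <- update_values(model_spec("rw"), subject_parameters(0.5, 0.5),
                      c(A = 0, B = 0), "A", 1)
  expect_equal(rw, c(A = 0.5, B = 0))
  # RSAV with the adolescent group means, punished A-choice from V = (0.5, -0.2):
  # RPE = -1 - 0.5 = -1.5; V_A = 0.5 + 0.69 * (-1.5); V_B = -0.2 - 0.63 * (-1.5)
  rsav <- update_values(model_spec("rsav"),
                        subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9),
                        c(A = 0.5, B = -0.2), "A", -1)
  expect_equal(rsav, c(A = -0.535, B = 0.745))
  # zero learning rates leave the state unchanged
  for (m in list(model_spec("rw"), model_spec("rs"), model_spec("rsav"))) {
    expect_equal(update_values(m, subject_parameters(0, 0, 0, 0, 1),
                               c(A = 0.3, B = -0.4), "B", 1),
                 c(A = 0.3, B = -0.4))
  }
})

test_that("softmax probabilities are a proper logistic policy", {
  expect_equal(softmax_choice_probabilities(c(A = 0.4, B = 0.4), 1)[["A"]], 0.5)
  # inverting the logistic: a value lead of tau * ln 3 gives p = 0.75
  tau <- 0.7
  p <- softmax_choice_probabilities(c(A = tau * log(3), B = 0), tau)
  expect_equal(p[["A"]], 0.75)
  expect_equal(sum(p), 1)
  # strictly increasing in the value difference; indifferent at large tau
  deltas <- seq(-2, 2, by = 0.25)
  pa <- vapply(deltas, function(d)
    softmax_choice_probabilities(c(A = d, B = 0), 0.5)[["A"]], numeric(1))
  expect_true(all(diff(pa) > 0))
  expect_equal(softmax_choice_probabilities(c(A = 1, B = -1), 1e6)[["A"]], 0.5,
               tolerance = 1e-5)
  expect_error(softmax_choice_probabilities(c(A = 0, B = 0), 0), "tau")
})

test_that("the models nest: tied rates reproduce the simpler model bit-identically", {
  seqs <- random_sequences(100, 100, seed = 71)
  rw <- model_spec("rw"); rs <- model_spec("rs"); rsav <- model_spec("rsav")
  alphas <- withr::with_seed(72, runif(length(seqs)))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    a <- alphas[i]
    p_rw <- subject_parameters(a, a)
    p_rs <- subject_parameters(a, a)
    v1 <- c(A = 0, B = 0); v2 <- c(A = 0, B = 0); v3 <- c(A = 0, B = 0)
    for (t in seq_along(s$choices)) {
      v1 <- update_values(rw, p_rw, v1, s$choices[t], s$outcomes[t])
      v2 <- update_values(rs, p_rs, v2, s$choices[t], s$outcomes[t])
      v3 <- update_values(rsav, p_rs, v3, s$choices[t], s$outcomes[t])
      expect_identical(v1, v2)
      expect_identical(v2, v3)  # alpha_u = 0 collapses RSAV to risk-sensitive
    }
  }
})

test_that("values stay bounded for chosen-only updates and finite for RSAV", {
  seqs <- random_sequences(50, 200, seed = 81)
  pars <- withr::with_seed(82, matrix(runif(50 * 5), ncol = 5))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    p_rs <- subject_parameters(pars[i, 1], pars[i, 2])
    p_av <- subject_parameters(pars[i, 1], pars[i, 2], pars[i, 3], pars[i, 4])
    v <- c(A = 0, B = 0); w <- c(A = 0, B = 0)
    for (t in seq_along(s$choices)) {
      v <- update_values(model_spec("rs"), p_rs, v, s$choices[t], s$outcomes[t])
      w <- update_values(model_spec("rsav"), p_av, w, s$choices[t], s$outcomes[t])
    }
    expect_true(all(abs(v) <= 1))    # convex combination for chosen-only models
    expect_true(all(is.finite(w)))   # anticorrelated values are unbounded but finite
  }
  # the fictive anticorrelated rule preserves the unit range
  for (i in 1:10) {
    s <- seqs[[i]]
    p_av <- subject_parameters(pars[i, 1], pars[i, 2], pars[i, 3], pars[i, 4])
    u <- c(A = 0, B = 0)
    for (t in seq_along(s$choices))
      u <- update_values(model_spec("rsav", unchosen_rule = "fictive"),
                         p_av, u, s$choices[t], s$outcomes[t])
    expect_true(all(abs(u) <= 1))
  }
})

test_that("replaying observed behavior reproduces the trial-wise recursion", {
  # independent R-level recursion vs the packaged replay, both RSAV rules
  for (rule in c("prediction_error", "fictive")) {
    m <- model_spec("rsav", unchosen_rule = rule)
    p <- subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9)
    rec <- withr::with_seed(91, simulate_agent(m, p, task_config()))
    trace <- compute_rpe_trace(rec, m, p)
    V <- c(A = 0, B = 0)
    for (t in seq_len(nrow(trace))) {
      ch <- trace$choice[t]
      expect_equal(trace$chosen_value[t], V[[ch]], tolerance = 1e-12)
      expect_equal(trace$rpe[t], trace$outcome[t] - V[[ch]], tolerance = 1e-12)
      expect_equal(trace$choice_prob[t],
                   softmax_choice_probabilities(V, p$tau)[[ch]],
                   tolerance = 1e-12)
      V <- update_values(m, p, V, ch, trace$outcome[t])
    }
  }
})

test_that("a three-trial toy trace matches the hand-unrolled recursion", {
  rec <- make_record(c("A", "A", "B"), c(1, -1, 1))
  trace <- compute_rpe_trace(rec, model_spec("rsav"),
                             subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9))
  # hand-unrolled: V = (0,0); RPE1 = 1; V = (.62, -.78);
  # RPE2 = -1 - .62 = -1.62; V_A = .62 + .69*(-1.62); V_B = -.78 - .63*(-1.62)
  # RPE3 = 1 - (-.78 + 1.0206) = 1 - 0.2406
  expect_equal(trace$rpe, c(1, -1.62, 0.7594), tolerance = 1e-12)
  expect_equal(trace$chosen_value, c(0, 0.62, 0.2406), tolerance = 1e-12)
  # one-step convergence of Rescorla-Wagner at alpha = 1 under constant reward
  rec2 <- make_record(rep("A", 5), rep(1, 5))
  tr2 <- compute_rpe_trace(rec2, model_spec("rw"), subject_parameters(1, 1))
  expect_equal(tr2$rpe, c(1, 0, 0, 0, 0))
})

test_that("misses are skipped in the trace without a value update", {
  rec <- make_record(c("A", NA, "A", "B"), c(1, NA, -1, 1),
                     missed = c(0L, 1L, 0L, 0L))
  full <- make_record(c("A", "A", "B"), c(1, -1, 1))
  m <- model_spec("rsav")
  p <- subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9)
  tr_miss <- compute_rpe_trace(rec, m, p)
  tr_full <- compute_rpe_trace(full, m, p)
  expect_equal(nrow(tr_miss), 3)
  expect_equal(tr_miss$rpe, tr_full$rpe)
  expect_equal(tr_miss$trial, c(1L, 3L, 4L))
})

test_that("agents without learning choose at chance; simulation is seed-reproducible", {
  cfg <- task_config(n_runs = 2, trials_per_run = 2500)
  rec <- withr::with_seed(101, simulate_agent(model_spec("rw"),
                                              subject_parameters(0, 0, tau = 1),
                                              cfg))
  expect_equal(mean(rec$choice == "A"), 0.5,
               tolerance = 3 * sqrt(0.25 / nrow(rec)))
  expect_equal(mean(rec$choice == rec$correct_stimulus), 0.5,
               tolerance = 3 * sqrt(0.25 / nrow(rec)))
  r1 <- withr::with_seed(102, simulate_agent(model_spec("rsav"),
                                             subject_parameters(.6, .7, .7, .6, 2),
                                             task_config()))
  r2 <- withr::with_seed(102, simulate_agent(model_spec("rsav"),
                                             subject_parameters(.6, .7, .7, .6, 2),
                                             task_config()))
  expect_identical(r1, r2)
})
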