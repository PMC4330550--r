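test_that("an uninformative policy scores at chance and a certain one at zero", {
  rec <- make_record(rep(c("A", "B"), 5), rep(1, 10))
  # zero learning rates keep both values at 0, so every term is log(1/2)
  expect_equal(log_likelihood(rec, model_spec("rw"), subject_parameters(0, 0, tau = 1)),
               log(0.5))
  # one-step learning at alpha = 1 with a tiny temperature predicts the
  # repeated choice with certainty
  rec2 <- make_record(c("A", "A"), c(1, 1))
  expect_equal(log_likelihood(rec2, model_spec("rw"),
                              subject_parameters(1, 1, tau = 0.01)),
               0, tolerance = 1e-12)
  expect_error(log_likelihood(make_record("A", 1), model_spec("rw"),
                              subject_parameters(.5, .5)),
               "no trial with a defined predecessor")
})

test_that("the likelihood matches a hand-unrolled oracle to 1e-12 on toy records", {
  toy <- withr::with_seed(111, list(
    choices = sample(c("A", "B"), 10, replace = TRUE),
    outcomes = sample(c(1, -1), 10, replace = TRUE)))
  rec <- make_record(toy$choices, toy$outcomes)
  expect_equal(log_likelihood(rec, model_spec("rw"),
                              subject_parameters(0.5, 0.5, tau = 1)),
               oracle_loglik(toy$choices, toy$outcomes, .5, .5, 0, 0, 1),
               tolerance = 1e-12)
  expect_equal(log_likelihood(rec, model_spec("rsav"),
                              subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9)),
               oracle_loglik(toy$choices, toy$outcomes, .62, .69, .78, .63, 1.9),
               tolerance = 1e-12)
  expect_equal(log_likelihood(rec, model_spec("rsav", unchosen_rule = "fictive"),
                              subject_parameters(0.62, 0.69, 0.78, 0.63, 1.9)),
               oracle_loglik(toy$choices, toy$outcomes, .62, .69, .78, .63, 1.9,
                             fictive = TRUE),
               tolerance = 1e-12)
  # misses contribute neither a term nor an update
  rec_miss <- make_record(c(toy$choices[1:4], NA, toy$choices[5:10]),
                          c(toy$outcomes[1:4], NA, toy$outcomes[5:10]),
                          missed = c(rep(0L, 4), 1L, rep(0L, 6)))
  expect_identical(log_likelihood(rec_miss, model_spec("rw"),
                                  subject_parameters(.5, .5, tau = 1)),
                   log_likelihood(rec, model_spec("rw"),
                                  subject_parameters(.5, .5, tau = 1)))
})

test_that("per-trial AIC follows its definition", {
  expect_equal(compute_aic(log(0.5), 2, 120), -2 * log(0.5) + 4 / 120)
  expect_equal(compute_aic(-0.6931, 2, 120), 1.4196, tolerance = 5e-4)
  expect_equal(compute_aic(-1.2, 0, 50), 2.4)
  expect_error(compute_aic(-1, 2, 0))
})

test_that("the optimizer is at least as good as exhaustive grid search", {
  rec <- withr::with_seed(121, simulate_agent(model_spec("rw"),
                                              subject_parameters(0.5, 0.5, tau = 2),
                                              task_config()))
  m <- model_spec("rw")
  fit <- fit_subject(rec, m, fit_settings(n_starts = 12, seed = 5))
  grid <- expand.grid(alpha = seq(0, 1, by = 0.01),
                      tau = seq(0.01, 10, by = 0.01))
  arrays <- flexrl:::record_arrays(rec)
  grid_ll <- vapply(seq_len(nrow(grid)), function(i)
    flexrl:::loglik_par(arrays, m, c(grid$alpha[i], grid$tau[i]))$mean,
    numeric(1))
  expect_gte(fit$logL, max(grid_ll) - 1e-3)
  # and no worse than the generating parameters
  expect_gte(fit$logL, log_likelihood(rec, m, subject_parameters(0.5, 0.5, tau = 2)))
  expect_true(fit$converged)
})

test_that("fits are deterministic given a seed and AIC is consistent with logL", {
  rec <- withr::with_seed(131, simulate_agent(model_spec("rs"),
                                              subject_parameters(0.7, 0.3, tau = 1),
                                              task_config()))
  f1 <- fit_subject(rec, model_spec("rs"), fit_settings(8, seed = 3))
  f2 <- fit_subject(rec, model_spec("rs"), fit_settings(8, seed = 3))
  expect_identical(f1$par, f2$par)
  expect_equal(f1$AIC, -2 * f1$logL + 2 * f1$M / f1$n_trials)
  expect_equal(f1$n_trials, 119)
})

test_that("a non-learner's record drives the fit toward an uninformative policy", {
  rec <- withr::with_seed(141, run_session(task_config(), agent_random()))
  f <- fit_subject(rec, model_spec("rw"), fit_settings(8, seed = 7))
  expect_gte(f$logL, log(0.5) - 0.05)
  expect_lte(f$logL, 0)
})

test_that("canonical fitting pools subjects sensibly", {
  rec <- withr::with_seed(151, simulate_agent(model_spec("rw"),
                                              subject_parameters(0.4, 0.4, tau = 0.8),
                                              task_config()))
  # identical records: the canonical optimum coincides with the individual one
  solo <- fit_subject(rec, model_spec("rw"), fit_settings(8, seed = 9))
  pooled <- fit_canonical(list(rec, rec), model_spec("rw"), fit_settings(8, seed = 9))
  expect_equal(pooled$logL, solo$logL, tolerance = 1e-6)
  expect_equal(unname(pooled$par), unname(solo$par), tolerance = 1e-3)
  # two subjects at opposite learning-rate extremes: the shared estimate lies
  # strictly between the individual fits
  recs <- withr::with_seed(152, list(
    simulate_agent(model_spec("rw"), subject_parameters(0.1, 0.1, tau = 0.5),
                   task_config()),
    simulate_agent(model_spec("rw"), subject_parameters(0.9, 0.9, tau = 0.5),
                   task_config())))
  fits <- lapply(recs, fit_subject, model = model_spec("rw"),
                 settings = fit_settings(8, seed = 10))
  both <- fit_canonical(recs, model_spec("rw"), fit_settings(8, seed = 10))
  a <- sort(c(fits[[1]]$par[["alpha"]], fits[[2]]$par[["alpha"]]))
  expect_gt(both$par[["alpha"]], a[1])
  expect_lt(both$par[["alpha"]], a[2])
  expect_error(fit_canonical(list(rec), model_spec("rw")), "2")
})
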