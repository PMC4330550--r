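#' Random-effects Bayesian model selection for groups
#'
#' Treats the model identity as a random effect across subjects: subjects are
#' assumed to be drawn from a population in which each model has an unknown
#' frequency r_k with a Dirichlet prior. The variational scheme iterates
#' between (a) the posterior model assignment of each subject, proportional
#' to \code{exp(log evidence + digamma(alpha_k) - digamma(sum alpha))}, and
#' (b) the Dirichlet counts \code{alpha = prior + column sums of the
#' assignments}, until the counts change by less than \code{tol}. Exceedance
#' probabilities (the posterior probability that model k is the most frequent
#' in the population) are then estimated by Monte-Carlo sampling from the
#' Dirichlet posterior.
#'
#' Model evidence here is the AIC-based approximation: for each subject and
#' model, \code{log evidence = -0.5 * N * AIC_per_trial = N * logL - M}
#' (see \code{\link{aic_evidence}}).
#'
#' @param evidence numeric matrix of approximate log model evidence, one row
#'   per subject, one column per model (column names become model labels).
#' @param prior_alpha Dirichlet prior count per model (uniform default 1).
#' @param tol convergence tolerance on the maximal change in alpha.
#' @param max_iter iteration cap; non-convergence is an error.
#' @param n_samples Monte-Carlo samples for the exceedance probabilities.
#' @param seed seed for the Monte-Carlo draw.
#' @return an object of class \code{"bms_result"}: list with
#'   \code{dirichlet_alpha}, \code{expected_frequencies},
#'   \code{exceedance_prob}, \code{assignments} (subject x model posterior),
#'   \code{n_iter}, \code{mc_samples} and \code{seed}.
#' @examples
#' ev <- rbind(c(-80, -70), c(-75, -72))  # two subjects, two models
#' bms_group(ev, n_samples = 1e4)$exceedance_prob
#' @export
bms_group <- function(evidence, prior_alpha = 1, tol = 1e-6, max_iter = 10000L,
                      n_samples = 1e6, seed = 1L) {
  evidence <- as.matrix(evidence)
  if (nrow(evidence) < 1L || ncol(evidence) < 2L)
    stop("need at least 1 subject and 2 models")
  if (any(!is.finite(evidence))) stop("non-finite model evidence")
  K <- ncol(evidence)
  stopifnot(all(prior_alpha > 0))
  alpha0 <- rep_len(prior_alpha, K)
  alpha <- alpha0
  g <- NULL
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)          # log-sum-exp stabilization
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("group BMS did not converge after ", max_iter,
         " iterations (last max |delta alpha| = ", format(delta), ")")
  labels <- colnames(evidence)
  if (is.null(labels)) labels <- paste0("model", seq_len(K))
  alpha <- stats::setNames(alpha, labels)
  structure(list(dirichlet_alpha = alpha,
                 expected_frequencies = alpha / sum(alpha),
                 exceedance_prob = exceedance_probabilities(alpha, n_samples, seed),
                 assignments = g,
                 n_iter = it,
                 mc_samples = n_samples,
                 seed = seed),
            class = "bms_result")
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo estimate of \code{P(r_k > r_j for all j != k)} under
#' \code{Dirichlet(alpha)}: the probability that model k is the most frequent
#' model in the population.
#'
#' @param dirichlet_alpha positive Dirichlet counts, one per model.
#' @param n_samples number of Monte-Carlo samples (>= 10^4).
#' @param seed seed for the draw.
#' @return a probability vector summing to 1 (up to Monte-Carlo error).
#' @export
exceedance_probabilities <- function(dirichlet_alpha, n_samples = 1e6, seed = 1L) {
  stopifnot(all(dirichlet_alpha > 0))
  if (n_samples < 1e4) stop("n_samples must be at least 10^4")
  K <- length(dirichlet_alpha)
  n_samples <- as.integer(n_samples)
  counts <- withr::with_seed(seed, {
    # Dirichlet draws via normalized gammas; argmax is invariant to the
    # normalization so the gamma draws are compared directly.
    draws <- vapply(dirichlet_alpha,
                    function(a) rgamma(n_samples, shape = a),
                    numeric(n_samples))
    tabulate(max.col(draws, ties.method = "first"), nbins = K)
  })
  stats::setNames(counts / n_samples, names(dirichlet_alpha))
}

#' AIC-based log model evidence matrix
#'
#' Converts per-subject fit results to the approximate log model evidence
#' used by \code{\link{bms_group}}: \code{-0.5 * N * AIC_per_trial}, i.e. the
#' per-trial AIC rescaled back to the total-deviance scale.
#'
#' @param fits a list (one element per subject) of lists of
#'   \code{"fit_result"}s (one per model, same order for every subject).
#' @return numeric matrix, subjects x models, with model-name column names.
#' @export
aic_evidence <- function(fits) {
  stopifnot(length(fits) >= 1L)
  models <- vapply(fits[[1]], function(f) f$model, character(1))
  ev <- t(vapply(fits, function(subject_fits) {
    vapply(subject_fits, function(f) -0.5 * f$n_trials * f$AIC, numeric(1))
  }, numeric(length(models))))
  colnames(ev) <- models
  ev
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects group BMS (", x$n_iter, " iterations, ",
      format(x$mc_samples, big.mark = ","), " MC samples)\n", sep = "")
  print(data.frame(alpha = round(x$dirichlet_alpha, 3),
                   expected_freq = round(x$expected_frequencies, 4),
                   exceedance_prob = round(x$exceedance_prob, 4)))
  invisible(x)
}
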