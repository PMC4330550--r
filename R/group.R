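#' Behavioral summary of a single subject
#'
#' Computes the standard descriptive behavioral measures on the non-missed
#' trials of one record:
#' \itemize{
#'   \item \code{percent_correct}: percentage of trials choosing the
#'     currently correct stimulus;
#'   \item \code{n_switches}: number of trials whose choice differs from the
#'     previous non-missed choice;
#'   \item \code{mean_punishments_before_switch}: mean, over switch events,
#'     of the run length of consecutive punished trials immediately
#'     preceding the switch (\code{NaN} when the subject never switches).
#' }
#'
#' The summary is invariant to relabeling the two stimuli.
#'
#' @param record a \code{"behavioral_record"} for a single subject.
#' @return a list of class \code{"behavioral_summary"}.
#' @export
summarize_behavior <- function(record) {
  if (nrow(record) == 0L) stop("empty behavioral record")
  keep <- !(record$missed == 1L | is.na(record$choice))
  choice <- record$choice[keep]
  correct <- record$correct_stimulus[keep]
  outcome <- record$outcome[keep]
  n <- length(choice)
  if (n == 0L) stop("record has no non-missed trials")
  switches <- if (n > 1L) which(choice[-1L] != choice[-n]) + 1L else integer(0)
  punish_runs <- vapply(switches, function(i) {
    k <- 0L
    j <- i - 1L
    while (j >= 1L && outcome[j] < 0) { k <- k + 1L; j <- j - 1L }
    k
  }, integer(1))
  structure(list(percent_correct = 100 * mean(choice == correct),
                 n_switches = length(switches),
                 mean_punishments_before_switch =
                   if (length(switches)) mean(punish_runs) else NaN,
                 n_trials = n),
            class = "behavioral_summary")
}

#' Group comparison of fitted model parameters
#'
#' Mirrors the parameter analysis customary for this design: a mixed-design ANOVA with
#' between-subject factor group and within-subject factor parameter
#' (classical split-plot sums-of-squares via \code{\link[stats]{aov}} with an
#' \code{Error(subject/parameter)} stratum, no sphericity correction),
#' followed by per-parameter two-sample pooled-variance t-tests with
#' Bonferroni correction over the parameter family.
#'
#' @param params_df data.frame with columns \code{subject_id}, \code{group}
#'   (exactly two levels) and one numeric column per parameter.
#' @param parameters character vector of parameter column names to analyse.
#' @return a list of class \code{"group_comparison"} with \code{anova}
#'   (data.frame: effect, df, df_error, F, p) and \code{t_tests} (data.frame:
#'   parameter, mean per group, t, df, p_raw, p_bonferroni).
#' @export
compare_groups_parameters <- function(params_df,
                                      parameters = c("alpha_c_pos", "alpha_c_neg",
                                                     "alpha_u_pos", "alpha_u_neg",
                                                     "tau")) {
  stopifnot(all(c("subject_id", "group") %in% names(params_df)),
            all(parameters %in% names(params_df)))
  groups <- unique(params_df$group)
  if (length(groups) != 2L) stop("exactly two groups required")
  if (any(table(params_df$group) < 2L)) stop("need >= 2 subjects per group")

  long <- data.frame(
    subject = factor(rep(params_df$subject_id, times = length(parameters))),
    group = factor(rep(params_df$group, times = length(parameters))),
    parameter = factor(rep(parameters, each = nrow(params_df)),
                       levels = parameters),
    value = unlist(params_df[parameters], use.names = FALSE))
  fit <- aov(value ~ group * parameter + Error(subject / parameter),
             data = long)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: subject:parameter"]][[1]])
  pick <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    err <- which(trimws(rownames(tab)) == "Residuals")
    data.frame(effect = term, df = tab$Df[i], df_error = tab$Df[err],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  anova_tab <- rbind(pick(between, "group"),
                     pick(within, "parameter"),
                     pick(within, "group:parameter"))

  g1 <- params_df$group == groups[1]
  tt <- lapply(parameters, function(pn) {
    x <- params_df[[pn]][g1]
    y <- params_df[[pn]][!g1]
    if (sd(x) == 0 && sd(y) == 0) {
      data.frame(parameter = pn, mean_1 = mean(x), mean_2 = mean(y),
                 t = 0, df = length(x) + length(y) - 2L, p_raw = 1,
                 degenerate = TRUE)
    } else {
      h <- t.test(x, y, var.equal = TRUE)
      data.frame(parameter = pn, mean_1 = mean(x), mean_2 = mean(y),
                 t = unname(h$statistic), df = unname(h$parameter),
                 p_raw = h$p.value, degenerate = FALSE)
    }
  })
  tt <- do.call(rbind, tt)
  names(tt)[2:3] <- paste0("mean_", groups)
  tt$p_bonferroni <- bonferroni(tt$p_raw, length(parameters))
  structure(list(anova = anova_tab, t_tests = tt, groups = groups,
                 correction = "bonferroni"),
            class = "group_comparison")
}

#' Bonferroni correction
#'
#' @param p raw p-values.
#' @param m family size (defaults to \code{length(p)}).
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' Two-sample t-statistic from summary statistics
#'
#' Pooled-variance two-sample t-test reconstructed from group means and
#' standard errors (as printed in group comparison tables), with
#' \code{df = n1 + n2 - 2}.
#'
#' @param mean1,sem1,n1 first group's mean, SEM and size.
#' @param mean2,sem2,n2 second group's mean, SEM and size.
#' @return list with \code{t}, \code{df} and \code{p}.
#' @export
t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  t <- (mean1 - mean2) / sqrt(sem1^2 + sem2^2)
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Tertile binning of a reward prediction error trace
#'
#' Sorts the trial-wise RPEs (ties broken by trial order) and splits them
#' into three equally sized bins — negative, neutral and positive — with
#' remainder trials assigned to the earlier bins. The reported boundaries
#' are the largest RPE of the negative bin and the largest RPE of the
#' neutral bin.
#'
#' @param trace an \code{"rpe_trace"} from \code{\link{compute_rpe_trace}},
#'   or a numeric vector of RPEs (>= 3 values).
#' @return an object of class \code{"rpe_bins"}: list with \code{labels},
#'   \code{boundaries} (\code{lower}, \code{upper}), \code{sizes},
#'   \code{bin} (per-trial factor in trace order) and \code{index}
#'   (per-bin trial index lists).
#' @examples
#' bin_rpes(c(-1, 0, 1))$boundaries
#' @export
bin_rpes <- function(trace) {
  rpe <- if (is.numeric(trace)) trace else trace$rpe
  n <- length(rpe)
  if (n < 3L) stop("need at least 3 trials to form tertile bins")
  ord <- order(rpe, seq_len(n))            # stable: ties by trial order
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + as.integer(seq_len(3L) <= rem)
  labels <- c("negative", "neutral", "positive")
  bin_sorted <- rep(labels, times = sizes)
  bin <- character(n)
  bin[ord] <- bin_sorted
  bin <- factor(bin, levels = labels)
  index <- split(ord, bin_sorted)[labels]
  boundaries <- c(lower = max(rpe[index$negative]),
                  upper = max(rpe[index$neutral]))
  structure(list(labels = labels, boundaries = boundaries, sizes = sizes,
                 bin = bin, index = index),
            class = "rpe_bins")
}

#' Export cue/feedback event regressors with mean-centered modulators
#'
#' Builds an events table suitable for constructing parametric-modulator
#' regressors: one cue event per trial carrying the mean-centered chosen
#' value, and one feedback event per trial carrying the mean-centered RPE
#' and its tertile bin label. Onsets are in seconds, zero-based from session
#' start; impulse events have duration 0.
#'
#' @param trace an \code{"rpe_trace"}.
#' @param bins an \code{"rpe_bins"} for the same trace.
#' @param onsets list (or data.frame) with numeric elements \code{cue} and
#'   \code{feedback}, each the same length as the trace.
#' @param file optional TSV path; when given the table is written to it.
#' @return the events \code{data.frame} (invisibly when \code{file} is
#'   given), columns \code{onset}, \code{duration}, \code{trial_type},
#'   \code{trial}, \code{rpe}, \code{chosen_value}, \code{rpe_bin}.
#' @export
export_regressors <- function(trace, bins, onsets, file = NULL) {
  stopifnot(inherits(bins, "rpe_bins"),
            !is.null(onsets$cue), !is.null(onsets$feedback))
  n <- nrow(trace)
  if (length(onsets$cue) != n || length(onsets$feedback) != n)
    stop("onsets length must match the trace (", n, " trials)")
  rpe_c <- trace$rpe - mean(trace$rpe)
  val_c <- trace$chosen_value - mean(trace$chosen_value)
  ev <- rbind(
    data.frame(onset = onsets$cue, duration = 0, trial_type = "cue",
               trial = trace$trial, rpe = NA_real_, chosen_value = val_c,
               rpe_bin = NA_character_, stringsAsFactors = FALSE),
    data.frame(onset = onsets$feedback, duration = 0, trial_type = "feedback",
               trial = trace$trial, rpe = rpe_c, chosen_value = NA_real_,
               rpe_bin = as.character(bins$bin), stringsAsFactors = FALSE))
  ev <- ev[order(ev$onset, ev$trial), ]
  rownames(ev) <- NULL
  if (!is.null(file)) {
    write.table(format(ev, digits = 15, trim = TRUE, scientific = FALSE),
                file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("%.2f%% correct, %d switches, %.2f punishments before switch (N = %d trials)\n",
              x$percent_correct, x$n_switches,
              x$mean_punishments_before_switch, x$n_trials))
  invisible(x)
}
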