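---
title: "Risk-sensitive reinforcement learning in probabilistic reversal learning: models, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-sensitive reinforcement learning in probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrl)
```

# The task

`flexrl` models behavior in a two-stimulus probabilistic reversal-learning
task. On every trial the subject chooses one of two stimuli; one of them is
covertly designated *correct* and pays a reward with probability 0.8 (a
punishment otherwise), while the other rewards with probability 0.2. Once
the subject has made a criterion number of correct choices since the last
reversal — drawn uniformly between 6 and 10 per block — of which at least 3
were consecutive, the designation flips without warning. A session consists
of two runs of 60 decision trials; task state, including the identity of
the correct stimulus, carries across the run boundary. Outcomes enter
learning on the unit scale, $R_t \in \{+1, -1\}$; the monetary magnitudes
(±50 centimes per outcome, −100 for a missed response) are payoff labels
with no role in the model equations.

`task_config()` holds these constants, `run_session()` plays a session for
any choice-policy callback, and `simulate_agent()` plugs a learning model
into the task. Missed trials can be injected with `miss_probability`; they
carry no outcome, do not advance the reversal counters, and are excluded
from likelihoods and value updates.

Two readings of the reversal rule were possible: the criterion could be
drawn once per run or once per block. We draw it per block, the simplest
reading of a criterion that is "randomly determined" between its bounds;
with a well-performing agent the number of correct choices between
reversals then equals the drawn criterion exactly.

# The learning models

All three models maintain one value per stimulus, updated from the reward
prediction error (RPE) of the chosen stimulus,
$$\delta_t = R_t - V_t^{c},$$
and choose through a logistic (softmax) policy with temperature $\tau$:
$$p_t(A) = \frac{1}{1 + e^{-(V_t^A - V_t^B)/\tau}}.$$

* **Rescorla–Wagner (`rw`, 2 free parameters)** — a single learning rate:
  $V^{c} \leftarrow V^{c} + \alpha\,\delta$; the unchosen value is untouched.
* **Risk-sensitive (`rs`, 3 parameters)** — separate learning rates for
  positive and negative RPEs, $\alpha^{+}$ and $\alpha^{-}$. Asymmetric
  rates make the asymptotic valuation of a probabilistic option depend on
  outcome variance, which is the construct's link to risk attitude.
* **Risk-sensitive with anticorrelated valuation (`rsav`, 5 parameters)** —
  in a two-option task, feedback about the chosen option is also
  informative about the unchosen one. The unchosen value is therefore
  pushed in the opposite direction, with its own rates
  $\alpha_u^{+/-}$ selected by the sign of the *chosen* RPE:
  $$V^{c} \leftarrow V^{c} + \alpha_c^{+/-}\,\delta, \qquad
    V^{u} \leftarrow V^{u} - \alpha_u^{+/-}\,\delta.$$

The models nest: `rs` with $\alpha^{+}=\alpha^{-}$ reproduces `rw`
trajectories bit-identically, and `rsav` with zero unchosen rates
reproduces `rs`. These equivalences are enforced by tests.

## The unchosen update is not variance-preserving

The anticorrelated difference equation above has a property worth being
explicit about: the unchosen value is *not* a convex combination of its old
value and a bounded target, so it is not confined to $[-1, 1]$. Whenever
the chosen and unchosen rates differ, repeated updates can drive the
unchosen value well outside the outcome range, after which a single
surprising outcome swings the value difference violently. At high learning
rates — including the group-mean estimates this package ships as cohort
presets — simulated agents can lock onto one stimulus for long stretches
and track reversals poorly, far below the performance level of the human
cohorts whose fits produced those estimates. The consequences for
validation are discussed under *Parameter recovery* below.

Because of this, the package also implements a bounded variant of the
anticorrelated update,
`model_spec("rsav", unchosen_rule = "fictive")`, which moves the unchosen
value toward the opposite outcome with its own rate:
$V^{u} \leftarrow V^{u} + \alpha_u^{+/-}(-R_t - V^{u})$. The two rules
coincide exactly whenever $V^{u} = -V^{c}$ (perfect anticorrelation, which
holds identically in the symmetric special case), and the fictive form
keeps all values in $[-1, 1]$. The unbounded difference equation remains
the default because it is the form the model family is defined by; the
fictive rule is provided for users who need a stable generative model at
high learning rates, and it is the rule under which estimator-consistency
properties are tested.

## Numerical conventions

* Initial values are $V_0 = (0, 0)$: a symmetric prior on the unit outcome
  scale, configurable via `v0`.
* Values are not reset between the two runs of a session; the session is
  treated as one continuous learning episode (configurable by fitting runs
  separately if desired).
* An RPE of exactly zero takes the positive-rate branch. The event has
  measure zero under continuous values; fixing the convention makes
  replays bit-reproducible.
* Inside the likelihood, softmax probabilities are clamped to
  $[10^{-15}, 1-10^{-15}]$ so that saturated logistics cannot contribute
  $-\infty$ terms.

# Fitting

## The switch/stay likelihood

Fitting maximizes the probability the model assigns to the observed
*switch or stay* behavior: for every trial with a defined predecessor, the
softmax probability (given values updated through the previous trial) of
repeating versus abandoning the previous non-missed choice. With two
stimuli this equals the probability of the observed choice itself. The
first non-missed trial of a session contributes no term; missed trials
contribute neither a term nor an update. `log_likelihood()` returns the
*mean* log probability per evaluated trial, and the information criterion
is kept on the same per-trial scale:
$$\mathrm{AIC} = -2\,\overline{\log L} + \frac{2M}{N},$$
with $M$ free parameters and $N$ evaluated trials.

A per-trial mean log-likelihood is bounded above by $0$ and below — for
any model that cannot do worse than ignoring its inputs — by
$\ln 0.5 \approx -0.693$ at the optimum. Published group means for this
task family sometimes fall below that bound, which indicates a different
(and not fully recoverable) normalization of the likelihood; absolute
log-likelihood levels are therefore not a reproduction target of this
package. Model *ranking*, which is what the likelihood is used for, is
unaffected.

## Optimization

`fit_subject()` runs a seeded multi-start search: `n_starts` uniform draws
inside the box bounds (learning rates in $[0,1]$, $\tau \in [0.01, 10]$)
plus the box midpoint, each refined by bounded quasi-Newton local
optimization. Ties in the final objective are broken by the smallest
$\tau$, then lexicographically over the learning rates, so fits are exact
functions of (data, seed). On 2-parameter models the resulting optimum is
verified against an exhaustive $0.01$-step grid in the test suite. The
choice of global optimizer is deliberately unremarkable — the contract is
the maximum, not the algorithm — and 16 restarts are the default because
doubling them was not observed to change any reported optimum beyond the
grid tolerance.

`fit_canonical()` estimates one shared parameter vector across all
subjects by maximizing the unweighted mean of the per-subject mean
log-likelihoods. A single canonical parameter set is what one wants when
deriving common RPE regressors that must not build group differences into
downstream analyses. Pooling trials instead of averaging subjects would
differ only through unequal evaluated-trial counts, which the study design
makes negligible.

# Model selection

`bms_group()` implements random-effects Bayesian model selection: model
identity is a random effect with population frequencies $r$ under a
uniform Dirichlet prior ($\alpha_0 = 1$ per model). The variational
iteration alternates subject-wise posterior model assignments
($\propto \exp(\text{log evidence} + \psi(\alpha_k) - \psi(\Sigma\alpha))$)
with Dirichlet count updates until the counts stabilize. Log model
evidence is approximated from the per-trial AIC rescaled back to the
total-deviance scale, $-\tfrac{1}{2} N \cdot \mathrm{AIC} = N\overline{\log L} - M$,
the natural proxy when AIC is the only reported criterion. Exceedance
probabilities $P(r_k > r_j \,\forall j \neq k)$ are estimated from at
least $10^4$ (default $10^6$) seeded Dirichlet samples; the two-model case
is checked against the closed-form Beta integral in the tests.

# Synthetic cohorts and what they can show

`generate_cohort()` reproduces the study design in silico: 19 "adolescent"
and 17 "adult" RSAV agents, 2 × 60 trials each, with subject-level
parameters drawn from independent truncated normals around the two groups'
published group-mean estimates. Published dispersions are interpreted as standard errors and
converted to population SDs by $\mathrm{SD} = \mathrm{SEM}\sqrt{n}$; this
interpretation is supported by the published two-sample statistic for the
negative chosen learning rate, which is reproduced almost exactly from the
means and SEMs under that reading. Truncation to the admissible boxes
shifts realized means slightly toward the interior (for a mean of 0.69
with SD ≈ 0.22 on $[0,1]$, by about 0.03); the sampling tests assert the
analytic truncated-normal mean rather than the nominal one.

Each subject receives a seed derived from the master seed, so cohorts
regenerate bit-identically regardless of simulation order, and the
generating parameters are retained for recovery scoring.

What the generator does *not* emulate: reaction times, within-session
nonstationarity of human parameters, parameter correlations across
subjects (none are reported), misses (off by default), and anything
neural. Passing pipeline tests on these cohorts therefore demonstrates the
estimation machinery — not that human data would yield the same
parameters.

## Parameter recovery

`recover_parameters()` simulates cohorts from a group specification, refits
the generating model per subject, and reports cohort-mean estimates across
replications. Two regimes emerge, and the contrast is instructive:

* Under the **fictive** unchosen rule, agents at the preset means track
  reversals, switch/stay data are informative, and the cohort-mean negative
  chosen learning rate is recovered close to its generating value; the
  test suite asserts the textbook consistency property that per-subject
  recovery error shrinks when sessions are lengthened tenfold.
* Under the **default difference-equation rule**, agents at the preset
  means generate lock-in behavior with long stay streaks. The likelihood
  is then nearly flat in the learning rates for many simulated subjects,
  per-subject estimates pile up at the box boundaries, and the cohort-mean
  estimate of the negative chosen learning rate is biased substantially
  downward even though the optimizer verifiably finds likelihoods at least
  as high as the generating parameters'. `scripts/acceptance.R` quantifies
  this bias each time it runs.

The second point is a genuine property of the model-estimator pair at
these parameter values, not an implementation artifact: the identical
fitting machinery recovers the same quantities well under the bounded
rule. Users running recovery studies at high learning rates should expect
weak identifiability from 120-trial sessions under the default rule.

# Behavioral summaries, group statistics and RPE binning

`summarize_behavior()` computes percent correct (share of non-missed
trials choosing the currently correct stimulus), the number of switches
(choice differing from the previous non-missed choice), and the mean
number of consecutive punished trials immediately preceding each switch —
the operationalization of "punishments before switching"; switches with no
preceding punishment count as zero.

`compare_groups_parameters()` mirrors the parameter analysis customary for this design: a
mixed-design ANOVA (between: group; within: the five parameters) using the
classical split-plot decomposition without sphericity correction, followed
by per-parameter pooled-variance t-tests with Bonferroni correction over
the five-parameter family. `t_from_summary()` reconstructs the two-sample
statistic from published means and SEMs.

`bin_rpes()` splits a subject's trial-wise RPEs into three equally sized
bins (negative / neutral / positive) by sorting with ties broken by trial
order and assigning remainder trials to the earlier bins; the reported
boundaries are the maxima of the lower and middle bins. Boundaries are
computed per subject and summarized as group mean ± SEM, matching how such
boundaries are reported. `export_regressors()` writes a cue/feedback
events table with mean-centered chosen-value and RPE modulators and the
bin label, onsets in seconds and zero duration — the tabular precursor of
parametric-modulator regressors; no neuroimaging formats or convolution
are in scope.

# The pipeline

`run_pipeline(pipeline_config("paper", seed))` chains every stage:
simulate the 36-subject cohort, fit all three models per subject, tabulate
mean log-likelihood and per-trial AIC per model for each group and
overall with group-BMS exceedance probabilities, fit the canonical RSAV
parameters, compare fitted RSAV parameters between groups, and derive
canonical-parameter RPE traces, tertile bins, boundary summaries and
events files. Results are returned as a list and, given an output
directory, written as per-subject TSVs, events TSVs and a versioned
`results.json`. The `"tiny"` preset (2 subjects per group, 2 × 10 trials,
4 restarts) runs in seconds and exercises every stage; it is the smallest
design on which the group-comparison stage is defined.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config("paper", seed = 1))
res$model_table
res$group_tests$t_tests
```

# Problem sizes and runtime choices

The validation suite uses cohorts of 36 subjects × 120 trials for model
identification, 10 replications of 19- or 17-subject cohorts for recovery,
$10^5$ trials for contingency convergence, $10^4$ random sequences for the
nesting equivalences, and $10^6$ Monte-Carlo samples for exceedance
probabilities. The likelihood replay is implemented in C++ (via Rcpp), so a
full three-model fit of a 120-trial subject at 16–20 restarts takes a
fraction of a second and the complete pipeline runs in minutes on one core.

# Known limitations

* Published absolute log-likelihood levels for this task family are not
  reproducible (normalization ambiguity documented above); only model
  ranking and exceedance patterns are.
* The default anticorrelated update is unstable at high learning rates,
  with the recovery consequences described above.
* No hierarchical or empirical-Bayes estimation; per-subject maximum
  likelihood plus group statistics only.
* Group BMS reports plain (not protected) exceedance probabilities.
* The generator draws parameters independently per subject; any true
  parameter correlations would change recovery noise but not the
  machinery.
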