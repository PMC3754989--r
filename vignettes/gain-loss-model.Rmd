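---
title: "The gain-loss model: task, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gain-loss model: task, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainloss)
library(dplyr)
```

## The task

The package simulates and scores a probabilistic classification task that
interleaves reward learning and punishment learning. On every trial one of
four abstract stimuli (S1–S4) appears and the learner assigns it to category
A or B. Each stimulus belongs to a *majority* category on 80% of its
appearances and to the other category on 20%. S1 and S2 are *reward*
stimuli: a correct classification (matching the category sampled for that
trial) gains 25 points, an incorrect one produces no feedback. S3 and S4 are
*punishment* stimuli: an incorrect classification loses 25 points, a correct
one produces no feedback. The no-feedback outcome is therefore ambiguous —
on reward trials it signals a missed reward, on punishment trials a
successfully avoided punishment — and how a learner values it is the
scientific quantity of interest.

A session is 160 trials in four blocks; within a block each stimulus appears
exactly 10 times, 8 with its majority category and 2 with its minority
category, in uniformly shuffled order. The composition is exact per block by
design, not an independent 80/20 draw per trial, because that is how the
task is constructed; `build_session()` enforces it and the tests count it.
The point tally starts at 500 and is not floored. Responses are scored as
*optimal* when they match the stimulus's majority category, regardless of
the category sampled on that trial — a learner can respond optimally and
still receive no reward on a 20% trial.

Two cosmetic aspects of the original administration are intentionally
absent: the assignment of visual stimuli to the abstract roles S1–S4
(irrelevant to the analysis) and the two unscored practice trials.

## The model

Behavior is modeled with a four-parameter gain-loss reinforcement-learning
model. Expectancies $Q[r, s]$ for each response $r \in \{A, B\}$ and
stimulus $s$ start at 0. Given stimulus $s$, the probability of responding A
is a softmax over the two expectancies,

$$\Pr(A) = \frac{e^{Q[A,s]/\beta}}{e^{Q[A,s]/\beta} + e^{Q[B,s]/\beta}},$$

where $\beta \in [0, 1]$ is an inverse gain: small $\beta$ concentrates
choice on the higher expectancy, large $\beta$ approaches random choice.
After the response, the received feedback is mapped to a reinforcement value
$R$: reward $R^+ = +1$, punishment $R^- = -1$, and no feedback $R_0$, a free
parameter in $[-1, +1]$. The prediction error is $PE = R - Q[r, s]$ for the
response actually emitted, and only that entry is updated,

$$Q[r,s] \leftarrow Q[r,s] + \begin{cases}
\alpha_G \, PE & PE > 0 \\
\alpha_L \, PE & PE < 0,
\end{cases}$$

with separate learning rates $\alpha_G, \alpha_L \in [0, 1]$ for
better-than-expected and worse-than-expected outcomes.

$R_0$ is the interesting parameter. An agent with $R_0$ near $+1$ treats
no-feedback like a reward: on reward trials both the optimal response
(rewarded 80% of the time) and the non-optimal one (mostly no feedback) then
look similarly good, so reward learning degrades, while on punishment trials
the contrast between no-feedback (frequent under optimal responding) and
punishment grows, so punishment learning improves. This asymmetry is the
mechanism behind the package's two-group presets (below) and is
property-tested in simulation.

Two conventions are fixed here because the softmax display leaves them open:

* **Functional form.** We divide by $\beta$ (temperature form). This matches
  the stated behavior — low $\beta$ means exploitation — and is equivalent
  to an inverse-temperature parameterization under relabeling.
* **$\beta = 0$.** Defined by the greedy limit: probability 1 for the larger
  expectancy, 0.5 on ties. In likelihood mode a single observed response
  inconsistent with greedy choice then has probability 0 and the session's
  log-likelihood is $-\infty$, which removes $\beta = 0$ grid points from
  contention without any numerical hack. No probability flooring or clamping
  is applied anywhere else either, because flooring would silently move the
  maximum-likelihood estimate.

## Estimation

The model is fit per participant by maximizing the log-likelihood

$$LLE = \sum_{t=1}^{160} \ln \Pr(r_t, t),$$

the summed log probability the model assigns to the participant's actual
responses, replaying the session with the actual feedback received. The
estimator is an exhaustive grid search: $\alpha_G$, $\alpha_L$ and $\beta$
from 0 to 1 in steps of 0.05 and $R_0$ from $-1$ to $+1$ in steps of 0.1
(21^4 = 194,481 points, `grid_spec()`). No continuous refinement is run on
top of the grid — the grid *is* the estimator, and the reported estimates
always lie on it.

Two implementation details matter:

* **Speed.** The expectancy trajectory depends only on the observed
  responses, the feedback, $\alpha_G$, $\alpha_L$ and $R_0$ — not on
  $\beta$, which enters only through the choice probabilities. The compiled
  kernel therefore replays each $(\alpha_G, \alpha_L, R_0)$ combination once
  and reuses the trajectory across all 21 $\beta$ values, evaluating the
  full grid for a 160-trial session in well under a second. A naive
  trial-by-trial replay in R (`session_log_likelihood()`) is kept as the
  reference implementation, and the test suite requires agreement to 1e-9
  at every point of a reduced grid.
* **Ties.** Distinct grid points can attain exactly the same likelihood —
  most plainly when $\alpha_G = \alpha_L = 0$, where every $(\beta, R_0)$
  point gives $160 \ln 0.5$. The fit reports the number of tied points
  (within an absolute tolerance of 1e-9, guarding floating-point noise in
  genuinely identical computations) and deterministically returns the first
  maximizer in ascending lexicographic order over
  $(\alpha_G, \alpha_L, \beta, R_0)$, so results do not depend on
  evaluation order.

## Behavioral scoring

`summarize_behavior()` scores percent-optimal responding over the 80 reward
and 80 punishment trials (and per block of 40). A participant is a *solver*
on a trial type when the optimal count reaches `criterion_count(80, 0.01)`
= 52, the smallest count whose exact two-tailed binomial test against
chance beats p < 0.01 (52/80 gives p = 0.0097; 51/80 gives 0.018). The
solver threshold is inclusive (≥ 52); the below-chance flag on reward
trials is strict (< 35%, i.e. ≤ 27 of 80). Both comparisons are made on
counts; percentages are derived output.

## Group statistics

The statistics used for group comparisons are thin, tested wrappers with
explicit conventions: Pearson chi-square with the Yates continuity
correction for 2×2 tables (each $|O - E|$ reduced by 0.5, floored at zero),
exact two-tailed binomial p-values
($\min(1, 2\min(P(X \le k), P(X \ge k)))$), two-sample t-tests computed
from summary statistics (pooled df or Welch–Satterthwaite, possibly
fractional), and Pearson/Spearman correlations. All p-values are two-sided.
Mixed-model ANOVA machinery is deliberately not included: those analyses
require raw cohort data this package does not ship, and standard tools
exist for them.

## The synthetic cohort

`default_presets()` defines the two-group design the package is built
around: a control group of 39 and a PTSS group of 48
(N = 87). Both groups share the same truncated-normal distributions for
$\alpha_G$ (mean 0.27, SD 0.32), $\alpha_L$ (0.23, 0.34) and $\beta$ (0.34,
0.27) — centered on the cohort-wide parameter estimates, and shared across
groups because no group difference in learning rates or inverse gain was
found. The groups differ only in $R_0$: the control preset is centered at
0.5 and the PTSS preset at 0, the configuration observed in unmedicated
subgroups. The $R_0$ spread of 0.2 is an implementation choice (only
centers and cohort-wide SDs are reported for the real cohort); it is
configurable, and 0.2 keeps the two groups overlapping but distinguishable,
which is what the direction properties require. Truncation to each
parameter's legal range uses inverse-CDF sampling, so draws are exact and
reproducible; all randomness flows from one master seed through per-agent
seeds recorded in the manifest.

Covariate labels (combat exposure, medication, behavioral-inhibition class)
are generated with exact per-group counts matching the reference cohort's
demographics, purely to exercise the contingency-table statistics; they have
no
behavioral effect on the simulated agents.

What the generator emulates: the task's exact trial structure, agents whose
choices follow the gain-loss model with stable parameters, and the group
difference in how ambiguous feedback is valued. What it does not emulate:
response perseveration beyond what the model produces, within-session
parameter drift, lapses and attention failures, reaction times, any
behavioral effect of medication or covariates, and questionnaire content.
Passing tests on this cohort therefore show that the pipeline recovers the
structure the model generates — not that real participants follow the
model.

## Validation

Three layers of validation run in the test suite:

* **Oracle equivalence.** The grid search agrees with an independent
  quadruple-loop reference on reduced grids, and with closed forms where
  they exist (non-learning parameters give exactly $160 \ln 0.5 \approx
  -110.90$).
* **Parameter recovery.** `recovery_experiment()` simulates agents with
  known parameters drawn uniformly from grid nodes, refits them, and
  reports per-parameter bias, mean absolute error and Spearman rank
  correlation. With 200 agents and 160-trial sessions the rank correlation
  for $R_0$ is about 0.8 (MAE about 0.24); with 10× longer sessions the
  $R_0$ error roughly halves, the expected consistency behavior. The
  acceptance suite runs 200 agents for the correlation and 20 per arm for
  the session-length comparison; the direction-of-effect cohort checks use
  one full 87-agent cohort. These sizes give unambiguous signs for every
  directional check while keeping the whole suite comfortably rerunnable.
* **Direction properties.** Under the default presets the control-preset
  group scores lower on reward trials than the PTSS-preset group, the
  punishment-trial difference is smaller than the reward-trial difference,
  and the fitted $R_0$ is higher in the control-preset group — the
  qualitative pattern the model was built to explain. Magnitudes are not
  asserted: they depend on the chosen spread of $R_0$, which the data do
  not pin down.

## Known limitations

* The estimator inherits the grid's resolution: estimates are quantized
  (0.05 / 0.1 steps), and near-flat likelihoods (low-information sessions,
  e.g. random responders) produce ties and boundary estimates; `n_ties`
  makes this visible rather than hiding it.
* A five-parameter variant with a perseveration term is sometimes fit to
  this task family; it is out of scope here and `grid_fit()` makes no
  attempt to approximate it.
* Learning-rate recovery from 160 trials is noisy (rank correlations around
  0.5–0.7 in the recovery report); conclusions about $\alpha_G$/$\alpha_L$
  from single sessions of this length deserve caution, which is precisely
  what the recovery harness is for.
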