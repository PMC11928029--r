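---
title: "Modelling exploration and exploitation in a contextual bandit with active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exploration and exploitation in a contextual bandit with active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifbandit)
```

## The task

The package studies a contextual two-armed bandit in which information has
an explicit price. Each trial has two choices. First the agent decides
whether to *Stay* (free, uninformative) or consult a *Cue* that costs one
apple and reveals the trial's hidden context. Then it chooses between a
*Safe* path that always pays 6 apples and a *Risky* path whose payoff
distribution depends on the context: in Context 1 the risky path pays
(0, 3, 6, 9, 12) apples with probabilities (.05, .05, .10, .25, .55)
(mean 9.6), and in Context 2 with the reversed probabilities (mean 2.4).
The context is redrawn independently every trial, so the cue is the only
way to know it. Sessions run 120 trials from an endowment of 5 apples; a
random half of trials additionally force the Stay option ("you can't
ask"), which enriches the behavioural contrasts between informed and
uninformed second choices.

`task_config()` holds all of these constants and `run_session()`
simulates the generative process for any decision policy.

## The agent

The agent is a discrete-state active inference model. Its hidden state
space factorises stage × context into 8 states
({Start, Cued, ChoseSafe, ChoseRisky} × {Context 1, Context 2});
observations are {Null, Cue1, Cue2, R0, R3, R6, R9, R12}. Deterministic
state–outcome pairs (Start→Null, Cued→matching cue, ChoseSafe→R6) carry
unit Dirichlet concentration; the two ChoseRisky columns carry the free
parameter `prior` on every reward outcome and are the only part of the
likelihood the agent learns. A `merge_null` switch collapses Null into R0
for a 7-outcome variant of the observation model; the default keeps the
two distinguishable so that every stage is observable.

Within a trial the agent evaluates four policies — {Stay, Cue} ×
{Safe, Risky} — by their expected free energy

G(π, τ) = AL·E[ln Q(A) − ln P(A|s,o,π)] + AI·E[ln Q(s|π) − ln Q(s|o,π)] − EX·E[ln P(o)],

the sum of the (coefficiented) *value of reducing novelty* (expected
information gain about the likelihood parameters, entering negated), the
*value of reducing variability* (expected information gain about the
hidden context, negated), and *extrinsic value* (expected log preference
of outcomes). Policies are selected by softmax(−γ·G) with fixed precision
γ, the first action marginalises over policies, beliefs are updated
exactly by Bayes' rule after the first result, the two still-consistent
policies are re-evaluated for the second choice, and after the reward the
likelihood concentrations update by `a ← a + α·(o ⊗ Q(s))`.

Two numerical choices matter here:

* The novelty term is computed **exactly**: for every candidate
  observation the Dirichlet KL divergence of a unit update reduces to
  `log(a₀) − log(a_os) + ψ(a_os + 1) − ψ(a₀ + 1)`, so the whole
  observation × state table is one vectorised expression and no
  linearised approximation is needed.
* State inference is closed-form filtering rather than iterative descent
  on the free energy functional: on this model family the filter *is* the
  variational minimum, and the test suite verifies it against brute-force
  enumeration at 1e-10. `variational_free_energy()` is retained as a
  directly testable functional (the bound `F ≥ −ln P(o)` is exercised on
  random grids).

## Preferences, precision, and their defaults

Log preferences are set proportional to monetary value,
`ln P(o) = c · value(o)` with value 0 for Null, −1 for the cues and the
reward in apples otherwise. The constant `c` (`preference_scale`, default
0.25 nats/apple) fixes the exchange rate between information (measured in
nats by the epistemic terms) and reward. The default is chosen so that
for a unit-coefficient agent the one-trial information value of the
context cue (ln 2 ≈ 0.69 nats) exceeds its one-apple cost
(0.25 nats): with the four fixed within-trial policies, the cue has no
channel of value at the first choice other than its epistemic term, so an
exchange rate of 1 nat/apple would make *any* unit-coefficient agent
avoid the cue, contradicting the information-seeking behaviour this model
family is meant to express. Fitted `EX` coefficients absorb the scale in
every other respect.

The policy precision is fixed at γ = 4 and is never fitted (the model's
free parameters are AL, AI, EX, `prior`, and α only). At the 0.25
nats/apple scale this makes a unit-coefficient agent's asymptotic choices
near-deterministic — a 3.6-apple advantage of the risky path in a known
Context 1 yields a choice probability near 1 — which is the regime the
simulated agent is intended to occupy once it has learned the
environment. With γ = 1 the same agent's choices stay close to chance
throughout and exploitation is never expressed.

Remaining defaults: `prior` = 0.25 (a quarter pseudo-count per reward
cell, the customary weakly informative initialisation for unknown
discrete likelihoods) and α = 1 (the concentration update as raw
cumulative counting). Beliefs about the initial state are fixed at the
true context marginal and are not learned, matching the free-parameter
list; no precision (β) updating is implemented for the same reason.

## Baselines and fitting

Two reinforcement-learning baselines share the likelihood interface. The
model-free learner (k = 2: learning rate, inverse temperature) applies
the delta rule to a stage-1 value of Stay/Cue (trained on net trial
return) and to stage-2 values conditioned on the revealed information
(Cue1 / Cue2 / no cue) — without that conditioning it could not express
context-dependent behaviour at all and the comparison would be vacuous.
The model-based planner (k = 3: learning rate, inverse temperature,
initial estimate) keeps per-context mean-reward estimates, values the cue
as the expected best-arm value after revelation plus the cue cost, and
updates the marginal (responsibility-weighted by the context
probability) when an outcome arrives without a cue.

`fit_bandit()` maximises the teacher-forced choice log likelihood: the
model is stepped through the participant's realized observations and
rewards, and every *free* choice contributes `ln P(recorded action)`;
forced Stays are excluded, so `n` for the BIC (`k·ln n − 2·lnL`) counts
both stages of every trial minus the forced first choices. Bounds are
AL, AI, EX ∈ [0, 10], `prior` ∈ (0, 10], α ∈ [0, 1], and analogous boxes
for the baselines. The optimiser runs a random exploration phase followed
by guided iterations (bound-clamped Nelder–Mead in square-root-scaled
unit coordinates, restarted until the evaluation budget is spent); the
default budget of 1000 + 1000 evaluations mirrors the fitting protocol
the task was analysed with, and reduced budgets are used in the test
suite. Every probed point is recorded and the returned optimum dominates
all probes.

## What the synthetic data emulate — and what they do not

`generate_cohort()` draws per-participant parameters uniformly from
documented ranges (AL, AI ∈ [0.25, 2], EX ∈ [0.5, 4], `prior` ∈
[0.25, 2], α ∈ [0.1, 0.9]) and simulates full sessions, recording ground
truth. The coefficient ranges are stated in raw units at γ = 4; in
effective sharpness units (γ·0.25·coefficient per apple) they span agents
from moderately stochastic to the near-deterministic context-appropriate
choosers that dominate real cohorts on this task. `generate_neural_epochs()`
builds trials × regions × timepoints arrays of Gaussian (optionally
AR(1)) noise with `beta_true` times the z-scored regressor planted in one
region's effect window.

Passing tests on these data show that the estimation and regression
machinery is correct and calibrated *under the model's own assumptions*.
They do not show that real participants obey the model: real choice data
contain forgetting, lapses, and session-level nonstationarity the
generator deliberately omits, and real source-space EEG has spatially and
temporally correlated noise far richer than AR(1).

Two identifiability facts about this model family, measured with the
package's own recovery pipeline, deserve emphasis. First, scaling the
learning rate α and the concentration prior together leaves every belief
trajectory exactly invariant — only the absolute novelty magnitude (whose
weight AL is itself free) breaks the ridge — so α is structurally weakly
identified; its maximum-likelihood estimates drift along the ridge and
can sit far from the generating value even when the fit is excellent.
Second, for sharply-behaving agents the coefficient vector's overall
scale suffers the usual softmax separation drift. Per-participant point
estimates of α and of raw coefficient magnitudes should therefore be
interpreted with caution; coefficient *ratios* and model-level BIC
comparisons are far better behaved (model recovery across the three
generators is diagonally dominant in the test suite).

## Trial-wise regressors and mass-univariate regression

`compute_regressors()` exports, per trial and stage: the chosen action's
expected free energy and its three constituent values at the two choice
stages (for the first choice, averaged over the two consistent policies
weighted by their posterior); the realized reduction of state uncertainty
at the first result (AI times the negated KL from post- to pre-observation
context belief — exactly −AI·ln 2 after a cue under a uniform prior); and
the realized reduction of parameter uncertainty (negated Dirichlet KL of
the actual concentration update), the reward, and the reward prediction
error at the second result. Because log preferences are proportional to
reward, the printed "reward minus expected log preference" form of the
prediction error reduces to the ordinary reward prediction error, which
is what the package exports (signed, with the absolute value alongside).

`mass_univariate_regression()` fits `Activity ~ Regressor + Intercept`
by ordinary least squares independently for every region × timepoint
series (vectorised closed form, verified against `lm()`), with the
regressor z-scored by default so slopes are per SD of the regressor, and
masks significance by Benjamini–Hochberg FDR over the flattened grid
(`fdr_correct()`, the plain BH step-up; the BY variant was not used).
The regression is pooled over the trials of the dataset it is given;
per-participant regression followed by group aggregation is left to the
caller, since the analysis choice depends on the study design.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is bit-reproducible
under it. The test suite exercises the environment samplers at 1e5
draws, the algebraic identities of the expected free energy at 1000
randomised models, the simulation phenomenology at 20 seeds × 60 trials,
parameter recovery at 20 synthetic participants with a 100 + 100
evaluation budget, model recovery at 10 cohorts of 3 participants per
generator at a 50 + 50 budget, and the regression machinery at 120-trial
epochs — sizes chosen so the full suite completes comfortably on a single
CPU while keeping every Monte-Carlo bound at three standard errors.

## Known limitations

* The four policies are fixed action sequences; the cue's *instrumental*
  value (choosing better second-stage actions after seeing it) is
  expressed only through the post-observation re-evaluation, not in the
  first-stage expected free energy. A sophisticated (tree-search) variant
  would value the cue extrinsically as well.
* α is weakly identified (see above); the package reports it but the
  vignette's caveats apply.
* No forgetting or habit term is modelled.
* Real-EEG ingestion (preprocessing, source localisation) is out of
  scope; any externally produced trials × regions × timepoints array can
  be supplied to the regression stage directly.
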