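---
title: "A task-model approach to tea-making rehabilitation: model, simulator and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A task-model approach to tea-making rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teatask)
```

## The problem

Stroke survivors with apraxia and action disorganisation syndrome (AADS)
make characteristic errors when carrying out everyday multi-step
activities: steps are omitted, repeated, done in the wrong order, done
with the wrong object, or done with the wrong quantities.  One line of
rehabilitation formalises a single activity of daily living — here,
making a cup of tea — as an explicit task model, monitors the
participant's action stream against it, and delivers corrective cues in
real time.  `teatask` implements that whole pipeline at desk scale: the
task model, the error classifier, the cueing policy, a synthetic
participant and cohort generator, and the statistical analysis of a
two-group crossover trial of the training.

## The task model

Tea making is modelled as a Markov decision process over eight
sub-actions: *add water from jug to kettle*, *boil water*, *add teabag to
cup*, *add boiled water to cup*, *add sugar*, *add milk*, *stir*, and
*remove teabag*.  A **state** is the set of sub-actions achieved so far;
**permitted transitions** are the sub-actions whose preconditions hold
and whose execution is not an error for the current recipe; **transition
probabilities** over permitted successors are estimated from complete
control performances.

Four recipes are bundled — black tea (BT), black tea with sugar (BTS),
tea with milk (WT) and tea with milk and sugar (WTS).  A recipe's
required set is derived from its two ingredient flags.  Two conventions
close gaps that a task description alone leaves open, and both are
deliberate, configurable decisions:

* **stirring is required only when sugar is present** (something must
  dissolve); stirring an unsugared tea is classified as an unnecessary
  extra action;
* **teabag removal is always required** for task completion.

The conditioning context of the transition table is the *unordered set*
of achieved sub-actions, not the full action history.  This keeps the
table small, matches the "most probable next step" semantics of cueing
(what remains to be done matters; the order it was done in does not), and
is the weakest sufficient statistic for the permission rules.  Whether
the original system conditioned on full history is not recoverable from
its description; the set-context is our choice and is documented as such.

Estimation uses per-cell pseudocounts (default 0.5, a Jeffreys-style
smoothing) over the *candidate* successors at each context — the union of
permitted next actions across recipes — so that a permitted continuation
never seen in the control corpus can still be recommended by a cue.  With
observed counts $n(c,a)$ the estimate is

$$\hat p(a \mid c) = \frac{n(c,a) + q}{\sum_{a'} n(c,a') + Kq},$$

with $K$ candidates and pseudocount $q$.  Argmax ties are broken
lexicographically on sub-action id for reproducibility.

The control corpus itself is a **synthetic stand-in** (the original
normative recordings are not published): for each recipe the canonical
ordering is repeated with weight 6 and permitted variants (teabag before
boiling, milk before sugar, milk after teabag removal) with weight 1,
giving a dominant path plus minority alternatives.  See
`control_sequences()`.

## The error taxonomy

Errors are described in neuropsychological, task-general terms.  Four
categories are non-recoverable — addition (N-ADD), object substitution
(N-OSUB), kettle operation error (N-KET), quantity overestimation
(N-QMO) — and six are recoverable — continuous perseveration (R-CP),
execution (R-EX), recurrent perseveration (R-RP), sequence (R-SEQ),
quantity underestimation (R-QMU), step omission (R-SOM).

`classify_event()` maps each performed action deterministically to one
category or to "permitted".  Where an event matches several categories
the fixed priority is: non-recoverable before recoverable (because
non-recoverable status terminates a training trial), and within each
class the taxonomy listing order.  Three thresholds matter:

| parameter | default | meaning |
|---|---|---|
| `stir_cp_threshold_s` | 10 s | stirring longer than this is R-CP |
| `underfill_threshold` | 0.5 | cup fill fraction below this is R-QMU |
| `overfill_threshold` | 1.0 | fill fraction above this is N-QMO (no published value; a full cup is the natural limit) |

Two categories cannot be inferred from a discrete action log: execution
errors (R-EX) are movement-quality judgements and enter as pre-coded
annotations on events, and omissions (R-SOM) are end-of-task judgements
made by `detect_omissions()` against the recipe's required set.

Over the discrete vocabulary with default event attributes,
`permitted_next_actions()` and `classify_event()` are complementary: the
test suite enumerates every state reachable by permitted actions within
8 steps and checks both against an independently written rule-table
oracle.

## The session engine

`run_training_trial()` drives a behaviour stream through the cueing
policy: a cue (recommending the most probable permitted next step) fires
when the participant presses the help button, when more than
`timeout_s = 30` s pass without an action, or when a recoverable
non-omission error occurs.  Omissions are cued at the end of the task.  A
non-recoverable error terminates the trial with the error type reported;
three successive cues with no intervening correct action also terminate
it.  Policy corner cases resolved here, each flagged as a convention:

* "successive" cues are cues with **no correct action between them**; the
  counter resets on any correct step;
* the inactivity clock is **suspended while the kettle boils** and
  restarts with the full 30 s timeout when boiling ends (the boil is an
  action's `duration`);
* help-button cues **count** toward the three-cue termination (a cue is a
  cue);
* recoverable non-omission errors cue **immediately**.

`run_assessment_trial()` is the feedback-free counterpart: no cues, no
time limit, no early termination; self-correction simply happens in the
stream and every error is counted once; omissions are appended when the
stream signals completion (an explicit `done` token, standing in for the
verbal completion signal).  Completion time is recorded raw and with the
boil time deducted downstream.

## The synthetic participant and cohort

`simulate_behaviour()` perturbs the canonical sequence with one Bernoulli
draw per error category per opportunity.  The realization rules are
chosen so that injections never create knock-on errors:

* insertions that leave the task state unchanged (an early dry boil for
  N-KET, a redundant kettle refill for R-RP, a distractor coffee use for
  N-OSUB, extra sugar/milk for N-ADD);
* annotations on canonical steps (12 s stir for R-CP, fill fraction 0.4
  or 1.2 for R-QMU/N-QMO, clumsiness flags for R-EX on the three
  non-stir, non-pour steps);
* a reordering whose early completion absorbs the later step (teabag out
  before the water for R-SEQ);
* omissions restricted to sugar and milk (R-SOM) — dropping the teabag or
  the water would make the later teabag removal a spurious second error.

Because of this, the expected per-trial count of every category is
*exactly linear* in its propensity (`expected_error_counts()` gives the
closed form; the single exception is that an overfill draw is suppressed
when an underfill draw fires on the same pour, a deliberately small
coupling).  Linearity is what makes the pipeline's parameter-recovery
tests sharp: a training effect that multiplies recoverable propensities
by $1-e$ multiplies their expected counts by exactly $1-e$.

A cohort (`simulate_cohort()`) assigns participants to two groups by a
seeded balanced permutation, runs 4 assessments of 8 cups each (two per
recipe, order shuffled per participant and session with breaks after
cups 4 and 8), and applies the training effect from the assessment
following each group's tea-training phase — Group 1 from assessment 2,
Group 2 from assessment 3 — with a retention fraction at follow-up
(default 1: the improvement is sustained).  Default conditions mirror the
emulated trial: 15 per group, baseline age 71.1 (SD 7.8), 44% female,
4.6 (3.3) years post stroke, ~10% dropout, a 50% recoverable-error
reduction and a ~15 s speed-up.  Washout is assumed complete (no
carryover), matching the crossover analysis's implicit assumption; the
stepping control phase is a pure null intervention.  The five weekly
training sessions per phase can be simulated through the training-mode
engine (`simulate_training_sessions = TRUE`) but contribute no
incremental effect by default, since no per-session learning curves are
available to calibrate one — learning is a single post-phase step, a
documented simplification.

What the generator does **not** emulate: real action-timing
distributions, within-phase learning dynamics, error bursts and
participant-level error-type correlations, fatigue and motivation, and
any carryover between phases.  Passing calibration tests therefore shows
that the *pipeline* is statistically sound under its own assumptions, not
that real cohorts behave this way.

## The trial statistics

`score_assessment()` sums errors (by recoverability) over the 8 cups and
averages boil-deducted completion time.  `build_contrasts()` forms the
within-participant change scores, signed earlier − later so positive =
improvement: experimental (around tea training), control (around stepping)
and follow-up, mapping to assessments 1−2, 2−3, 2−4 in Group 1 and 2−3,
1−2, 3−4 in Group 2.

`rm_anova_2x3()` runs the 2 (error type) × 3 (contrast) within-subject
ANOVA, `rm_anova_oneway()` the one-way time analysis.  Mauchly's test is
applied to every effect with ≥ 3 levels and the Greenhouse–Geisser
corrected p is reported whenever it is significant (ε̂ always lies in
$[1/(k-1), 1]$).  Post-hoc pairwise comparisons are uncorrected paired
t-tests by default (matching the emulated analysis; Bonferroni is
available).  Both are verified against a from-scratch matrix-algebra
oracle at 10⁻⁸.

Missing assessments are handled by `impute_missing()`, a chained-equation
scheme (iterated stochastic linear regression per incomplete variable
with baseline auxiliaries; Rubin's rules via `pool_rubin()`).  The
scheme is written in-package and is deliberately simple: normal-residual
draws rather than posterior parameter draws, which at these sample sizes
is a second-order difference.  "Improved" for the exploratory logistic
models (`improvement_model()`, univariable by design) means a positive
experimental contrast in total errors — no published threshold exists, so
the zero cut is our documented convention.  `plan_sample_size()` refuses
to run without an explicit test family, because an effect size alone
does not determine the power equation.

## Numerical and design notes

* Determinism: every stochastic component runs from an explicit seed;
  `(config, seed)` reproduces a cohort byte-for-byte.
* Argmax ties in cue recommendations: lexicographic on sub-action id.
* Unseen transition contexts: uniform over permitted actions.
* Degenerate inputs: an all-missing variable, a constant logistic
  predictor, fewer than 3 ANOVA participants, or zero-variance
  reliability scores are rejected with explicit errors; complete
  separation in a logistic fit is flagged, not silently estimated.
* Problem sizes in the shipped tests: pipeline calibration uses 500 null
  cohorts of 15 per group and effect recovery 60 cohorts; the acceptance
  script uses 200 and 30.  These sizes give Monte-Carlo standard errors
  of about 0.01 on the rejection rate — comfortably sharp for a ±0.02
  acceptance band — while keeping a full run in the minutes range.

## Known limitations

* The two-cup "complex tea" task is out of scope: its event logs can be
  scored by the error engine, but no two-cup task model is bundled.
* The error engine supports all ten categories online, but which four
  were assessment-only in the original system is not fully enumerable
  from its description; the `trained_by_system` flag in
  `error_categories()` is a documented convention.
* The paper-scale inferential results (exact F values, contrast means)
  depend on unpublished raw trial data and are not reproduction targets;
  the statistics layer is validated structurally (oracle agreement,
  calibration, parameter recovery) instead.
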