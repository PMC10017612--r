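---
title: "Models, simulator and design choices in mptswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulator and design choices in mptswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptswitch)
```

## The problem

In cued task switching with three tasks, an error can reflect a
*task-selection failure* (the wrong task set was activated and executed)
or a *task-execution failure* (the correct task was selected but the wrong
response emitted within it). Observed responses can only be classified
into *task-confusion* and *response-confusion* categories, and the
fidelity of that classification depends on the paradigm. `mptswitch`
implements three paradigms and the multinomial processing tree (MPT)
machinery that converts observed category frequencies into estimates of
the latent failure probabilities, plus the downstream sequence analysis of
N-2 repetition costs.

## Paradigms and classification schemes

* **Univalent** (`make_paradigm("univalent")`): three tasks, two levels
  per stimulus dimension, six response keys, two per task and disjoint
  across tasks. For every stimulus: 1 correct key, 1 response-confusion
  key (cued task, wrong level), 2 task-confusion keys (the other tasks'
  correct keys for this stimulus), 2 mixed keys. Each observed category
  maps to exactly one processing path, so latent probabilities are
  estimated by direct proportions (`exp1_failure_probs()`): p(tsf) =
  (TC + mixed)/n and p(tef) = (RC + mixed)/n, mixed errors counting in
  both since they require a joint failure.
* **Bivalent with congruency** (`"bivalent_congruency"`): three levels per
  dimension, three shared keys; 3 congruent stimuli (all dimensions point
  at one key) and 3 incongruent ones (all keys distinct). Errors on
  congruent trials are classified as response confusions, errors on
  incongruent trials as task confusions.
* **Three-key target/distractor** (`"three_key"`): pairs of elements from
  two of three ordered categories (numbers, letters, symbols), 36
  incongruent stimuli, three keys by ordinal position. The distractor's
  key is a task confusion, the third key a response confusion.

Key labels are abstract symbols (`k1`...`k6`); the physical keyboard
mapping and its counterbalancing across participants are presentation
detail, deliberately out of scope.

## The MPT models

Both fitted models are saturated (two free parameters, two independent
observable proportions), with the random-execution probability `RE` fixed
at 0.5 on the assumption that after a double failure the final two-way
choice is random. `category_probabilities()` implements the trees;
`fit_mpt()` maximizes the product-multinomial likelihood over
\((T, R) \in [0,1]^2\).

A note on the three-key tree: the published equation set for this model
contains a typographic slip — its `correct` line reads
\(TR + (1-T)R\cdot 0.5\), under which the three category probabilities do
not sum to one for general \((T,R)\). The tree diagram (and the
denominators of the conditional-probability equations derived from it)
imply \(TR + (1-T)(1-R)\cdot 0.5\): after selecting the distractor's task
*and* failing response selection within it, the random two-way split can
accidentally land on the correct key. That normalized version is
implemented, and the package's simulator, classifier and fitter are
mutually consistent under it (verified by convergence tests of simulated
category shares to the tree probabilities).

### Optimization

Bounded quasi-Newton (`L-BFGS-B`) with an analytic gradient, from five
deterministic starting points \((0.5,0.5), (0.9,0.9), (0.99,0.8),
(0.8,0.99), (0.7,0.7)\); the best likelihood wins. The multistart guards
against flat or multimodal regions near the boundary. Convergence is
tightened (`factr = 1e2`) so that interior fits reproduce observed
proportions to \(G^2 < 10^{-6}\); estimates within \(10^{-5}\) of the box
are flagged `boundary`. A 1001×1001 grid-search oracle in the test suite
confirms agreement of the argmax within \(10^{-3}\) per parameter.

The headline derived quantity, p(task-selection failure | observed
category), is computed per participant and then averaged; because the
ratio is nonlinear in \((T,R)\), the mean of per-participant values
differs from the plug-in at mean parameters (Jensen's inequality) for the
task-confusion conditional — though not for the response-confusion
conditional, which reduces algebraically to \(1-T\).

## The synthetic-data generator

The generator is a stated world, not a tuning knob: its defaults describe
one realistic experiment and the tests interrogate that world.

* **Designs**: switch-only task sequences with exactly equal ABA/CBA
  triplet counts per block (constructed by shuffling a balanced vector of
  binary "return vs third task" moves — with three tasks and no immediate
  repetitions each trial from the third on makes exactly that choice);
  stimulus assignment is uniform within the cued task's inventory under a
  strict no-repeat constraint at lags 1–2. The reference designs allowed a
  handful of lag-2 repeats in one variant; we forbid them outright, which
  simplifies the invariant and affects no analysis.
* **Responses**: cued task selected with probability `T`; when selection
  fails, the three-key paradigm routes to the distractor's task (capture
  by the competing element), the other paradigms choose uniformly between
  the two irrelevant tasks — the trees are binary in selection outcome, so
  the uniform choice is the minimal assumption. Response selection then
  succeeds with probability `R` within the selected task's afforded keys.
* **RTs**: shifted lognormal, `exp(N(rt_mu, rt_sigma))`, defaults
  `rt_mu = log(550)` (≈550 ms median) and `rt_sigma = 0.25`, values in the
  range typical of speeded three-task switching; no RT model is prescribed
  by the reference analyses, so the lognormal is a package choice. Added
  to the baseline: post-error slowing `pes` (default 60 ms) after an
  observed error, and the injected N-2 repetition cost `delta_n2`
  (default 30 ms) when inhibition applies.
* **Inhibition rule**: inhibition applies on trial N iff the cued task of
  N equals the cued task of N-2 *and* (task selection at N-2 succeeded,
  or the correction process fired at N-1). Rationale: the cost reflects
  inhibition of a task set that was actually activated and then abandoned.
  After a task-selection failure the relevant task was never executed, so
  no cost arises — unless a slow correction process at N-1 re-instantiated
  (and then inhibited) it. The correction fires with probability
  `plogis(kappa * (rt(N-1) - tau))` (`kappa = 0.01`/ms, `tau` = baseline
  median RT), becoming a deterministic threshold as `kappa` grows; the
  degenerate `tau = ±Inf` regimes (always/never) are what the dissociation
  tests use. An alternative literal reading — conditioning on the
  *executed* N-2 task matching the cued task of N — would attach costs to
  some CBA trials after selection failures and cannot produce the
  documented always-regime dissociation; it was rejected in favour of the
  reading above.
* **Timeouts** arise only by truncation at `timeout_ms` (2000 ms
  laboratory, 1500 ms online, `NULL` for the no-limit group); the key is
  dropped and the trial is never categorized as an error. The correction
  probability at N-1 uses the latent (pre-truncation) RT.

What the generator does **not** emulate: parameter drift and practice
effects, congruency effects on RT, task-specific RT differences,
sequential dependencies beyond post-error slowing and the N-2 mechanism,
and response-repetition effects. A green test therefore establishes that
the pipeline recovers what this world contains — not that real data meet
the model's assumptions.

## Trimming and sequence analysis

Trial-level rules: first two trials per block; the single trial after an
error; timeouts, fast guesses (< 300 ms laboratory / < 100 ms online) and
slow responses (> 3000 ms, no-limit group only) each with the two
subsequent trials; windows operate on within-block trial numbers and never
cross blocks. A removed trial is ineligible only *as trial N*: its raw
accuracy and RT remain available as N-1/N-2 context, which is what makes
analyses conditioned on N-2 errors possible at all. Error trials get the
distinct reason `error_rt_only`: they count for MPT tabulation but not as
RT targets. Participant-level rates (fast guesses > 10%, errors > 33%)
are computed on raw trial counts; the ≥10-trials-per-cell check runs on
the analyzed (possibly simplified) design.

Sequence labelling takes each eligible RT target, classifies its triplet
(ABA vs CBA by the *cued* tasks of N and N-2), attaches the N-2 observed
category (or the latent N-2 outcome, for simulation studies) and the N-1
RT. The median split of N-1 RTs is computed per participant over all of
that participant's included targets — not per cell — so cells remain
comparable; ties go to `slow`. It is computed before cell-count-based
participant exclusion; with ≥10 trials per cell the boundary trial moved
by recomputation is immaterial.

N-2 repetition costs are ABA minus CBA participant cell means. The ANOVA
runs on participant cell means (the design-language of the reference
analyses), fully within-subject, each effect tested against its
interaction with participants; partial eta squared uses the effect's own
error stratum, generalized eta squared divides by effect SS plus all error
strata including the subject stratum. No sphericity correction is applied
— all analyzed within factors have two levels. Effect sums of squares
below \(10^{-12}\) of the total are clamped to zero to avoid 0/0 noise in
degenerate (exactly equal means) inputs.

The permutation test compares two independent groups of per-participant
values by the absolute difference of means, enumerating all assignments
exactly when \(\binom{n_a+n_b}{n_a} \le 20{,}000\) and otherwise sampling;
in both modes the identity assignment is included in the numerator and
denominator, so p ≥ 1/(number of assignments considered) and the test is
never anti-conservative at the identity.

## Numerical and degenerate-input choices

* Zero observed counts contribute \(0 \cdot \log 0 = 0\) to \(G^2\);
  all-zero count vectors are rejected.
* Zero-probability error categories make the conditional failure
  probabilities undefined; they are reported as `NA`, not 0.
* `block_length - 2` must be even, otherwise exact triplet balance is
  impossible and generation is refused.
* Seeds: every stochastic stage takes an explicit seed; multi-stage
  drivers derive per-stage child seeds deterministically (kept below
  \(2^{31}\)), so a full run is reproducible from one integer.

## Known limitations

* The acceptance surface covers in-model worked examples and
  simulation-based recovery; reproducing the reference study's
  real-participant statistics would require its deposited raw data, which
  are not bundled.
* Hierarchical/Bayesian MPT variants, bootstrap confidence intervals,
  Bayes-factor model comparison and arcsine-transformed error-rate ANOVAs
  are out of scope.
* The ANOVA engine expects balanced complete cell-mean tables and drops
  participants with missing cells rather than imputing.
* The null-calibration check in the test suite runs the ANOVA's Task
  Sequence test on 1,000 simulated null datasets of 20 participants each
  (4 blocks × 50 trials, scaled down to fit test-time budgets; the test's
  level does not depend on trial count).
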