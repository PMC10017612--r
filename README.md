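# mptswitch

Disentangling **task-selection failures** from **task-execution failures**
in cued task-switching experiments.

When people switch among several classification tasks, an error can arise
in two ways: the wrong task set was selected (a *task-selection failure*),
or the right task was selected but the wrong response executed within it
(a *task-execution failure*). Neither latent event is directly observable —
experiments instead record *observed* error categories (task-confusion vs
response-confusion errors) whose mapping onto the latent failures depends
on the paradigm. `mptswitch` implements the full analysis pipeline for the
three classification methodologies used in this literature, together with a
generative simulator, so that every stage can be validated against known
ground truth. It is aimed at researchers in cognitive psychology /
mathematical psychology working on task-switching, error monitoring and
inhibition.

## The models

Each paradigm defines a multinomial processing tree (MPT): with `T` the
probability of selecting the cued task, `R` the probability of selecting
the correct response within the selected task, and `RE = 0.5` a random
two-way execution split, the observed category probabilities are sums of
branch products. For the three-key (target/distractor) design:

    p(correct) = T·R        + (1−T)·(1−R)·0.5
    p(TC)      = T·(1−R)·0.5 + (1−T)·R
    p(RC)      = T·(1−R)·0.5 + (1−T)·(1−R)·0.5

`(T, R)` are estimated per participant by maximum likelihood
(`fit_mpt()`), and the quantities of interest are conditional
probabilities such as

    p(task-selection failure | TC) = (1−T)·R / [T·(1−R)·0.5 + (1−T)·R]
    p(task-selection failure | RC) = 1 − T

Downstream, the package computes **N-2 repetition costs** (the RT
decrement on ABA task triplets relative to CBA, the signature of
persisting task-set inhibition) conditioned on the N-2 error category and
on N-1 speed (median split), with repeated-measures ANOVA (partial and
generalized eta squared), paired contrasts (Cohen's dz) and permutation
tests. The simulator carries an injectable N-2 cost `delta_n2` and a slow
error-correction mechanism that restores the cost after an N-2
task-selection failure only when the N-1 response was slow.

## Worked example

```r
library(mptswitch)
p  <- make_paradigm("three_key")
lp <- latent_params(T = 0.93, R = 0.93, delta_n2 = 30, timeout_ms = 1500)
trials  <- simulate_experiment(p, n_participants = 8, n_blocks = 4,
                               block_length = 72, latent = lp, seed = 123)
trimmed <- trim_trials(trials, trim_config(fast_guess_ms = 100))

counts <- tabulate_categories(trimmed[trimmed$eligible_as_target, ], p)
fits   <- fit_mpt_all(counts, "exp3_three_key")
round(colMeans(fits[c("T_hat", "R_hat")]), 3)
#> T_hat R_hat
#> 0.923 0.933

cp <- conditional_failure_probs("exp3_three_key", fits$T_hat, fits$R_hat)
round(100 * colMeans(cp), 1)
#> p_tsf_given_TC p_tsf_given_RC
#>           68.8            7.7

lab <- median_split(label_sequences(trimmed))
ct  <- cost_table(lab, strata = "n2_category")
aggregate(n2_cost ~ n2_category, ct$costs, function(x) round(mean(x), 1))
#>          n2_category n2_cost
#> 1            correct    31.5
#> 2 response_confusion    61.3
#> 3     task_confusion     7.9
```

Reading the output: the per-participant MPT fits recover the generating
parameters (T = 0.93, R = 0.93); about 69% of observed task-confusion
errors — but only ~8% of response-confusion errors — are attributed to
latent task-selection failures. The injected 30 ms N-2 repetition cost is
visible after N-2 correct trials but strongly reduced after N-2
task-confusion errors (7.9 ms), because a task-selection failure means the
cued task was never executed, hence never inhibited; the response-confusion
stratum is noisy at 8 participants.

## Command line

A thin CLI mirrors the pipeline stages
(`design`, `simulate`, `classify`, `trim`, `fit-mpt`, `n2cost`, `compare`):

```sh
Rscript inst/exec/mptswitch design --paradigm=three_key --participants=2 \
    --blocks=4 --block-length=72 --seed=1 --out=design.csv
```

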