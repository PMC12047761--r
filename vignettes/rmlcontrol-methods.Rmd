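---
title: "Meta-learning of cognitive control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learning of cognitive control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmlcontrol)
```

## The model

`rmlcontrol` simulates an agent in which the *intensity of cognitive control*
is itself a learned decision. The agent has two value-learning modules,
mirroring a medial-prefrontal division of labour:

* an **action module** that tracks the expected value of every concrete
  option (a fractal stimulus, a bandit, a match/non-match response) with a
  scalar Kalman filter per option;
* a **boost module** that, at the onset of every trial, selects a discrete
  control intensity ("boost") by softmax over Kalman-tracked action values of
  its own, learned from the *net* outcome of the trial: reward minus a cost
  that is linear in the boost level.

The boost level drives two simulated neuromodulatory outputs through
affine-then-clip maps: an LC (locus coeruleus) gain signal and a VTA
(ventral tegmental area) reward-scaling signal. LC output is what makes
control *do* something: it tightens the boundaries of the diffusion
decision process (faster, slightly less careful decisions), discounts the
start-point bias toward the default "engage" choice in foraging, and raises
the gain of the working-memory network during retention. VTA output scales
reward signals; at its neutral default of 1 learning reduces to plain
Kalman reinforcement learning, which is the regime used in all three
simulated experiments.

Because boost is selected by reinforcement learning *about* reinforcement
learning, the agent settles wherever the marginal performance gain of more
control equals its marginal cost. All the "brain activity" this package
reports — simulated dACC profiles — are read directly off the trial log:
the boost level, the value expectation, and surprise (absolute prediction
error).

### Kalman value learning

Each value estimate carries a mean and an uncertainty. An outcome `y`
updates the estimate with gain `k = u / (u + r)`, where `u` is the current
uncertainty and `r` the assumed outcome variance; the posterior uncertainty
is `(1 - k) u`, plus an optional process-noise term (default 0: all task
environments here are stationary, so the sample-average behaviour of the
shrinking gain is exactly what is wanted; a positive process noise keeps
the filter adaptive if a user builds a drifting environment). Boost
q-values start at an optimistic prior with high uncertainty — every level
of the grid is therefore tried early without any explicit exploration
bonus. The prior must dominate the environment's achievable outcomes for
this to work; the defaults (7 for the speeded task's 2–7 rewards, 1 for
the WM task's 0/1 feedback) do.

### The diffusion module

Decisions that produce reaction times use a discrete-time random walk with
unit time step (one "cycle"): `x_{t+1} = x_t + drift + noise`, absorbed at
`±boundary`. The drift is proportional to the signed difference `δv`
between the learned values of the two options; the boundary decays
exponentially from `base_boundary` toward `boundary_floor` as LC rises.
The choice of a per-cycle noise SD of 1 fixes the evidence scale; all
other diffusion parameters are expressed in those units. In the
large-boundary regime in which every task here operates (boundaries of
40–220 noise units) the walk is an accurate discretisation of a Wiener
process, and the test suite checks its choice probabilities against the
closed form `1 / (1 + exp(-2·drift·boundary / noise²))`. With boundaries
of order one the discrete walk overshoots the boundary by a non-negligible
fraction of its width and the closed form no longer applies; the package
never operates there.

## The three simulated experiments

### Speeded decision-making

Two options drawn from six reward levels (2–7, two interchangeable
stimulus exemplars per level; 36 ordered pairs, side-balanced) are
presented; the agent is pretrained on the stimulus values, so `δv` is
available at cue onset. Reward is devalued linearly with reaction time,
reaching zero at the 14 000-cycle deadline, and timeouts pay nothing.

The boost module's condition label is the difficulty class `|δv|`
(0–5), which the stimulus pair reveals at onset. The printed design
(36 types balanced by side) makes the pair identity visible at onset; we
use its difficulty class rather than the full pair as the learning state
because boost demand depends on the pair only through `|δv|`, and the
coarser state lets the policy converge within a session at reduced
designs (10–36 presentations per type) where a 36-state × 10-level table
cannot.

Under the default operating point (`base_boundary = 220`,
`boundary_floor = 40`, `drift_scale = 0.02`, `cost_rate = 0.3`), ties and
near-ties are slow enough to threaten the deadline unless boosted, while
easy trials are fast regardless. The learned boost is therefore a sharply
peaked inverted-U over value difference, the expected net value a U (slow,
devalued, costly trials in the middle), and their sum — the simulated dACC
signal — a W: a center bump where control peaks, dips near `|δv| ≈ 2-3`,
and high shoulders at easy trials where value dominates. The package
quantifies the W as a quartic-versus-quadratic AIC comparison (Akaike
weights) over the 11 value-difference bins of the group-mean curve, with
the per-participant tables retained; both bin-mean and participant-level
fits are available because figure-style group curves and trial-level fits
are both common practice.

### Verbal working memory

A match-to-sample task at loads 1, 4, 6 and 8 words (90 trials each, 50%
match probes, stratified). The external module is a two-layer competitive
network: one unit per word in a 16-word lexicon (the smallest lexicon
allowing non-match probes at the highest load), presented words encoded at
activation 1, and an output layer that sustains them through the delay via
self-excitation with gain `gain_base + gain_lc_coeff · LC`, while lateral
inhibition proportional to the summed activity of the other units pulls
them down. With 50 retention steps the dynamics are effectively
threshold-like: a presented unit survives the delay iff its effective
multiplier (gain minus accumulated inhibition) exceeds 1, so the gain a
load needs grows linearly with load. The probe readout compares the probed
unit's end-of-delay activation (plus Gaussian decision noise) against a
fixed criterion of 0.5. The decision noise SD (0.416) sets the accuracy
ceiling near the 87% operating point reported for humans in this paradigm;
the criterion was calibrated once against the noise-free retained/baseline
activations (1 versus 0) and is symmetric, so hit and correct-rejection
ceilings match.

Correct/incorrect feedback is delivered as reward 1/0; the boost condition
label is the load cue. The learned policy buys just enough gain per load,
so accuracy is approximately flat across loads while boost rises — and
because accuracy is flat, surprise (mean absolute prediction error) and
the value expectation (the average of the two modules' expectations) are
flat too. The boost cost rate is deliberately small (0.01 per boost unit)
so that the cost component does not impose a detectable negative trend on
the value regressor; what pins low-load boost down is the cost *gradient*
under a sharp selection temperature, not the cost's magnitude.

Accuracy flatness in this design has an irreducible ~1–2 percentage-point
residual: early in each session the optimistic prior forces the agent to
sample sub-threshold boost levels, and those exploratory trials score at
chance at high loads. The same residual would be present in any
within-session learner; with 15 simulated participants the load ANOVA and
the surprise/value trend tests are usually, but not on every random seed,
non-significant.

### Foraging

Sixteen contexts ("patches") each hold eight two-armed bandits; a compound
cue proposes one bandit from one patch, and the agent either engages it or
forages — pays a waiting cost and draws a different bandit from the same
patch, up to 20 consecutive times. Patch means rise evenly from 4 to 7
(optimal-arm reward); the suboptimal arm sits a fixed margin of 2 below.
Each decision is a diffusion run with `δv` = (learned value of the
proposed bandit) − (learned forage value of the patch), a start-point bias
toward "engage" (the human default), and a 2000-cycle deadline after which
the trial aborts unrewarded.

Two design choices matter for the value/difficulty structure:

* **Within-patch heterogeneity peaks at intermediate patch value.** Bandit
  values are placed by stratified-uniform draws (one draw per simulated
  participant) in `mean ± spread`, with the spread rising from 0.5 to 3.5
  across the lower half of the patch-quality range and falling back to 0.5
  across the upper half. Poor and rich patches are therefore internally
  homogeneous — the engage/forage comparison is unambiguous — while
  mid-value patches mix bandits above and below the forage value, creating
  near-ties. This is the same logic by which foraging fMRI designs cross
  offer value with choice difficulty: difficulty is maximal at
  intermediate foraging values by construction of the offer set.
* **Forage value is learned from realised foraging returns** (final reward
  minus the forage costs incurred), initialised at the learned patch mean
  minus one forage cost. Because the agent forages selectively past bad
  bandits, realised returns embed the option value of choosing when to
  stop.

The boost condition label is again the onset difficulty class
`|δv|`, binned on a fixed grid. Hard classes face near-certain timeout
unless boosted (base boundary 140 → zero-drift mean first passage ≫
deadline), so their learned boost is high; easy classes buy almost
nothing and pay the linear cost, so theirs is low. Binned by per-trial
forage value (12 quantile bins), the boost traces the inverted-U of the
heterogeneity profile; binned by difficulty, it rises monotonically. The
trial-level value signal recorded for composites is the offer-set value —
the mean of the engage and forage values at cue onset — which is the
standard cue-evoked value regressor; the boost module's net-value
expectation is kept in a separate column (`state_value`).

## Analysis conventions

* Polynomial comparisons use `AIC = n log(RSS/n) + 2k` with `k` counting
  the coefficients plus the noise variance; Akaike weights are
  `exp(-Δ/2)` normalised. AIC differences under this convention equal
  those of the full Gaussian log-likelihood, which the tests verify
  against `stats::AIC`. AICc is available as a toggle since the fits have
  8–16 points.
* Linear trends are tested as one-sample t tests on per-participant
  regression slopes (df = participants − 1).
* The load effect on accuracy uses the standard one-way repeated-measures
  decomposition, `aov(accuracy ~ load + Error(participant))`, reporting
  its own degrees of freedom `(3, (n-1)·3)`; a zero between-load sum of
  squares is reported as F = 0.
* Group curves are means of within-participant bin means; fits are run on
  the group curve by default, per-participant tables are returned
  alongside.

## Scales, seeds, reproducibility

Every simulated participant `p` runs under seed `base_seed + p`; a
(config, base seed) pair fully determines every trial record, and
`run_experiment()` writes a manifest with the resolved configuration,
seeds and per-file checksums so a run can be reproduced from its artifacts
alone. The package's documented analysis scales are 100 participants × 36
reps per type for the speeded task, the full 15 × 360 design for working
memory, and 40 participants × 6 blocks for foraging; these keep each
experiment's simulation in the minutes range on one core while leaving the
group-level statistics stable. The full printed designs (200 × 54, 15 ×
360, 40 × 18) are the configuration defaults.

## Known limitations

* The simulator reproduces qualitative activity *profiles*, not BOLD
  amplitudes; all signals are in model units.
* The working-memory boost trend's t statistic depends on how consistent
  the learned policies are across participants; within-session learning
  noise bounds it well below what a converged policy would produce.
* The cRNN has no phonological similarity structure or serial-position
  effects; words are interchangeable units.
* Exact parameter values of the antecedent agent literature were not
  available; all defaults are this package's own calibration of the
  model into its intended operating regime, and every one of them is
  exposed in the configuration.
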