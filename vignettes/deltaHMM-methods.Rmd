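---
title: "deltaHMM: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltaHMM: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaHMM)
```

## The modelling problem

A replicated expression time course gives, for each of G features (genes,
transcripts, probes), R replicate measurements at T ordered time points in
Z biological conditions. G is in the thousands; T and R are small (T = 3–9,
R = 2–3 are typical). We want the features whose temporal behaviour is
attributable to a treatment: changing over time in a treated condition
while flat in the control. The two obstacles are the tiny per-feature
sample size and the absence of any principled expression-level threshold.

`deltaHMM` deals with both by (i) modelling expression *changes* between
consecutive time points instead of levels, (ii) pooling every feature of
every condition as an independent observation sequence of one shared
two-state hidden Markov model, and (iii) making the change/no-change call
through decoded hidden states rather than a numeric cut-off.

## Preprocessing

Each condition is rearranged into a 3-D array (features × replicates ×
time). Differencing consecutive time points (`delta_transform()`) removes
each feature's baseline offset — two profiles with the same shape at
different absolute levels become identical — and shortens the time axis to
T − 1. Replicates may be kept as an R-dimensional observation vector or
summarized to their per-time mean or median (`summarize_replicates()`);
with unequal replicate counts across conditions the loader forces the mean
summary, because the emission dimension must be common to all sequences.

Missing values are rejected, never imputed: silently filling them would
distort the difference statistics the whole method feeds on.

Before fitting, the feature axis is shuffled (`shuffle_features()`, seed
1729 by default) so that any ordering structure in the input table cannot
bias the estimation; the same permutation is applied to every condition —
a feature's sequences must stay aligned across conditions for the later
path comparison — and the inverse permutation is retained so all reports
use the original order. Shuffling changes nothing about the fitted model's
stationary behaviour; it is cheap insurance against order effects.

## The hidden Markov model

Two hidden states: `N` (no relevant change, the null) and `C` (relevant
change, up **or** down — the sign lives in the observation, not the
state). Each state emits the R-vector of replicate differences at one time
step from a multivariate normal. Two states are deliberately minimal:
separate up/down states would add parameters without adding selective
power, since the decoded question is only "did anything happen here?".

Design choices a reader should know:

* **Zero emission means.** Differenced data are centred at zero: most
  steps carry no change in either direction, and real changes are
  symmetric in sign. The means are therefore constrained to the zero
  vector by default (`em_config(zero_mean = )` frees them), halving the
  emission parameters — valuable when R is small. When freed on simulated
  data they are re-estimated within a few standard errors of zero.
* **Covariance structure.** Full R × R per state by default (replicates
  can be correlated in real data), `"diagonal"` available. Covariances are
  symmetrized each M-step, their eigenvalues floored at `var_floor`
  (1e-8) to stop collapse on constant features, and a ridge (1e-6) is
  added if a Cholesky factorization ever fails.
* **State identifiability.** EM does not label states. After fitting, the
  state with the larger covariance trace is called `C`: "change" is by
  definition the wider-dispersion regime.
* **Initialization.** Uniform initial distribution, transition matrix
  [[0.9, 0.1], [0.1, 0.9]], state variances at 0.25× and 2× the pooled
  delta variance. Restarts (default 3) jitter these with seeded noise and
  the best final log-likelihood wins, guarding against local optima at
  trivial cost.
* **Convergence.** Relative change in total log-likelihood below 1e-6 or
  500 iterations. The trace is recorded and must be non-decreasing — the
  test suite asserts this on every fit it makes.
* **Numerics.** Forward–backward uses per-step scaling plus a per-step
  max-shift of the log emission densities, so extreme observations (log
  densities far below the exp underflow point) remain finite; all path
  scoring in Viterbi is in log space.

The fit pools the sequences of *all* conditions, control included: the
model describes what changes look like, not where they happen, and more
sequences mean tighter estimates. `em_config(conditions = )` restricts the
pool when a user has reason to.

## Decoding and selection

Each feature's path over {N, C} is decoded per condition with the Viterbi
algorithm. Exact ties are broken toward `N` at every dynamic-programming
step, so perfect ambiguity can never create a selection — the conservative
direction for a feature selector.

With a control condition, the default ("whole-path") rule is: relevant ⇔
the control path is entirely `N` and at least one treated condition's path
contains a `C`. Features whose control changes are excluded outright
(reason `control-changes`): their case-group changes cannot be attributed
to the treatment. A `per-step` mode is provided in which a case `C` counts
only when the control is simultaneously `N` at that step and the control
path need not be globally flat; it trades attributability for sensitivity
on noisy controls. Without a control, flat features are discarded and
everything else kept.

There is deliberately no significance threshold anywhere: the state
variances estimated from the data determine what counts as a change.
A consequence worth knowing: a feature with small but persistent drift can
be selected if the fitted `C` state is narrow — the scores, not a p-value,
express how strong the signal is.

## Scores and ranking

Three scores are computed for every relevant feature, summing over all Z
conditions (the control contributes zero changes by construction but does
contribute to the magnitude and replicate sums):

1. `n_changes` — number of decoded `C` states across conditions and steps;
2. `magnitude` — Σ |Δ| over conditions, steps and replicates;
3. `replicate_score` — Σ |g(t, 1) − g(t, r)| over conditions, all T time
   points and replicates r ≥ 2, on the *raw* (pre-difference) values.
   Despite being a sum of disagreements, it is a quality score: smaller is
   better, and it is 0 exactly when replicates 2..R duplicate replicate 1
   (or R = 1, e.g. after summarization).

No canonical combination of the three into a single number exists, so the
default ranking is lexicographic — `n_changes` descending, `magnitude`
descending, `replicate_score` ascending, feature id as the final
deterministic tie-break — and per-score rank columns are emitted so users
can re-rank by any single criterion. Ranks are always 1..n with no gaps.

## The synthetic-data generator

`simulate_dataset()` builds a two-condition time course with known ground
truth at the scale of a typical RNA-seq validation: 10,000 transcripts, 6
time points, 3 replicates, 10% of case-group features perturbed, state
standard deviations 1.0 (`C`) and 0.2 (`N`). Mechanism:

* Control features, and unperturbed case features, carry the all-`N` path.
* Each perturbed case feature draws its path from a persistent two-state
  chain (transition [[0.9, 0.1], [0.1, 0.9]], initial distribution
  (0.9, 0.1)), rejected until it contains at least one `C`. The
  null-biased initial distribution matches the rare-change setting the 10%
  prior encodes: most perturbed features show one or few change episodes
  rather than changing at half of all steps.
* At each step every replicate's difference is drawn independently from
  the state's Gaussian — i.e. the data are generated from the emission
  model itself — then cumulatively summed from a per-feature uniform
  [2, 12] baseline (a log-expression-like range; the baseline is removed
  again by differencing and exists only to make fixtures realistic).
* White measurement noise (sd 0.1, configurable) is added to every
  replicate/time-point value. Observed differences therefore have sd
  √(sd_state² + 2·0.1²) ≈ 0.245 / 1.010 — the tests take this inflation
  into account when asserting parameter recovery within ±0.05.

What the generator does **not** emulate: count noise and mean–variance
coupling of RNA-seq, probe effects of microarrays, library-size or batch
artefacts, correlated replicates, or genes co-regulated in modules
(features are generated independently). Passing the simulation benchmark
therefore demonstrates the estimator, decoder and selection logic are
correct under the stated model, not that the model is adequate for any
particular real dataset — on real data the input must already be
normalized, and replicate correlation is absorbed by the full covariance.

On this design the full pipeline reaches feature-level sensitivity around
0.92 and precision above 0.99 (averaged over seeds; the acceptance script
recomputes both). Sensitivity is bounded away from 1 for a structural
reason: a perturbed feature whose only change-step draw happens to be
small is indistinguishable from noise, and a control false positive
excludes an otherwise detected feature.

## Problem sizes in the test suite

Unit tests run on small instances (G ≤ 40, T ≤ 10) where exhaustive
enumeration over all 2^(T−1) paths is feasible — every Viterbi and
forward result is checked against that oracle. EM behaviour (monotone
likelihood, simplex preservation) is asserted over 100 random small
datasets, and the recovery benchmark runs the generator at its full
default size, which completes in a few seconds per seed thanks to the
vectorized forward–backward over all pooled sequences.

## Known limitations

* Time points are treated as equally informative regardless of spacing;
  the chain has no notion of elapsed time between measurements.
* A single HMM is shared by all features; genes with idiosyncratic noise
  scales are judged against the global variance estimates.
* Selection is binary per feature. Borderline features are visible only
  through their scores, not through any uncertainty measure on the path.
* The replicate-quality score uses replicate 1 as the reference, so it is
  not symmetric under replicate relabelling; it is a tie-breaking
  heuristic, not a test statistic.
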