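# deltaHMM

Feature selection and ranking for replicated gene-expression time courses
with a two-state Gaussian hidden Markov model.

## The problem

Time-course transcriptomics experiments routinely measure thousands of
genes at a handful of time points with two or three biological replicates.
Per-time-point differential-expression tests throw away the temporal
structure, and most time-series models cannot be estimated from so few
samples. `deltaHMM` addresses both issues for case/control (or
single-condition) longitudinal designs: it identifies the genes whose
expression *changes over time* in a treated condition while remaining flat
in the control, and ranks them — without any hard expression-level cut-off.

## The model

For each condition the normalized expression matrix is rearranged into a
3-D array (features × replicates × time points), then reduced to
consecutive-time differences

```
Δg(t, r) = g(t+1, r) − g(t, r),    t = 1 … T−1,
```

which removes each gene's baseline offset: profiles that differ only by a
constant shift become identical. The sequence of difference vectors
(dimension R = number of replicates) of each feature is modelled by a
hidden Markov model with two states:

* **N** — no relevant change (the null state; small emission dispersion),
* **C** — relevant change, up or down (large emission dispersion),

each emitting an R-dimensional multivariate normal with mean **0** (the
model sees changes, not levels). Every feature of every condition is an
independent observation sequence, so the EM (Baum–Welch) fit pools
features × conditions sequences — this rearrangement is what overcomes the
few-samples limitation. After fitting, each feature's state path is decoded
per condition with the Viterbi algorithm and compared across conditions:

* with a control: a feature is **relevant** iff its control path is all-N
  and at least one treated condition's path contains a C;
* without a control: any feature whose path contains a C is kept.

Relevant features are ranked by three scores: the number of decoded
changes `#Ch` (more is better), the total magnitude of change
`‖Δ‖ = Σ_z Σ_t Σ_r |Δg_z(t, r)|` (more is better), and a replicate-quality
score `scoreR = Σ_z Σ_t Σ_{r≥2} |g_z(t, 1) − g_z(t, r)|` (less is better —
consistent replicates win).

## Worked example

```r
library(deltaHMM)

sim <- simulate_dataset(simulation_config(n_features = 1000, seed = 42))
cfg <- run_config(design = sim$design, em = em_config(seed = 42))
res <- run_pipeline(cfg, tensors = sim$tensors)

res$fit
#> EM fit over 2000 sequences: 14 iterations (converged), final log-likelihood -2301.9152 (restart 1)
#> Two-state Gaussian HMM (emission dimension 3)
#>   initial:    N=0.9838 C=0.0162
#>   transition rows:  N -> (0.9911, 0.008875)   C -> (0.06777, 0.9322)
#>   per-state sd (mean diag): N=0.2455 C=1.036

head(res$ranked[, 1:7])
#>   feature_id rank n_changes magnitude replicate_score path_control path_case
#> 1 gene_00068    1         5  21.43607        25.97505        NNNNN     CCCCC
#> 2 gene_00025    2         5  19.56831        21.07088        NNNNN     CCCCC
#> 3 gene_00021    3         5  17.89044        49.26008        NNNNN     CCCCC
#> ...

ev <- evaluate_detection(res$selection$feature_id[res$selection$relevant],
                         sim$truth)
#> sensitivity 0.950  precision 1.000
```

The fitted per-state standard deviations (0.25 / 1.04) bracket the
generating values (0.2 / 1.0, inflated by the replicate measurement
noise), the decoded case paths of top-ranked genes change at every step
while their control paths are flat, and 95 of the 100 truly perturbed
genes are recovered with no false positives at this size.

For real data, `load_expression()` reads a TSV/CSV matrix (rows =
features, first column = identifiers) plus a sample→(condition, time,
replicate) column map; `inst/scripts/deltahmm.R` exposes the same pipeline
as a command line with `simulate`, `run` and `evaluate` subcommands.

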