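---
title: "Unsupervised early warning for inspection batches: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised early warning for inspection batches: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrws)
```

## The screening problem

A food-inspection batch is a matrix `X ∈ R^{n×m}`: n tested samples, m
numeric laboratory indicators, each indicator carrying a legal bound of one
of three kinds — a minimum content requirement (protein, fat, nonfat milk
solids), a maximum contaminant limit (lactose, aflatoxin M1) or a closed
interval (acidity). Samples violating any bound are *unqualified*; in
routine sterilized-milk surveillance they are rare, on the order of 2% of a
batch. The package treats risk screening as unsupervised anomaly detection:
learn the shape of the dominant in-specification distribution and score
each sample by how badly it fits. No risk labels are used anywhere in
training; the qualification labels enter only for threshold discovery and
evaluation.

Two assumptions underlie this framing:

* the qualified majority is well-concentrated, so a low-capacity model fit
  to the whole batch is effectively a model of the qualified distribution;
* risky samples deviate from that distribution in the measured indicators
  (a hazard invisible to all six indicators is invisible to the screen).

## Direction-aware normalization

Indicators live on incommensurable scales (acidity ~12 °T, aflatoxin M1
~0.3 µg/kg), so Euclidean reconstruction error on raw values would be
dominated by the large-magnitude columns — the preprocessing ablation
(`run_preprocessing_ablation()`) demonstrates exactly this failure. The
min-max transform additionally aligns risk direction. Per column, with
batch statistics `(min_j, max_j, mean_j)`:

* maximum-limit: `x* = (x − min)/(max − min)` — higher reading, higher
  risk, mapped to [0, 1];
* minimum-limit: `x* = 1 − (x − min)/(max − min)` — the direction is
  reversed so that, again, higher normalized value means higher risk;
* interval: `x* = (x − mean)/(max − min)` — a signed, centred deviation in
  [−1, 1].

The reversal is attached to the *minimum-limit* set: for those indicators a
higher raw reading means lower risk, and the contract "after normalization,
higher value = higher risk" forces the `1 − minmax` branch onto them. For
interval indicators no single direction exists; the default keeps the
signed centred form, and `interval_absolute = TRUE` substitutes
`|x − mean|/(max − min)` so that deviation to either side raises the value.
We default to the signed form for fidelity to the centred convention;
the absolute form is arguably the better risk index and is one switch away.

Statistics are computed on the batch being screened (transductive), which
matches single-batch usage; `normalize_batch(stats = )` freezes a
reference batch's statistics for scoring new samples consistently.
A constant column makes the transform undefined and is an error, not a
silent zero. Missing cells are rejected — qualification and scoring need
complete rows — rather than imputed; imputation is a preprocessing decision
we deliberately leave to the caller.

## The auto-encoder scorer

The scorer is a symmetric fully connected auto-encoder: encoder layers
`y = σ(Wx + b)` down to a low-dimensional code, mirrored decoder
`z = σ(W̃y + b̃)`, objective

```
J = Σ_i ‖z_i − x_i‖² + λ‖W‖_F
```

with the penalty on the encoder weights only (Frobenius norm, not squared),
minimized by full-batch Adam. The per-sample risk score is
`k_i = ‖z_i − x_i‖²`. With the overwhelming majority of samples qualified,
the capacity bottleneck (6→4→2) forces the network to spend its capacity on
the bulk; out-of-specification samples are reconstructed poorly and score
high.

The denoising variant (DAE, `noise_sd > 0`) corrupts the training inputs
afresh every epoch with `x̂ = x + ε`, `ε ~ N(0, noise_sd²)` per coordinate,
while the error is measured against the clean input. Corruption is a
training-time device only: scoring always uses clean inputs, for AE and DAE
alike, so the two scorers are directly comparable.

### Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `hidden` | `c(4, 2)` | encoder widths; 6-4-2-4-6 on six indicators — a mild bottleneck; deeper nets buy nothing at m = 6 |
| `activation` | sigmoid | bounded activations suit the unit-scaled inputs; `linear` exposes the PCA limit used in testing |
| `lambda` | 0.1 | weight-norm penalty in [0, 1]; mild shrinkage, negligible against the error term at n ≈ 2000 but stabilizing on small batches |
| `epochs` | 1000 | see below |
| `learning_rate` | 5e-3 | see below |
| `batch_size` | n (full batch) | full-batch training makes AE scores exactly invariant to row order |
| `noise_sd` | 0 (AE); 0.3 for the DAE scorer | corruption SD on the normalized scale, where columns span about one unit |
| `seed` | required | initialization (and DAE corruption) stream |

The optimizer settings deserve a note. With Adam at learning rate 1e-3 and
500 epochs the objective on a 2158×6 batch is still falling steeply and the
scorer visibly under-ranks the planted failures; at 5e-3/1000 the objective
has plateaued and another doubling of epochs only adds variance (the model
begins to reconstruct the anomalies too). The defaults are therefore
5e-3/1000 — converged but not overtrained, and still about two seconds of
CPU per fit.

Training is transductive (fit on the batch being screened, no split), which
is the intended usage for batch surveillance; for streaming use, fit once
on a reference batch, serialize with `write_risk_ae()` (config, weights and
normalization statistics in one JSON container) and score new CSVs against
it.

### Numerical choices

* Initialization: uniform Glorot draws scaled by fan-in/fan-out, biases
  zero, under `set.seed(seed)`; `epochs = 0` returns exactly this state.
* The Frobenius-norm penalty has gradient `λ·W/‖W‖_F`, undefined at
  `‖W‖ = 0`; that point is unreachable from a random initialization and the
  gradient is simply skipped there.
* A non-finite epoch loss aborts with a diagnostic rather than returning
  garbage parameters.
* Score ties (and rank ties generally) are broken by the original row
  index, ascending, everywhere — ranking, thresholds, top-k confusion —
  so every downstream quantity is reproducible.

## Rank thresholds and the four levels

With `U` unqualified samples, the descending score ranking yields `n*`, the
smallest n such that the top-n contains every failure, and two cutoffs: the
scores at ranks `U` and `n*`. Unqualified samples are always level 3 (high
risk). Qualified samples are banded lower-edge-inclusively:

* level 0 (safe): `score < r(n*)`
* level 1 (low): `r(n*) ≤ score < r(U)`
* level 2 (medium): `score ≥ r(U)`

i.e. inside the top-U band → medium, inside the top-n* band but outside
top-U → low. Under a perfect ranking `n* = U`, the two cutoffs coincide and
the low band is empty. The inclusive lower edge is a convention — the band
definition by ranks leaves the knife-edge case open — chosen so that a
qualified sample tied with the cutoff score is escalated, not waved
through (conservative for a safety screen). New batches are banded against
frozen thresholds from a reference batch.

## What the synthetic generator emulates — and what it does not

No inspection archive is publicly deposited, so validation runs on
synthetic batches built to the same regime: n = 2158 samples, 41 planted
failures (contamination 41/2158 ≈ 1.9%), inspection dates uniform over
November 2013 – October 2021. In-specification values are Gaussians
truncated inside the legal limits, centred near routine readings
(lactose 1.75 ± 0.05 g/100 g, acidity 12.1 ± 0.20 °T, NMS 8.8 ± 0.15,
fat 4.2 ± 0.15, protein 3.4 ± 0.08 g/100 g, AM1 0.3 ± 0.08 µg/kg — means
taken from published example rows of such testing, spreads chosen as
plausible assay variation). Each failure violates exactly one indicator,
pushed past its limit by a uniform 5–30% of the limit's magnitude (interval
indicators pick a side at random). The planted count is exact
(`round(n × contamination)`), and generated labels agree exactly with
`qualify()` by construction. Truncated draws use the inverse-CDF form, so a
fixed seed reproduces the batch byte-for-byte.

What this does *not* emulate: correlated indicators (real milk chemistry
ties protein, fat and solids together), temporal drift across eight years
of testing, heavy-tailed assay errors, censored readings at detection
limits, multi-indicator failures, and fraud-like adversarial patterns.
Passing tests on this generator therefore demonstrate that the pipeline
recovers planted, single-indicator excursions under clean Gaussian bulk —
a necessary sanity property, not a field-performance claim.

The noise experiment (`inject_noise()`, `run_noise_experiment()`) corrupts
`ceil(fraction × n)` distinct samples, one uniformly chosen indicator each,
with N(0, 0.3²) on the normalized scale — emulating mis-recorded or
partially missing readings. Noise is applied on the normalized scale
because that is what the models consume; 0.3 is roughly one column-spread.
Under the top-k rule, corrupted qualified samples are *genuinely*
anomalous, so absolute detection of the planted failures drops for every
scorer as the fraction grows; the relevant comparison is between scorers,
where denoising training never does worse and occasionally recovers more.

## Evaluation conventions

The confusion rule is top-k: predict unsafe for the k highest scores, with
k defaulting to the ground-truth failure count. (A score-threshold rule is
implicit in the frozen-threshold classification path.) The metrics are
precision, fault detection rate TP/(TP+FN), false alarm rate FP/(FP+TN),
accuracy, and the pairwise AUC — the probability that a random unsafe
sample outscores a random safe one, ties counting ½, computed from ranks.
Zero-denominator metrics return `NA` with a warning, never a silent 0.
`run_benchmark()` reports per-scorer means over a seed list (the
mean-over-five-initializations convention); runtime is recorded as
information only and never asserted.

The level t-tests resample 100 scores with replacement from each level's
pool and compare the pairs {0,3}, {1,3}, {2,3}, {0,1}, {1,2} with Welch's
two-sided test (Student's pooled-variance optional). Raw p-values are
reported, without multiplicity correction, alongside the t statistic.

## Problem sizes used in the tests

The unit suites run on small batches (tens to a few hundred samples, 100–300
epochs) against brute-force oracles: per-element normalization recomputation,
rule-by-rule qualification, all-pairs AUC, exhaustive top-k tabulation, a
hand-evaluated 2-1-2 forward pass, and the rank-1 PCA reconstruction error
for the linear bottleneck limit. The end-to-end checks run at the full
emulated regime (2158 × 6, five seeds): the default AE recovers ≥ 90% of
planted failures with AUC above 0.99, and the denoising variant matches or
beats the vanilla one under 10–15% corruption on at least four of five
seeds. Whole-suite runtime is a couple of minutes on one CPU.

## Known limitations

* Transductive scoring means a batch's own anomalies influence the
  normalization statistics and the fitted weights; with gross contamination
  (tens of percent) the bulk assumption collapses.
* Threshold discovery needs at least one unqualified sample in the
  reference batch; a spotless batch has no banding (and `find_thresholds()`
  says so rather than inventing cutoffs).
* The sigmoid output layer cannot express values outside (0, 1); for the
  signed interval column this inflates the error floor of every sample
  symmetrically. It does not hurt ranking in practice, but a linear output
  layer would be the first thing to try if interval indicators ever
  dominate m.
* Scores are comparable only within a normalization frame; mixing scores
  across batches normalized independently is meaningless. Freeze statistics
  and thresholds for cross-batch work.
* The DAE's training stream couples corruption draws to row order, so
  unlike the full-batch AE its fitted weights are not exactly invariant to
  row permutation (scores typically agree to optimizer noise).
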