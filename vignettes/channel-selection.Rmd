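---
title: "Channel selection for P300 classification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel selection for P300 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpselect)
```

## The estimation problem

An oddball BMI classifies single EEG epochs as target (P300 present) or
nontarget.  Two user-specific quantities must be chosen at calibration
time: the subset of electrodes that carries discriminative information,
and the shrinkage strength of the classifier, which compensates for the
poor conditioning of a scatter matrix estimated from a few hundred
trials in up to 1600 feature dimensions.  `erpselect` estimates both
jointly by a stochastic wrapper search: candidate configurations are
scored by the cross-validated performance of the classifier they
parameterize, so the selection criterion is exactly the quantity the
final system is judged on.

## Classifier

Feature vectors `z` (25 decimated samples per selected channel,
concatenated in channel order) are projected on
`w = (S_W + λI)^{-1}(m₁ − m₋₁)`, where `S_W` is the summed-outer-product
within-class scatter of the training set and `m₁, m₋₁` the class means.
The system is solved by Cholesky factorization, never by explicit
inversion; for `λ = 0` a singular scatter raises an informative
rank-deficiency error rather than a silent pseudo-inverse.  A sample's
score is the inner product `s(z) = ⟨w, z⟩`; classification assigns the
class `j` minimizing `(s − μ_j)² / σ_j²` with `μ_j, σ_j²` the mean and
variance of the training scores of class `j` — a one-dimensional
Mahalanobis rule.  Two readings of the printed rule are possible
(denominator as variance or as squared variance); the standard
Mahalanobis reading (variance) is implemented, isolated in one internal
function (`classify_scores`).  Exact ties break to nontarget, the
conservative choice for an oddball interface where targets are the rare
class.  Class variances use the unbiased `ℓ_j − 1` denominator; at the
sample sizes involved the difference is immaterial.

## Search

One real coordinate `a ∈ [−1, 1]` encodes `λ = 10^{5a}` — exponential,
so equal steps in `a` explore orders of magnitude of shrinkage — and 64
bits encode channel inclusion.  Updates follow the classic inertia
formulation with per-component uniform perturbations; binary coordinates
are resampled through the logistic transfer `S(v)`.  Defaults mirror the
standard configuration: 30 particles, up to 100 iterations or fitness 1,
`c1 = c2 = 2`, real inertia 0.9 → 0.4 linear, binary inertia 1, velocity
clamps 0.1 (real) and 6 (binary).  Infeasible positions (real coordinate
out of range, or no channel selected) are handled by an invisible wall:
they are never evaluated and never update bests, but their particles
keep moving and typically return.

Choices the formulation leaves open, fixed as follows:

* **Initial velocities are zero**, so the first move is driven purely by
  the cognitive/social pull; together with a single seed this makes runs
  bit-reproducible.
* **Perturbations are drawn per component**, the richer and more common
  variant.
* **Bests update on strict improvement**; ties keep the earlier
  position, again for reproducibility.
* **Global (star) topology** for the swarm best.
* **The real coordinate is not clipped**; the wall alone handles
  excursions.
* **Velocity clamping applies to the summed update**, not to individual
  terms.
* **Revisited positions are served from a cache.**  The fitness is a
  deterministic function of the position within a run (folds are
  frozen), so caching has no semantic effect, only a large wall-clock
  one.

## Fitness

`F = w₁·sqrt(TP/Ps × TN/Ns) + w₂·(N_Ch − n + 1)/N_Ch` with
`w₁ + w₂ = 1`.  The geometric mean punishes unbalanced classifiers —
with 20% targets a trivial always-nontarget rule scores 0, not 0.8 — and
the sparsity term equals 1 at a single channel, so only a perfect
one-channel classifier can reach `F = 1`.  Rates come from 10-fold
stratified cross-validation (equal class ratio per fold up to one
trial), with confusion counts pooled across folds before the rates are
computed: with only ~18 targets per fold, per-fold rates would be too
granular.  The fold assignment is drawn once per run from its own seed
and frozen, which keeps the optimization landscape stationary and the
fitness cacheable.  Stratification is by class only; direction and
session stratification belongs to the outer train/test split.

Internally each particle evaluation reuses per-fold, per-class Gram
matrices of the full montage, precomputed once per run; a channel
subset's scatter is then a submatrix plus two rank-1 corrections.  This
is algebraically identical to refitting fold by fold (a test asserts
exact equality with the reference implementation `cv_confusion`) and is
what makes a 3000-evaluation wrapper search affordable in seconds to
minutes.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the statistical structure the method assumes:
6 directions × 2 sessions × 150 trials, exactly 20% targets per session
(deterministic count, seeded positions — matching the fixed design and
making counts testable), epochs of [−100, 1000) ms at 250 Hz, a
Gaussian-bump P300 surrogate (peak 350 ms, width 120 ms, default 5 µV,
optional latency jitter) added on target trials on a configurable
informative subset, and Gaussian noise, white or spectrally shaped to
1/f^α, independent across trials and channels.  The 250 Hz default
follows from the feature specification: 25 features per channel over
[0, 1000) ms after 10:1 block averaging.  Half-open windows make sample
counts exact; closed intervals would double-count boundary samples.

Not modeled: volume conduction and spatial noise covariance (channels
are independent by default), ocular/muscular artifacts, inter-trial
dependence, continuous raw recordings, realistic P300 morphology beyond
a bump.  Passing tests therefore demonstrate that the estimator recovers
planted structure under its own assumptions — not performance on real
EEG, where channel correlations both help (noise cancellation) and hurt
(redundancy).

## Preprocessing numerics

Filtering is per epoch (epoch first, then filter), with edge effects at
the 0.1 Hz corner accepted as a property of short epochs.  The
zero-phase realization applies the 3rd-order Butterworth forward and
backward (effective order 6) with odd-reflection padding of 18 samples
and step-matched initial conditions — the state that makes a constant
input pass through unchanged.  During development this implementation
was verified to agree with an independent reference implementation of
forward–backward filtering to ~1e-7.  Decimation uses strict
non-overlapping block means and refuses partial blocks.

## Evaluation harness

`stratified_split` halves the data preserving every (class, direction,
session) stratum, alternating the odd-stratum remainder so 1800 trials
split exactly 900/900.  The search must see the training half only; the
decoded configuration is refitted on the full training half and judged
on the untouched test half.  Score averaging fabricates an `M`-trial
from the mean discriminant score of `M` same-class test trials drawn
with replacement from a seeded master list — built once and reused
across all configurations so comparisons combine exactly the same
information.  The averaged score is classified with the single-trial
training statistics `μ_j, σ_j²`: no averaged-trial training set exists,
and averaging `M` i.i.d. scores shrinks their spread, moving correct
classifications toward their class mean — which is why accuracy grows
with `M`.  Pareto extraction over the visited (channel count, accuracy)
pairs and selection-frequency maps across repeated runs summarize the
trade-off structure of a search.

## Problem sizes used by the shipped tests

The test suite exercises the full method at desk scale, chosen as the
smallest designs in which the effects of interest are comfortably
resolved:

* Parameter recovery: five seeded runs on 600 trials / 32 channels with
  the P300 planted on 4 channels (amplitude 15 µV against 10 µV 1/f
  noise — strong but realistic for an averaged-free single-trial
  paradigm), plus one full 64-channel run on 900 trials, all at the
  standard 30 × 100 swarm configuration with balanced (case7) weights.
  The 32-channel montage for the reduced runs is deliberate: the
  sparsity term is normalized by the montage size, and on a very small
  montage its per-channel step exceeds any attainable accuracy gain, so
  the optimum degenerates to one channel.  The 64-channel run uses 900
  trials because with fewer the ~3 targets per CV fold make the wrapper
  fit fold noise.
* Weight sweep: the eight presets on one 300-trial, 16-channel dataset,
  two seeds each at 20 particles × 40 iterations; the median selected
  channel count falls monotonically as the channel weight grows.
* Averaging trend: one 400-trial, 8-channel dataset; geometric-mean
  accuracy is non-decreasing in `M`.

## Known limitations

The wrapper criterion is an in-search CV estimate; the selected
configuration's CV fitness is optimistically biased (winner's curse over
~3000 evaluated configurations) and only the held-out evaluation is
honest.  PSO carries no global-optimality guarantee; distinct seeds can
return different, similarly fit subsets — the selection-frequency map
across seeds is the intended summary.  With heavily weighted sparsity
the method deliberately discards redundant informative channels;
"recovery" of a planted set is then recovery up to redundancy.  The
generator's independence assumptions make multi-channel gains smaller
than in real EEG, where spatial filtering against correlated noise is a
major effect.
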