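---
title: "Trajectory-library decoding: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-library decoding: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mintdecode)
```

## The generative model

The decoder treats the neural state $x_t \in \mathbb{R}^N$ (firing rates in
spikes/s) as drawn uniformly from a finite library of states
$\Omega = \{\bar{x}^c_k : k > \tau\}$, where $c$ indexes behavioral
conditions and $k$ indexes progress through the movement at 1 kHz. Each
state has a *unique, deterministic history*: the state at $k$ was preceded
by the state at $k-1$ on the same trajectory. Binned spike counts
$\bar{s}_{t'}$ (bin width $\Delta$, default 20 ms) are conditionally
independent Poisson given the rates, with per-bin mean equal to the average
of the $\Delta$ per-sample rates times $\Delta/1000$. Each neural state is
paired with a behavioral state $\bar{z}^c_k$ read out by direct
association.

Because each candidate state has exactly one possible history, the log
posterior over $\Omega$ is (up to a constant) a plain sum of per-neuron,
per-bin Poisson log-likelihoods over the trailing window of
$\tau'+1$ bins. Three consequences drive the implementation:

1. **Lookup table.** Each term depends only on (count, rate), so all terms
   are precomputed on a discretized rate axis. Entries are clipped below at
   $\ln 10^{-6}$, and library rates are floored at 1 spike/s before grid
   assignment, so one spurious spike from a near-silent neuron cannot veto
   a state.
2. **Recursion.** Successive bins share all but two terms of the sum, so
   per-bin cost is one table gather per neuron per queried state. Queried
   states are downsampled to $k$ divisible by $\Delta$; the precision lost
   is restored by interpolation (below). The recursive and direct sums are
   required to agree to 1e-9 by the test suite, which checks them against
   each other on random libraries and streams.
3. **Deterministic advance.** Between bin completions the estimate advances
   one index per millisecond along its trajectory with interpolation
   weights frozen, giving 1 kHz output from 20 ms observations.

## Interpolation

The mesh of decodable states is denser than the library: after the argmax,
the decoder maximizes the spike log-likelihood over convex combinations
$(1-\alpha)\lambda^1 + \alpha\lambda^2$ of two candidate rate histories.
The second derivative of that objective in $\alpha$ is
$-\sum s\,\big((\lambda^2-\lambda^1)/\lambda(\alpha)\big)^2 \le 0$, so the
objective is concave and Newton's method is used with the stopping rules:
step smaller than 0.01, saturation at 0 or 1, or 10 iterations.

Refinement proceeds in two stages. *Index refinement* blends the best state
with whichever in-range neighbor one bin-width away has the larger
log-likelihood (at a trajectory end, only the in-range neighbor is
considered). *Condition refinement* selects additional candidates by
log-likelihood under an exclusion policy (different trajectory by default;
optionally a minimum separation along the same trajectory, or a different
library section), index-refines each, optimizes $\alpha$ for every
unordered pair, and keeps the best pair. Behavioral output applies the same
blend weights to the paired behavioral states; circular variables always
blend across the lesser angle between the two phases.

Numerical decisions the source procedure leaves open, decided here:

* **Newton initialization** is $\alpha = 0.5$ with iterates clamped to
  $[0,1]$; concavity makes the start point a matter of speed, not
  correctness.
* **Saturation** is read as *settling at a boundary whose gradient points
  outward* (the constrained optimum). A clamped iterate whose gradient
  points back inside continues iterating; stopping at the first clamp can
  strand the estimate up to ~0.1 from the optimum when the curvature is
  much larger near the optimum than at the start.
* **Degenerate pairs** (identical candidates, or an exactly linear
  objective with equal endpoints) return $\alpha = 0$, i.e. the first
  candidate.
* **Blended means are floored** at the same 1 spike/s (expressed per bin)
  used by the lookup path, so a zero blended rate with a nonzero count
  yields a finite objective; floored terms have zero derivative.

## Learning the library

Single-trial rates are obtained by Gaussian filtering of 1 kHz spike
counts. The kernel is truncated at $\pm 4\sigma$ and renormalized over the
in-range portion near trial boundaries, so a constant-rate stream stays
flat at the edges (the alternative — zero-padding — depresses rates at
both ends of every trajectory). Rates and behavior are extracted in
event-relative windows; with a two-event window, trials are linearly
resampled to the per-condition *median* duration (uniform warping). Only
uniform warping is supported; nonlinear warping is out of scope.

Trial averaging is either the arithmetic mean (Type I) or a rank-1
reconstruction across the trial dimension before averaging (Type II):
trials are soft-normalized and mean-centered using factors computed from
the Type I averages, reshaped to trials × (neurons·samples), projected onto
their first trial-space principal component, un-normalized, and averaged.
Outlier trials — e.g. one neuron briefly wild on one trial — contribute
little to the leading trial-space component, which is the point. Because
the preprocessing already centers the data, the projection is computed by
plain SVD without re-centering across trials; with one trial, or identical
trials, the projection is exactly the identity.

Smoothing across neurons (and, when all trajectory lengths match, across
conditions) soft-normalizes, projects onto the top $D$ principal
components, reverses the normalization, and rectifies at zero.
`"full"` disables a stage. When trajectory lengths differ across
conditions, condition smoothing is skipped with a warning rather than an
error, since the hyperparameter tables that motivate it mark it
inapplicable in exactly that case.

Soft normalization scales each neuron by $1/(\text{rate range} + 5)$; the
5 spikes/s constant follows the convention of the normalization scheme this
procedure descends from, and is configurable
(`training_config(soft_norm_constant=)`).

Circular behavioral variables are stored in radians on $[0, 2\pi)$.
Averaging unwraps each trial along time, aligns trials to a common branch
(each trial shifted by the multiple of $2\pi$ nearest the first trial),
averages, and re-wraps. This is rotation-equivariant and reduces to the
naive mean for non-wrapping traces.

Session-section adaptation learns, per section $d$, an affine correction
$(W^{(d)}\Lambda + I)\bar{X} + b^{(d)}$ of the session-wide rates toward
section-specific estimates, by weighted ridge regression in closed form;
$\Lambda$ is the diagonal soft-normalizer. Regularization applies only to
the deviation from the session-wide rates, so $\lambda \to \infty$ recovers
the session library plus a mean offset, and identity inputs return the
session library. The reference configuration weights a designated task
epoch 4× and uses $\lambda = 100$.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `delta_ms` | 20 | ms | bin width; long enough to cut compute, short relative to rate timescales |
| `window_ms` | 300 | ms | spiking history $(\tau'+1)\Delta$; task-dependent (240–480 in the reference analyses) |
| `sigma_ms` | 25 | ms | filter SD; trade smoothness of rate estimates vs temporal precision |
| `n_candidates` | 2 | — | interpolation candidates; >2 only for task structures with many similar trajectory fragments |
| `rate_floor` | 1 | spikes/s | regularizes against spurious spikes from silent neurons |
| `clip_floor` | ln 1e-6 | — | caps the penalty a single (count, rate) term can contribute |
| `grid_step` | 0.1 | spikes/s | rate-axis resolution of the lookup table |
| `max_count` | 20 | counts/bin | table height; higher observed counts are clamped with a warning |
| `soft_norm_constant` | 5 | spikes/s | keeps low-rate neurons from dominating PCA stages |

The rate axis spans 0 to 1.2× the largest library rate unless
`lambda_max` is given; at the reference grid (0–200 spikes/s by 0.1,
counts 0–20) the table is 2001 × 21.

## What the synthetic data does and does not establish

The maze-style generator produces minimum-jerk reaches to targets on a
ring with trial-to-trial amplitude and duration jitter, rates as a random
affine function of z-scored position/velocity/acceleration rescaled to
target mean/SD (defaults 20 and 8 spikes/s, typical of motor cortical
units and keeping pre-rectification rates essentially non-negative), and
Poisson or gamma-interval spiking (ISI shape 2, rate $2\lambda$, matched
long-run rate, sub-Poisson regularity). Time-varying rates use per-
millisecond Poisson draws (exact for an inhomogeneous Poisson process at
1 kHz) and time-rescaled unit-mean gamma renewals respectively.

The trajectory world generates smooth latent trajectories whose basis
coefficients vary smoothly around a ring of conditions, with a 30%
idiosyncratic per-condition component, softplus rate readout, and linear
behavior readout. The ring structure is deliberate: in real reach data
neighboring conditions have similar trajectories, and a blend of two
neighboring conditions lies near the mesh between them. With fully
independent random conditions every pair of trajectories is roughly
equidistant and the *identity* of the second interpolation candidate is
genuinely ambiguous — a property of that artificial geometry, not of the
decoder. Test trials carry per-millisecond ground truth: exact replays,
uniformly time-dilated replays (±10–20%), and fixed-$\alpha$ blends defined
on per-bin expected counts (matching the interpolation model's affine
blending), with $\alpha$ recovery measured as the provenance weight the
decoder assigns to the second condition.

A green recovery test therefore establishes that the engine identifies
condition, index, and blend weight when the data really were generated
from the mesh (conditionally Poisson, stationary library). It does not
establish performance under model mismatch — non-Poisson variability
beyond the gamma option, rate drift across a session, behavioral
variability off the mesh — nor does it reproduce any empirical decoding
number from recorded datasets; those depend on external data. Thresholds
used by the acceptance tests (condition recovery ≥ 0.90, mean
$|\hat\alpha - \alpha| \le 0.10$) were committed from a pilot run
(`scripts/pilot_recovery.R`, seeds 101–105) before the tests were frozen.

## Other numerical choices

* **Tie-breaking** in the argmax is lexicographic: lowest condition, then
  lowest index. Exact ties occur with duplicated trajectories and in toy
  problems.
* **Counts above the table height** are clamped to `max_count` with a
  warning; overflow behavior is otherwise unspecified upstream.
* **Units.** Rates are spikes/s at 1 kHz sampling everywhere in the
  library; per-bin expected counts appear only inside the likelihood and
  interpolation modules. The bin-mean convention (mean of per-sample rates,
  then × Δ/1000) resolves an upstream ambiguity about whether the bin sum
  is over per-sample or per-bin rates.
* **Rate flooring order.** The 1 spike/s floor is applied *after* bin
  averaging, immediately before grid-index assignment.
* **Trajectory ends.** During deterministic advance the estimate holds at
  the final state rather than wrapping; trajectories are not cyclic in
  general. Acausal boundary estimates freeze interpolation parameters and
  advance/rewind provenance along trajectories, clamped at the ends.
* **Warm-up.** Estimates before a full window has accrued are emitted as
  records flagged invalid rather than omitted, keeping output aligned with
  input length.
* **Condition indices are 1-based** throughout (R convention), including
  logs and serialized provenance.
* **Serialization** uses a plain-text bundle (JSON metadata +
  full-precision CSV matrices) written deterministically, so save → load →
  save is byte-identical. Configs are JSON with unknown keys rejected.

## Known limitations

* Behavior off the library (novel movements far from every trajectory) is
  estimated as the nearest mesh point; there is no outlier flag beyond the
  selected-state log-likelihood, which users should monitor.
* Only pairwise interpolation is supported; simultaneous blends of three or
  more states are not part of the model.
* The observation model is Poisson only; the lookup table isolates the
  distribution so alternatives could be added, but none are provided.
* Non-uniform (nonlinear) time warping and multi-event piecewise alignment
  are out of scope for library learning.
* The decoder loop is pure R; it decodes comfortably faster than real time
  at the scales used in the tests, but no real-time scheduling guarantees
  are made.
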