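---
title: "Methods: burst coincidence, surrogate nulls, and laminar enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst coincidence, surrogate nulls, and laminar enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoconn)
```

# Scope

`neoconn` quantifies corticocortical connectivity in the neonatal cortex
along two independent arms:

1. **Electrophysiology** — multi-unit activity (MUA) from multi-electrode
   slice recordings is reduced to spike trains, burst discharges are
   detected, and pairwise burst *coincidence* and onset *directionality*
   are tested against surrogate nulls; spike-level synchrony in the
   monosynaptic 5–15 ms window is assessed with cross-correlograms (CCGs)
   and joint-ISI-dithered surrogates.
2. **Anatomy** — somata of retrogradely labeled neurons are assigned a
   *normalized cortical depth* between the pial surface (0) and the lower
   subplate boundary (1), mapped to layers (MZ, CP, L5, L6, SP) via
   relative-thickness schemes, and tested for laminar enrichment against
   expected neuron proportions.

Raw recordings and confocal volumes of the kind this pipeline targets are
generally not shareable, so the package ships a synthetic-data generator
with known ground truth; every downstream stage is exercised against that
ground truth.

# Electrophysiology arm

## MUA extraction

Raw extracellular traces (20 kHz) are band-passed 200–5,000 Hz and spikes
are detected at negative crossings of −5·SD, where SD is the sample
standard deviation of a spike-free baseline interval. Choices the band and
threshold do not pin down, and our defaults:

* **Filter realization**: 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero phase, so spike times are not shifted by
  filter delay.
* **Threshold polarity**: negative (extracellular somatic spikes are
  predominantly negative); configurable.
* **Dead time**: 1 ms. A bare threshold detector would report several
  samples per spike; the dead time collapses them. MUA is not sorted into
  units, so the dead time only needs to cover one waveform.
* **Spike time**: the first sample beyond threshold, not the trough —
  simpler, monotone in the threshold, and identical across channels.
* The baseline helper warns when the chosen interval has sample kurtosis
  above 5 (a Gaussian baseline has 3): a heavy-tailed "baseline" usually
  contains spikes and would inflate SD.

## Burst detection and coincidence

A **burst** is a maximal run of at least 3 successive spikes with every
inter-spike interval at most 300 ms (the boundary value is inside the
burst). Burst statistics are occurrence (min⁻¹), duration, spike count,
and an intra-burst rate defined as `(n_spikes − 1) / duration` — the
denominator convention matters only for display.

Two bursts on different electrodes **coincide** when at least one spike of
either lies within the other's interval; because a burst's interval is
spanned by its own spikes this is exactly interval overlap, and we
evaluate it symmetrically. Bursts are matched **one-to-one**, greedily in
time order (earliest available partner wins), so a long burst cannot be
counted against several partners. The **coincidence ratio** divides the
number of matched pairs by the burst count of the electrode with the lower
burst activity; a pair of identical trains therefore has ratio 1.
**Lead/lag** compares the first spikes of matched bursts; exact onset ties
are their own category, never assigned arbitrarily, and the three ratios
sum to 1.

## Jittered surrogate null for coincidence

The null asks: would this much coincidence arise if the two trains shared
only their slow structure? Each surrogate displaces every spike of one
train independently by U(−750, +750) ms — the approximate duration of a
burst — clips to the recording span, re-sorts, re-detects bursts, and
re-matches against the partner's observed bursts. We jitter the train with
the lower burst count (the ratio's denominator train); this is
configurable. The observed ratio is significant when it strictly exceeds
the empirical 99th percentile (inverse-ECDF convention) of the surrogate
ratios.

Two numerical choices deserve emphasis:

* **Surrogate normalization.** Jitter at burst scale fragments bursts: a
  13-spike, 600 ms burst spread over ±750 ms re-detects as one-to-several
  shorter bursts, so the surrogate's own burst count is inflated relative
  to the observed train. If surrogate ratios were normalized by their own
  recomputed burst minimum, the null would sit on a different scale than
  the observed ratio and the flag would fire on independent data an order
  of magnitude too often. Surrogate ratios therefore share the observed
  pair's denominator; detection and matching are still recomputed per
  surrogate. With this convention the false-positive rate on independent
  pairs is at or below the nominal 1% (the discreteness of small counts
  makes the strict-exceedance rule conservative).
* **Power against dense bursts.** When bursts carry many spikes relative
  to the jitter span, fragments survive re-detection and re-pair with the
  partner's bursts, so the surrogate retains part of a genuine coupling
  and the test is conservative for saturated coupling. Coupling detection
  is sharpest when bursts are sparse enough that jittering destroys them
  as detectable events; reported surrogate coincidence ratios near zero in
  real recordings are consistent with that regime.

Directionality inference does not depend on the flag: per-pair lead ratios
are tested against the chance level 0.5 with a Wilcoxon signed-rank test
(stars `*` p < 0.05, `**` p < 0.01).

## CCG analysis and joint-ISI dithering

CCGs histogram target-minus-reference spike-time differences in 1 ms bins
over ±50 ms (both unstated in the source protocol; 1 ms resolves the
5–15 ms question comfortably). Positive lag means the target fires after
the reference. For distinct channels no self-pairs exist; autocorrelation
diagnostics keep them by convention.

The surrogate generator is **joint-ISI dithering**: each surrogate moves
every interior spike within the open interval spanned by its two
neighbours in the original train, so the sum of its two adjacent ISIs —
its position on the anti-diagonal `l + r = const` of the joint-ISI plane —
is conserved exactly, and the train is re-sorted (displacements are capped,
so only near neighbours can swap). The new position is drawn proportional
to the kernel-smoothed empirical joint-ISI density along that
anti-diagonal (2D Gaussian kernel, 5 ms bandwidth), restricted to
displacements of at most 25 ms; with fewer than 50 ISI pairs the density
is too sparse to smooth and sampling falls back to uniform on the capped
segment. First and last spikes never move; spike count is always
preserved. The 25 ms cap destroys only fine timing — the scale of the
monosynaptic question — while leaving rate structure and bursts intact.

An earlier design dithered only alternating spikes so that conservation
held without re-sorting; it was abandoned because freezing half the spikes
correlates each surrogate CCG with the observed one and collapses the
per-bin exceedance far below its nominal level. The simultaneous scheme
calibrates at the nominal rate.

Per-bin significance uses the empirical 99th percentile across surrogate
CCGs (target train dithered, reference fixed). The summary also reports
whether significant bins *cluster* inside the 5–15 ms window: a one-sided
binomial test of the in-window fraction of significant bins against the
window's share of all bins. A genuine monosynaptic delay spread over a few
milliseconds elevates several window bins and makes this cluster test
reject; isolated false positives scattered over the full range do not.

# Anatomy arm

## Surfaces, depth, and layers

Pial and lower-subplate boundary point clouds are fit with full
least-squares quadratics `z = c₀ + c₁x + c₂y + c₃x² + c₄xy + c₅y²` (at
least 6 non-degenerate points; rank-deficient designs are an error). For
each cell the nearest point on the pial surface is found numerically
(BFGS over the lateral coordinates, dense-grid fallback on
non-convergence); the **local thickness** is measured along the ray from
that nearest pial point through the cell until it meets the subplate
surface (a 1-D root find), and the **normalized depth** is the pial
distance divided by the local thickness, clipped to [0, 1] with the
overshoot logged. For a cell inside the cortex the nearest-point direction
is the pial surface normal; for gently curved cortex it agrees with the
vertical to well under the 0.01 depth tolerance used throughout.

Layer assignment uses relative thickness schemes (per area: MZ, CP, L5,
L6, SP). Raw rows are renormalized to sum exactly to 1; cumulative sums
define half-open depth bins `[c₍ₖ₋₁₎, cₖ)` with the last bin closed, so
depth 0 is MZ, depth 1 is SP, and a boundary depth belongs to the deeper
layer. The bundled S2 row contains an L6 value of 0.867 that is an
apparent transcription error (the row would sum to 1.602); the default
scheme substitutes 0.267 and the verbatim value stays loadable via
`layer_scheme("S2", verbatim = TRUE)`.

## Proportions and enrichment

Per-layer percentages are *truncated* to integers (`floor(100·k/n)`),
matching the convention of the published tables this summarizer
reproduces; the denominator defaults to the tabulated cell count but can
be an explicitly stated total, since published totals occasionally exceed
the sum of the per-layer counts printed beside them.

Enrichment testing excludes the MZ by default (essentially no backlabeled
cells arise there), renormalizes the expected neuron proportions over the
remaining layers, and runs a chi-square goodness-of-fit test. Only when
that omnibus test rejects at α are per-layer **exact two-sided binomial
tests** (minimum-likelihood two-sidedness, i.e. `binom.test`) run, with
enriched/depleted direction reported. No multiple-testing correction is
applied by default, matching common practice for this design; Holm or
Bonferroni can be switched on via `p_adjust`. Expected counts below 1
trigger a warning that the chi-square approximation is unreliable.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Bursty MUA** (`burst_model()`): burst onsets follow a homogeneous
  Poisson process at 2 min⁻¹, thinned so a burst cannot begin before the
  previous one ends; spikes per burst are `3 + NegBin(size 5, μ 10)`
  (mean 13, so every burst is detectable); intra-burst ISIs are gamma
  (shape 2, mean 50 ms), resampled when a draw reaches the 300 ms
  burst-breaking threshold; isolated background spikes are Poisson at
  0.05 Hz and may fall inside bursts. These defaults give occurrence,
  duration (≈ 600 ms), spike counts and intra-burst rates in the ranges
  reported for subplate and deep-layer MUA in neonatal slices.
* **Coupling** (`coupling_spec()`): each source burst triggers, with a set
  probability, a target burst at the source onset plus a gamma lag
  (default mean 150 ms); lags can be made deterministic. Inserted bursts
  are truncated at the recording span. Ground-truth burst onsets are
  stored so directionality analyses can be checked by construction.
* **Cortical volumes** (`volume_spec()`): pial and subplate boundaries are
  analytic quadratics; per-layer neuron counts are multinomial draws from
  the scheme's expected proportions; each neuron's true normalized depth
  is uniform within its layer's depth bin and its 3D position lies on the
  inward pial normal at that depth fraction of the local normal thickness,
  so the geometric ground truth is exact. Boundary clouds are sampled on a
  regular grid with optional isotropic Gaussian jitter (default 0).
* **Backlabeling** (`sample_backlabeled()`): independent per-cell
  Bernoulli draws with per-layer probabilities.

What the generator does **not** emulate: spindle-like oscillations or any
LFP structure (only MUA is modeled), electrode drift and artifacts,
non-stationary burst rates, correlated (clustered) backlabeling, surface
segmentation error beyond isotropic jitter, and real somato-dendritic
geometry. Passing tests therefore demonstrate the correctness and
calibration of the *analysis* under a plausible generative model, not the
biology of any particular recording.

One global seed expands into labeled substreams, so ensembles and volumes
can be regenerated stage by stage, bit-identically.

# Validation sizes and numerical conventions

The test-suite and the acceptance script use these problem sizes, chosen
to keep Monte-Carlo error well below the effects being checked:

* Burst-flag null calibration: 300 independent pairs of 10-min trains,
  200 surrogates each (the analysis default is 1,000 surrogates; 200 give
  a 99th percentile from rank 198 and leave the false-positive band
  unchanged).
* CCG null calibration: 30 independent 15 Hz / 120 s Poisson pairs, 200
  dither surrogates; the Monte-Carlo error of the exceedance rate is taken
  at the pair level because bins within a pair share one train and one
  surrogate set.
* Directionality: 20 pairs at coupling 0.5, lag mean +150 ms; 40 uncoupled
  control replicates.
* Parameter recovery: one 30-min train; agreement within 3 standard errors.
* Anatomy: 1,000 cells on curved surfaces (depth error < 0.01 at zero
  noise; ≥ 99% layer accuracy for cells ≥ 2 µm from a boundary); planar
  surfaces are exact to 1e-6.
* Enrichment: 1,000 null replicates at n = 300 (type-I ≈ α), 200
  replicates at n = 2,000 with the L5 probability doubled (power > 0.8).

Empirical percentiles use the inverse-ECDF convention
(`quantile(type = 1)`), and significance always requires *strict*
exceedance, so ties act conservatively. Dither sampling discretizes the
anti-diagonal into 41 candidate positions; the joint-ISI density grid step
is half the kernel bandwidth.

# Known limitations

* The burst-coincidence flag is conservative: for very dense bursts the
  jittered null retains genuine coupling (see above), and small coincident
  counts tie at the threshold. Lead-ratio inference is the more sensitive
  instrument for directionality.
* Point-to-surface distances assume the quadratic fit is adequate; strongly
  folded cortex would need a richer surface model than any single
  quadratic.
* `wilcox.test`'s exact p-values require untied absolute differences; with
  ties the normal approximation (continuity-corrected) is used, as usual.
* The CCG cluster test treats bins as exchangeable under the null; with
  strong slow co-modulation bins are positively correlated and the cluster
  p-value is approximate.
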