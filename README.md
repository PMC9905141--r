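# neoconn

Quantitative analysis of corticocortical connectivity in the newborn
rodent cortex, for developmental neurophysiologists and anatomists working
with multi-electrode slice recordings and retrograde tracing.

At birth, the transient **subplate (SP)** acts as a hub relaying thalamic
and corticocortical input into the developing cortical layers. Whether
adjacent cortical areas (primary somatosensory barrel field S1Bf, motor
M1, secondary somatosensory S2) are already wired through the SP at
postnatal day 0 can be probed two ways, and `neoconn` implements the
analysis for both:

**Electrophysiology.** Multi-unit activity (MUA) is extracted from
200–5,000 Hz band-passed extracellular traces by −5·SD threshold
crossings. A *burst* is a maximal run of ≥ 3 spikes with inter-spike
intervals ≤ 300 ms. For an electrode pair, bursts *coincide* when a spike
of one falls inside the other's bursting interval (equivalently, their
intervals overlap); matching is one-to-one and greedy in time order. The
**coincidence ratio** is

```
CR = n_coincident / min(n_bursts_A, n_bursts_B)   ∈ [0, 1]
```

and the **lead ratio** of an electrode is the fraction of coinciding pairs
whose burst onset (first spike) precedes the partner's. Chance levels come
from surrogate spike trains: spikes jittered by U(±750 ms) (≈ one burst
duration) with bursts re-detected per surrogate, the observed ratio
flagged when it exceeds the surrogate 99th percentile; lead ratios are
tested against 0.5 with a Wilcoxon signed-rank test. Spike-level synchrony
in the monosynaptic 5–15 ms window is assessed with cross-correlograms
(1 ms bins, ±50 ms) against joint-ISI-dithered surrogates: every interior
spike is displaced (≤ 25 ms) within the interval spanned by its
neighbours, conserving the sum of its two adjacent inter-spike intervals
exactly and respecting the kernel-smoothed joint-ISI density, so rate
structure survives while fine timing is destroyed.

**Anatomy.** Pial and lower-SP boundary point clouds are fit with
least-squares quadratic surfaces `z = f(x, y)`. Each retrogradely labeled
soma gets a **normalized cortical depth** — Euclidean distance to the pial
surface divided by the local pial-to-subplate thickness measured along the
nearest-point ray (0 = pia, 1 = SP/white-matter boundary) — and a layer
label (MZ, CP, L5, L6, SP) from relative-thickness schemes. Laminar
**enrichment** of backlabeled cells against expected neuron proportions is
tested with a chi-square goodness of fit (MZ excluded) followed, when
significant, by per-layer exact two-sided binomial tests.

A synthetic-data generator (bursty trains with controllable coupling and
lag; cortical volumes with exact geometric ground truth and per-layer
backlabeling probabilities) stands in for raw recordings and confocal
volumes, so the whole pipeline is testable end to end.

## Worked example

Simulate a coupled SP → L5/6 pair, detect bursts, and test coincidence and
directionality:

```r
library(neoconn)

models <- list(
  s1_sp  = burst_model(span_s = 600),                  # 2 bursts/min
  s1_l56 = burst_model(burst_rate = 1.2, span_s = 600))
ens <- generate_coupled_ensemble(
  models,
  list(coupling_spec("s1_sp", "s1_l56", coupling_prob = 0.6,
                     lag_mean_s = 0.15)),
  seed = 42)

burst_stats(detect_bursts(ens$s1_sp), span_s(ens$s1_sp))
#>   n_bursts occurrence_per_min mean_duration_ms mean_n_spikes mean_intra_freq_hz
#> 1       20                  2           731.12         15.05              19.86

pair_coincidence(ens$s1_sp, ens$s1_l56, n_surrogates = 200, seed = 43)
#> <pair_coincidence> s1_sp vs s1_l56: ratio 0.500 (n = 10 / bursts 20, 28)
#>   lead A 0.90  lead B 0.10  tie 0.00 | null p99 = 0.500 -> not significant
```

Half of the SP bursts find a partner in L5/6 (ratio 0.50), and 90% of the
coinciding bursts start first at the SP electrode — the imposed SP → L5/6
coupling with its +150 ms lag is visible in the lead ratio. (With dense
default bursts the jittered null retains part of the coupling, so the
ratio flag stays conservative; directionality is the sensitive readout.)

Laminar enrichment of backlabeled cells (counts per layer out of 136
cells) against the S1Bf neuron proportions:

```r
sc <- layer_scheme("S1Bf")
enrichment_test(c(CP = 30, L5 = 47, L6 = 50, SP = 9), sc)
#> <enrichment_result> 136 cells over CP, L5, L6, SP
#>   chi-square GoF: X2 = 11.538, df = 3, p = 0.00914
#>  layer observed  expected     p_value direction significant
#>     CP       30 47.744681 0.001163607  depleted        TRUE
#>     L5       47 34.723404 0.018207044  enriched        TRUE
#>     L6       50 44.851064 0.362076273  enriched       FALSE
#>     SP        9  8.680851 0.860269623  enriched       FALSE
```

CP contributes fewer projecting neurons than its share of all neurons
predicts (depleted), L5 more (enriched); L6 and SP are as expected.

An end-to-end run (simulate → detect → coincidence → anatomy → report)
with outputs, summary tables and a reproducibility manifest:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "neoconn"),
             outdir = "demo_out", seed = 1)
```

or from a shell via the thin wrapper
`Rscript inst/scripts/run_pipeline.R --outdir demo_out --seed 1`.

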