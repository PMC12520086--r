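---
title: "Pattern-Temporal Synergy: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-Temporal Synergy: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ptsynergy)
```

## The index

Pattern-Temporal Synergy (PTS) is a composite, threshold-gated index of
*reflexive coherence* computed from multichannel physiological recordings —
in the plant setting, cytosolic Ca2+ waves (0.05–0.5 Hz), phloem surface
voltage (0.2–5 Hz), O2 micro-flux (1e-3–0.1 Hz) and heat flux
(1e-2–0.1 Hz). The driving idea is that unified, self-referential
processing requires five relational patterns — self-reference,
division-creation, information integration, responsiveness and flux — to be
simultaneously strong *and* phase-locked within the system's intrinsic
binding window τ (about 2 s for leaf-scale plant signalling).

Analysis proceeds in sliding windows of `3 τ` with 50% overlap (a literal
6 s / 5 s "leaf" preset and a 30 s / 15 s "whole-organ" preset are also
available). Per window:

1. **Five pattern scores.** Active information storage (AIS) for
   self-reference, Louvain modularity Q of the |rank-correlation| channel
   graph for division-creation, Williams–Beer partial-information-
   decomposition (PID) synergy over channel triplets for integration,
   symbolic transfer entropy (TE) for responsiveness, and the aperiodic
   1/f spectral slope for flux.
2. **Surrogate z-scoring.** Each score is z-scored against a pooled null of
   phase-randomized surrogates (channels randomized independently), putting
   heterogeneous quantities on one scale. Strengths are the standard-normal
   CDF of the z-scores, so 0.5 is "indistinguishable from the null".
3. **P-bar and S-bar.** The central pattern strength P̄ is the median of
   the five strengths. The mean synergy S̄ is the average pairwise
   Williams–Beer synergy of channel pairs about the (quantile-discretized)
   leave-two-out global state, passed through the same z-to-strength map.
4. **The temporal-coherence gate.** A window is temporally coherent
   (TC = 1) only when its mean pairwise weighted phase-lag index (wPLI,
   computed in the τ band `[1/(3τ), 1/τ]` over the modality-band overlap of
   each pair) strictly exceeds the 75th percentile of the surrogate null.
   `PTS = P̄ × S̄` when the gate passes and exactly 0 otherwise.

Windowed PTS is then aggregated into non-overlapping 10-minute epochs. An
epoch shows *sustained* reflexive coherence only if at least 75% of its
valid windows have PTS above the threshold φ = 0.75 (the dual gate), and it
is summarized by median ± MAD. The preregistered decision rules follow:
H1 (baseline coherence) is supported when ≥ 75% of baseline windows reach
φ; H2 (anesthetic collapse) when the ether-block PTS falls below φ for
more than half of its windows with a sub-φ median, evaluated only if H1
holds; H3 (recovery) when the post-stabilization wash-out median returns to
within ±10% of the plant's own baseline and the φ gate holds again,
evaluated only if H2 holds.

## Estimator choices and why they matter

The package makes several estimator-level decisions where the index's
published description is silent. These were settled by explicit desk
experiments on the synthetic generator (comparing each estimator against
its own surrogate null), and they are worth knowing about because several
"obvious" choices fail in instructive ways at this window length
(300 samples at the 50 Hz desk scale; a handful of carrier cycles).

**Quantile symbols, not ordinal patterns.** Ordinal (rank-pattern) symbols
are invariant to amplitude, so wave packets and bursts — the very structure
that phase randomization destroys — are invisible to them; on oversampled
smooth signals ordinal AIS and TE measure *below* their surrogate nulls
(the Gaussianized surrogate is ordinally more regular). Amplitude-tercile
symbols see the bursts, and with a history lag and prediction horizon of
`0.1 τ` they yield honestly positive z-scores. Ordinal symbolization
remains available (`metrics$symbolizer$scheme = "ordinal"`) and the
monotone-invariance property is kept under test.

**Prediction horizons.** Consecutive samples of band-limited signals are
nearly identical, so "next-sample" prediction is saturated for both data
and surrogates. AIS and TE therefore predict one symbol-lag ahead
(`horizon_s`, default τ/10), where genuine signal innovation lives.

**Occupancy-bias correction for TE.** Plug-in conditional information is
biased upward in proportion to the occupied state space. Coupled channels
*concentrate* the joint state space, so raw plug-in TE of strongly coupled
channels measures below independently-surrogated channels — an inverted
contrast. Each pair's TE is therefore measured against a cyclic
source-rotation baseline (a source-shuffle that preserves both series'
dynamics while breaking their alignment) before entering the window score.

**Band-capacity weighting.** A channel can only express window-scale
structure inside its own passband; a 0.1 Hz stream carries less than one
cycle per 6 s window. AIS, TE and the integration score weight channels by
passband width, and channels whose band cannot complete 1.5 oscillations
within a window are excluded from that tier entirely — this is the
two-tier logic: slow O2/heat streams enter through the 30 s whole-organ
tier.

**The flux slope is fitted in-band.** Band-limited channels have an
artificially steep spectral roll-off outside their passband, and — more
subtly — the coherent leakage cancellation of a smooth filtered signal
breaks under phase randomization, so out-of-band slope comparisons show a
spurious surrogate offset. The 1/f slope is fitted only across channels
whose usable range spans at least a factor of three in frequency (in
practice the broadband voltage stream).

**Phase-randomized null, not IAAFT, for the pipeline.** The
amplitude-adjusted iterated surrogate preserves the marginal distribution
but its spectrum match on 300-sample windows is imperfect, which biases
every spectrum-sensitive null. Plain phase randomization preserves the
amplitude spectrum bit-exactly. IAAFT remains available
(`surrogates$method = "iaaft"`).

**S̄.** The mean-synergy term is named but never defined operationally in
its source material. Two constructions were implemented. The
sub-slice construction (pattern-score sub-series, pairwise synergy about a
discretized global state, normalized by joint information;
`synergy_profile()`) is retained and tested, but plug-in normalization
caps it near 0.6 for *any* dependent data at 8–16 sub-slices — the marginal
plug-in bias inflates the unique-information terms — which would cap PTS
permanently below φ and make every verdict trivially negative. The
pipeline therefore uses the same normalization as every other quantity in
this method: the raw statistic (average pairwise channel synergy about the
leave-two-out global state) is z-scored against the pooled surrogate null
and mapped through the normal CDF. The leave-two-out state matters:
a state built from the pair's own channels is circular and shows identical
"synergy" in surrogates.

**The gate.** wPLI is the gated statistic (robust to common-drive zero-lag
artifacts); PLV is computed and reported alongside. Gating is restricted
to the τ band `[1/(3 τ), 1/τ]` — synchrony at binding-window timescales is
what the gate is about — and pairs are formed across the modality-band
overlap. Two hard small-window facts shape this design: a single Fourier
mode per analysis band makes *any* phase statistic degenerate (its
surrogate keeps the same carrier), so the gate needs broadband shared
content plus genuine noise in-band; and wPLI is insensitive at near-zero
lag, so cross-modality pairs (which carry a conduction lag) are the
informative ones.

## The synthetic generator

`simulate_recording()` emulates the study conditions end-to-end. Each
plant carries three latent binding drives, all delivered through
per-channel conduction delays (voltage fastest, Ca/O2 latest, spread below
τ/2 at baseline):

* a **shared chemical wave** — discrete Gaussian-enveloped wave packets
  (Poisson events, two tissue sectors around a common core) in
  0.1–0.3 Hz, the broadband carrier of cross-modality phase coherence;
* a **fast electrical spike wave** — asymmetric action-potential-like
  events (fast depolarization, slower repolarization) at 0.8–2.4 Hz on the
  voltage channels, the carrier of directed information (a leading
  electrode genuinely predicts a lagging one) and of time-irreversible
  self-structure;
* a **relaxation oscillation** — a phase-diffusing harmonic sawtooth at
  0.45 Hz shared by all channels; its slow-rise/fast-fall asymmetry is
  invisible to the amplitude spectrum and hence to the surrogates.

Per-modality shared components and 1/f-shaped in-band noise complete each
channel. Ether (4% v/v, minutes 60–120 of the canonical 180-minute
session) multiplies the conduction delays by a per-plant factor drawn
uniformly in [3, 5], adds fast per-channel phase jitter and damps the
binding coupling, with a ~90 s onset ramp; wash-out relaxes all three
exponentially (3-minute time constant). The generator never writes
non-finite samples, is bit-reproducible given (protocol, plant, seed), and
concentrates ≥ 80% of each channel's power inside its declared band.

What the generator does *not* emulate: imaging artifacts and motion,
slow circadian nonstationarity, inhomogeneous electrode coupling,
stimulus-evoked nonlinear saturation, or any biophysically detailed
reaction–diffusion dynamics. Passing tests on this generator demonstrate
that the pipeline detects (and loses) τ-windowed multichannel coherence of
the kind the theory predicts — not that real plants exhibit it.

## Calibration, problem sizes, and two structural findings

Desk-scale runs use 50 Hz sampling, three channels per modality, 20
surrogates and 6–12 plants; tests run a 6-plant cohort and the acceptance
script a 12-plant cohort plus a baseline-only cohort. Generator constants
were fixed once, by a documented calibration against the estimators'
surrogate nulls at baseline, and are shipped as the defaults of
`pts_regimes()` / `pts_protocol()`.

Two quantitative expectations of the source material could not be met, for
reasons worth recording.

*The baseline 75% rule.* With 6-s windows of sub-hertz signals, each
pattern z-score carries roughly ±1σ of irreducible sampling noise, and the
dual requirement (gate pass *and* median strength *and* synergy all high)
is a conjunction of noisy events. Even with three of five metrics
averaging z ≈ 2–5 at baseline, the fraction of windows with PTS ≥ 0.75
plateaus near 30–45%, not 75%. No generator inside the declared modality
bands escapes this: it is a property of window-level information estimates
at a few carrier cycles, and the honest measured fraction is reported.

*The depth of the anesthetic collapse.* The index's own algebra forces the
ether block to near-zero PTS: the 3–5× delay stretch pushes every
cross-channel lag past half a cycle of every gate-band frequency, the
temporal-coherence gate fails, and gated windows are defined as exactly 0.
The regenerated collapse is therefore ~100%, deeper than the ~58%
illustrative figure, though consistent in direction and with the ≥ 40%
preregistered bound. Recovery behaves as predicted: wash-out returns to
within a few percent of baseline and stabilizes well inside the session.

## Numerical details worth knowing

* Filtering is zero-phase FFT band-passing with raised-cosine edges (20%
  transition), stable at arbitrarily low normalized frequencies where IIR
  designs are not; resampling is polyphase FIR with anti-alias filtering;
  stimulus channels are zero-order-held, never filtered.
* Windows are half-open `[start, end)`, left-aligned, trailing partials
  dropped; epochs tile from t = 0 and a trailing partial epoch is dropped.
* Ties fail the TC gate (strict `>`); window counting against φ is strict
  (`>`) inside epochs, while H1's per-window rule is inclusive (`≥`),
  both following the respective stated rules.
* Louvain runs on a fixed node order under a fixed seed; integration
  triplets and synergy pairs are seeded samples, fixed per run.
* Degenerate inputs are flagged, not guessed at: constant series pass
  through surrogates unchanged, zero-variance nulls give z = 0, constant
  gate channels give NA coherence, windows with undefined scores are
  invalidated and excluded from every downstream statistic.
* All randomness (surrogates, Louvain, triplet draws, bootstrap,
  permutations, the generator) is seed-controlled; derived seeds stay
  below 2^31.

## Limitations

The estimators are plug-in and window-local; their absolute values are
biased and only comparisons against the paired surrogate null are
meaningful. The S̄ construction is one defensible reading of an
under-specified quantity and is isolated behind the configuration so a
future faithful variant can replace it. The whole-organ tier inherits the
same small-window statistics at its own scale. Nothing here bears on real
plants until the pipeline is run on real recordings.
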