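---
title: "Quantifying cooperative gating of clustered CaV1.3 channels"
author: "coopgate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperative gating of clustered CaV1.3 channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopgate)
```

# The problem

L-type CaV1.3 channels cluster in the plasma membrane of neurons and
excitable cells. The short C-terminal splice variant (CaV1.3S) can gate
*cooperatively*: Ca²⁺ entering through one channel promotes the opening of
its cluster neighbors, so that optically recorded Ca²⁺ influx events
(sparklets) show coordinated multi-quantal openings, and whole-cell Ca²⁺
current is amplified relative to what independent channels would produce.
`coopgate` implements the measurement chain that quantifies this behavior
— the coupled gating model and its κ estimator, quantal amplitude
analysis, sparklet activity scoring, photobleaching stoichiometry, and
localization-microscopy cluster statistics — together with synthetic-data
generators that make every stage testable against known ground truth.

# The coupled Markov-chain gating model

A site holds N identical two-state (closed/open) channels observed at the
imaging frame rate (default dt = 10 ms, i.e. 100 Hz). The observable state
is the occupancy k ∈ {0, …, N}, the number of open channels in a frame.
Gating is a discrete-time Markov chain on occupancy with kernel

$$T = (1-\kappa)\,T_{\mathrm{ind}} + \kappa\,T_{\mathrm{coh}}$$

* **Independent kernel.** Each open channel stays open with probability
  $1-p_{\mathrm{close}}$, each closed channel opens with probability
  $p_{\mathrm{open}}$, independently:
  $T_{\mathrm{ind}}(k \to k') = P[\mathrm{Bin}(k, 1-p_{\mathrm{close}}) +
  \mathrm{Bin}(N-k, p_{\mathrm{open}}) = k']$.
* **Coherent kernel.** The site acts as one super-channel: from $k=0$ it
  jumps to $N$ with probability $p_{\mathrm{open}}$, otherwise stays
  closed; from any $k \ge 1$ it closes completely with probability
  $p_{\mathrm{close}}$, otherwise moves to $N$.

The coupling coefficient κ ranges from 0 (purely independent gating) to 1
(fully coupled, all-or-none gating). The published description of the
coupled-chain analysis does not reproduce its transition structure; this
mixture kernel is **this package's concrete realization**, chosen because
it (a) reduces *exactly* to the independent-channels kernel at κ = 0,
(b) produces all-or-none gating at κ = 1, and (c) leaves κ identifiable by
maximum likelihood. It is a reimplementation, not a bit-match of the
original analysis scripts.

## Likelihood and estimation

A fluorescence record $x_t$ is modeled as a hidden-Markov chain over the
N+1 occupancy states with Gaussian emissions of mean
$\mathrm{baseline} + k q$ and SD `noiseSd`, where q is the quantal
amplitude (38 nM is the standard sparklet analysis constant; quantal fits
of event histograms give ~40 nM — both are exposed, 38 is the default).
`traceLogLikelihood()` runs the forward recursion with per-frame rescaling
(compiled code), initialized at the chain's stationary distribution.
Already-quantized records (`OccupancyTrace`) instead use the exact
transition-count likelihood — both input paths are provided because it is
not documented which one the original scripts used.

`estimateKappa()` maximizes the likelihood over
$(p_{\mathrm{open}}, p_{\mathrm{close}}, \kappa)$ deterministically: a
coarse grid (κ in steps of 0.05, probabilities log-spaced in
[2×10⁻³, 0.7]) followed by Nelder–Mead refinement from the best three grid
points, probabilities constrained to [10⁻⁴, 0.9999] to keep the likelihood
finite, and ties broken toward smaller κ. N is supplied by the caller
(from the observed quantal level count), not estimated — this matches the
per-site quantal-level bookkeeping of the original analysis. Sites with
κ̂ > 0.1 are classified coupled. A constant record carries no gating
information and returns κ̂ = 0 with a `"no transitions"` flag.

```{r kappa-demo}
sim <- makeSparkletTrace(gatingPreset("cav13s_sparklet"),
                         signalPreset("sparklet_default"),
                         nFrames = 2000, seed = 1)
estimateKappa(sim$trace, nChannels = 2, q = 38, baseline = 100, noiseSd = 8)
```

# Quantal amplitude analysis

All-points histograms pool every sample of every sweep into bins aligned
so one bin center is exactly 0 pA (default width 0.02 pA ≈ q/25 for Ca²⁺
unitary currents: fine enough to resolve the ~0.49 pA spacing with smooth
peaks). The quantal model fitted to the histogram is

$$N(i) = \sum_{j=1}^{n} a_j\,
  \exp\!\left[-\frac{(i - j q)^2}{2 j b}\right]$$

component j has mean $jq$ and variance $jb$ — the "2jb" denominator is
read as level-proportional broadening. Inward currents are negative
throughout and q̂ is reported with its sign.

Numerical choices worth knowing:

* The j = 0 (closed) peak is **not** part of the quantal sum (the sum
  starts at j = 1). It is modeled as a separate free Gaussian
  (a₀, μ₀, σ₀) and estimated *jointly* with the quantal parameters in a
  single least squares. A sequential "fit the closed peak, subtract, then
  fit the quanta" procedure was tried first and left a systematic ~2% bias
  in q̂ because each peak's tail contaminates the other's fit; the joint
  fit removes it. Setting `fitBaseline = FALSE` fits the bare quantal sum.
* Starts: q seeded at the largest off-zero local maximum of the smoothed
  histogram, times {0.5, 1, 2}; amplitudes enter as squares (nonnegative);
  each Nelder–Mead run is restarted once from its own optimum to guard
  against simplex collapse.
* **Identifiability.** If only one open level is present (a true
  single-channel patch), a 2-component fit is degenerate: q/2 with a₁ = 0
  reproduces the same curve. Choose `nComponents` to match the number of
  occupied open levels — 1 for N = 1 patches, 2–3 for sparklet event
  histograms where multi-quantal peaks are populated.

The same fitter, in nM units, serves sparklet event-amplitude histograms
(`fitEventAmplitudes()`, default 4 nM bins). An event's amplitude is the
mean signal over the frames at the event's maximum level, minus baseline,
which keeps multi-level events centered on integer multiples of q.

# Sparklet detection and activity

Detection: baseline is the histogram mode (1 nM bins — robust when the
site is active and the mean exceeds rest), an event is a maximal run of
frames at or above baseline + q/2 lasting ≥ 2 frames (20 ms at 100 Hz —
rejects single-frame noise while keeping brief quantal events; both
configurable). Activity **nPs** is defined as time-averaged occupancy
$\sum_t k_t / T$ — the optical analog of NPo. The cited nPs formulation is
not reproduced in the original methods, so this concrete definition is the
package's documented choice; Ps (fraction of active frames) and the
maximum quantal level are reported alongside.

# Whole-cell metrics

* Conductance: $G = I/(V - E_{\mathrm{rev}})$, normalized to its maximum;
  points at $E_{\mathrm{rev}}$ are excluded with a warning. Default
  reversal potentials: +54 mV (2 mM Ca²⁺) and +65 mV (Ba²⁺) for CaV1.3S.
* Boltzmann: $g = 1/(1 + e^{(V_{1/2} - V)/k})$, initialized at the voltage
  nearest g = 0.5 with k = 8 mV.
* CDI: r300 is the fraction of peak current (absolute values — the sign
  convention for the ratio is not stated in the source methods) remaining
  at 300 ms; f300 is fixed as r300(Ba²⁺) − r300(Ca²⁺) so that stronger
  Ca²⁺-dependent inactivation gives f300 > 0 (the printed wording is
  direction-ambiguous). Peaks are read off a 5-sample moving mean so a
  single noise spike cannot masquerade as the peak.
* Activation: $I(t) = I_{\max}(1 - e^{-t/\tau})$ fitted from onset to the
  smoothed peak. Presets carry the measured constants 1.17 ms (CaV1.3S)
  and 1.60 ms (CaV1.3L) at −10 mV.
* Split-fluorophore F/F₀: per voltage, the last 10 frames are averaged and
  summed over the cell mask, then divided by the value at the −80 mV
  holding stack, so F/F₀(−80) = 1 by construction.

# Step photobleaching

The detection image is the mean of the first 5 frames, minus a
rolling-ball background (grayscale opening with a disk; the radius is not
stated in the source recipe — default 10 px, configurable), band-passed as
the difference of two Gaussian blurs with σ = cutoff/2 for the stated 2 px
low-pass and 5 px high-pass cutoffs (the exact kernel, for
reproducibility: separable Gaussians with reflecting edges). Thresholding
("auto" = mean + 3 SD; the original value is unstated) and 8-connected
labeling yield spots; a 4×4 ROI is anchored with the peak at window
position (2, 2) — "centered" is ambiguous for an even window, so this
convention is fixed. The z-profile is the per-frame window sum.

The original analysis counted bleaching steps *manually*; `countSteps()`
is this package's automated replacement, validated only on synthetic
ground truth. It fits a piecewise-constant profile greedily (each
iteration adds the breakpoint that most reduces squared error) and stops
by a Schwarz-type criterion $T \log(\mathrm{RSS}/T) + 2m\log T$ over the
number of breakpoints m; only downward steps with magnitude ≥ `minStep`
are kept ("auto" = half the median step magnitude of the first fit, which
makes the count invariant to positive rescaling of the trace). Known
limitations, shared with all GFP-counting approaches: simultaneous bleach
events merge into one step, steps within < 2 frames of each other or at
the movie edge are not resolvable, and blinking/immature fluorophores bias
counts downward.

# Localization microscopy

Localization precision follows the photon-budget law DLR/√N. The DLR
default is **710 nm — the center of the 660–760 nm detection band —
because 710/√1900 = 16.3 ≈ 16 nm**, the printed accuracy at ~1900 detected
photons; the source's exact DLR definition is unstated, so the value is a
documented configurable default, not a claim. Rendering is a 2D count
histogram at 10 nm/px; binarization at ≥ 1 localization per pixel (the
original binarization rule is unstated), 8-connected labeling, areas in
nm² and densities per µm². Localization error dilates rendered clusters,
so recovered areas carry an upward bias that grows with σ — the
`clusterRecovery()` report makes this visible against ground truth.

# The synthetic world

Generators return ground truth (occupancy, bleach times, emitter
positions) sufficient to score downstream recovery, and all randomness
flows from one top-level seed through named substreams
(`substreamSeed()`), so adding one generator call never perturbs another.
Defaults are anchored to published constants wherever they exist:
q = 38 nM sparklet quanta; unitary currents −0.49/−0.48 pA (Ca²⁺) and
−1.10/−1.14 pA (Ba²⁺) at −30 mV; κ = 0.21 (CaV1.3S) and 0.08 (CaV1.3L);
τ_act 1.17/1.60 ms; E_rev +54/+65 mV; DLR 710 nm with lognormal photon
counts of median 1900 (heavy right tail typical of switching events);
2000-frame bleach movies at 30 Hz; Poisson(mean 8, min 1) channels per
cluster, matching the 8 ± 1 channels/cluster stoichiometry; 30 nm cluster
disk radius, giving rendered areas on the scale of the measured
~3660 nm².

Where no value is stated, one realistic choice was made and is not
revisited: sparklet-site gating pOpen = 0.03, pClose = 0.3 per 10 ms
frame (brief ~30 ms openings at low resting activity, 1–3 quantal
levels); single-channel gating with Po = 0.3 and 20 ms mean open time
(dihydropyridine-agonist conditions) at 10 kHz; 100 nM resting [Ca²⁺]
baseline with 8 nM measurement noise; bleach steps of 100 AU with
2×10⁻³/frame hazard (geometric — the memoryless discrete analog of
exponential bleaching; forced bleach times are available for
deterministic tests). The sparklet movies' pixel size and PSF width are
likewise unstated; stack rendering uses a 1.3 px Gaussian PSF at
100 nm/px as documented defaults, not claims about the original data.

What the generators deliberately do **not** emulate — and therefore what
a green test does not establish: no Ca²⁺-dependent inactivation inside
the gating chain (CDI lives only in the whole-cell waveform generator),
no optics beyond a Gaussian PSF, no EMCCD gain/photon-transfer model, no
fluorophore blinking or maturation, no drift. Recovery results on this
synthetic world validate the estimators' correctness, not their
robustness to those unmodeled effects.

# Verification strategy

Each estimator is tested against an independent oracle: the forward
likelihood against exhaustive path enumeration (N = 2, traces ≤ 6
frames, agreement < 10⁻⁸), the κ = 0 kernel against a hand-enumerated
independent kernel, stationary occupancy against the eigenvector,
closed-form r300 = e^(−300/τ) for exponential decays, and fits against
their own noiseless generators. Parameter-recovery suites then run the
full chain on the preset-anchored synthetic world: quantal units within
±0.02 pA, mean κ within the published SEMs, sparklet quanta within
±2 nM, activation τ within ±0.01 ms, and the step counter exact on
noiseless 1–10-step staircases and ≥ 90% exact at step-SNR 3.

`scripts/acceptance.R` re-runs exactly these recoveries from scratch at a
caller-supplied seed and writes the measured values as JSON; the numbers
it prints are computed at run time, never stored.

# Known limitations

* κ estimation assumes exchangeable channels and a known N; heterogeneous
  unitary amplitudes or miscounted quantal levels bias κ̂.
* The mixture kernel is one of several chains consistent with the verbal
  model; κ values are comparable within this package, and against the
  published values only to the extent that the original kernel behaved
  similarly at κ = 0 and κ = 1 (both endpoints are exact by construction).
* The quantal fitter requires the component count to match the occupied
  levels (see identifiability above).
* Cluster areas from binary masks are resolution- and threshold-dependent;
  only comparisons at fixed rendering settings are meaningful.
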