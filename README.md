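# coopgate

Quantitative analysis of **cooperative gating in clustered CaV1.3 Ca²⁺
channels**, for electrophysiologists and imaging labs working on L-type
channel physiology.

Small clusters of CaV1.3 channels can gate cooperatively: Ca²⁺ entering
through one channel promotes the opening of its neighbors, producing
multi-quantal Ca²⁺ influx events ("sparklets") and amplified whole-cell
current. `coopgate` implements the full measurement chain used to
demonstrate and quantify this behavior:

- **Coupled Markov-chain gating model.** The occupancy (number of open
  channels) of an N-channel site evolves under the mixture kernel

  T = (1 − κ)·T_ind + κ·T_coh

  where T_ind is the kernel of independently gating two-state channels
  (binomial closures and openings) and T_coh is an all-or-none
  super-channel. The coupling coefficient κ ∈ [0, 1] interpolates from
  purely independent (κ = 0) to fully coupled (κ = 1) gating; sites with
  κ > 0.1 are called coupled. κ is estimated by maximum likelihood with a
  hidden-Markov forward recursion (Gaussian emissions, mean
  baseline + k·q) or an exact transition-count likelihood for quantized
  records.
- **Quantal single-channel analysis.** All-points amplitude histograms and
  the multi-Gaussian quantal fit
  N(i) = Σⱼ aⱼ·exp[−(i − j·q)² / (2·j·b)], half-amplitude idealization,
  ensemble averages, and NPo = |I|/|i| arithmetic with Ca²⁺/Ba²⁺ fold
  changes.
- **Sparklet analysis.** Event detection at the q/2 threshold, nPs
  (time-averaged occupancy) activity scoring, event-amplitude quantal
  fits in nM, site density, and fluorescence→[Ca²⁺] calibration.
- **Whole-cell metrics.** G = I/(V − E_rev) conductance transform,
  Boltzmann activation fits, CDI metrics (r300, f300, % inactivation),
  activation τ, and split-fluorophore F/F₀–voltage relations.
- **Step photobleaching.** The standard detection-image recipe (first-5
  average, rolling-ball background, 2 px/5 px band-pass, threshold, 4×4
  ROIs, z-profiles) plus an automated penalized step counter for
  channels-per-cluster stoichiometry.
- **Localization microscopy.** DLR/√N precision, 2D Gaussian centroid
  fitting, rendering, and binary-mask cluster area/density statistics.
- **Synthetic data generators** for every input class, with ground truth
  returned alongside, so each stage is verifiable at desk scale.

## Worked example

Simulate 20 s of a two-channel sparklet site at the CaV1.3S coupling
preset (κ = 0.21, q = 38 nM, 100 Hz) and estimate κ back from the trace:

```r
library(coopgate)

gating <- gatingPreset("cav13s_sparklet")
signal <- signalPreset("sparklet_default")
sim <- makeSparkletTrace(gating, signal, nFrames = 2000, seed = 1)

fit <- estimateKappa(sim$trace, nChannels = 2, q = 38,
                     baseline = 100, noiseSd = 8)
fit
#> CouplingFit: kappa = 0.195 (coupled, threshold 0.10), pOpen = 0.02911,
#>   pClose = 0.283, logLik = -7720.50

site <- siteNps(sim$trace, q = 38, baseline = 100)
site
#> SparkletSite '': 69 events, nPs = 0.258, Ps = 0.201, n levels = 3
```

The coupling fit recovers the preset's κ = 0.21 within sampling error and
classifies the site as coupled (κ̂ > 0.1); `siteNps()` reports the site's
activity nPs (mean open channels per frame) and the number of quantal
levels visited. The same estimator applied to `independent_sparklet`
records (κ = 0) returns κ̂ ≈ 0 and "uncoupled".

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from freshly simulated data, the quantities the package is
validated against: the DLR/√N localization precision at 1900 photons; the
quantal units recovered from synthetic CaV1.3S single-channel sweeps with
Ca²⁺ and Ba²⁺ presets; mean coupling coefficients over 15 CaV1.3S-preset
and 12 CaV1.3L-preset simulated sparklet sites; the elementary sparklet
amplitude from event-histogram fits; and the activation time constant from
a noiseless whole-cell trace. Results are written as a flat JSON object
keyed by target id.

See `vignettes/cooperative-gating.Rmd` for the model, its assumptions,
parameter choices and known limitations.
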