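---
title: "Modeling skin-tone bias in pulse oximetry with voxel Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling skin-tone bias in pulse oximetry with voxel Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxisim)
```

## The problem

Pulse oximeters estimate arterial oxygen saturation (SpO2) from the
pulsatile modulation of light transmitted through or reflected from
perfused tissue at two wavelengths, red (660 nm) and infrared (940 nm).
The instrument reduces the photoplethysmographic (PPG) signal at each
wavelength to a perfusion index,

$$\mathrm{PI}_\lambda = \frac{\mathrm{AC}_\lambda}{\mathrm{DC}_{\mathrm{diastole},\lambda}},$$

and forms the *ratio of ratios* $R = \mathrm{PI}_{660} / \mathrm{PI}_{940}$,
which is mapped to SpO2 through an empirical calibration curve. Clinical
studies have repeatedly reported that oximeters overestimate SpO2 in
heavily pigmented skin (occult hypoxemia). Because melanin attenuates red
light much more strongly than infrared, the question is whether — and in
which sensor geometry — epidermal melanin biases $R$ itself.

`oxisim` reproduces this question *in silico*: a voxelized four-layer
finger phantom, a compiled voxel Monte Carlo photon-transport kernel, and
the pulse-oximetry analysis chain (AC/PI/R, attenuation decomposition,
path-length statistics, calibration-curve read-off), organized as
transmission, central-reflection and finite source–detector-separation
experiments over a sweep of arterial saturations and two skin tones.

## Tissue model

The phantom is a 1 × 1 × 0.41 cm cuboid divided into 101 × 101 × 201
voxels. Media, in label order:

1. **Epidermis** — 0.015 cm at the illuminated (top) face *and* at the
   detection (bottom) face. A finger has skin on both sides of the light
   path; with epidermis only on the source side the model cannot produce
   transmission-mode melanin attenuation stronger than reflection-mode
   attenuation, while the symmetric layer reproduces both (see
   "Design choices" below).
2. **Dermis** — everything else, including the thin interior slab not
   covered by the nominal layer thicknesses (no separate subcutis
   properties are defined).
3. **Arteries** — two cylinders of radius 0.025 cm along y, centered at
   x = 0, at axis depths 0.07 and 0.31 cm.
4. **Bone** — one cylinder of radius 0.05 cm at axis depth 0.18 cm.

Voxels are labeled by their center coordinate. The tissue is laterally
unbounded: beyond the grid's x/y edges the layer structure continues
unchanged (the edge columns are pure layers, so clamping the label lookup
is exact), and photons may wander outside the fluence grid and return.

### Optical properties

Every layer's absorption coefficient is a volume-fraction mixture of
arterial blood, venous blood, water and melanin over a power-law baseline:

$$\mu_a = V_a\,\mu_{a,A} + V_v\,\mu_{a,V} + V_w\,\mu_{a,w} + V_m\,\mu_{a,m}
  + \bigl[1 - (V_a+V_v+V_w+V_m)\bigr]\,\mu_{a,\mathrm{baseline}},$$

with $\mu_{a,\mathrm{baseline}}(\lambda) = 7.84\times10^{8}\,
\lambda^{-3.255}\ \mathrm{cm}^{-1}$ and blood absorption the
saturation-weighted mix of oxy-/deoxyhemoglobin. Venous saturation is held
10 percentage points below arterial. Skin tone enters through the
epidermal melanin volume ($V_m$ = 0.05 light, 0.25 dark; Fitzpatrick
types ~2 and ~5) and the tone-dependent tabulated epidermal scattering
(250/150 cm⁻¹ light, 300/170 cm⁻¹ dark at 660/940 nm). The cardiac pulse
enters through the arterial blood volume, 0.3 in diastole and 0.6 in
systole.

The artery layer's volume fractions sum to 1.2 (diastole) and 1.5
(systole), which makes the baseline residual term negative. The mixing
rule is applied literally — the source tables define no renormalization —
and the package warns once per session. The resulting artery absorption
stays positive at both wavelengths.

Dermis and artery scattering come from the reduced-scattering power law
$\mu_s'(\lambda) = a'[f_{\mathrm{ray}}(\lambda/500)^{-4} +
(1-f_{\mathrm{ray}})(\lambda/500)^{-b_{\mathrm{Mie}}}]$ scaled by
$1/(1-g)$; the artery's unlisted Rayleigh fraction is taken as 0, which is
required to reproduce the published artery scattering values (75.76 and
53.19 cm⁻¹). All media share $g = 0.9$ and $n = 1.43$; the uniform index
means no Fresnel reflection or refraction anywhere.

All built-in constants live in a human-readable YAML file
(`system.file("extdata", "tissue_optics.yaml", package = "oxisim")`) and
can be overridden wholesale via `tissue_config(path)`.

```{r media}
st <- physio_state(0.9, "diastole", "dark")
suppressWarnings(assemble_media(st, 660))
```

## Transport kernel

The compiled kernel implements standard voxel Monte Carlo with
MCML-style implicit capture:

- **Launch**: collimated Gaussian beam, "radial width" interpreted as the
  1/e² intensity radius (0.2 cm), samples outside the domain redrawn.
- **Stepping**: dimensionless step $s = -\ln\xi$ converted through the
  local $\mu_t = \mu_a + \mu_s$, with carry-over of the remaining
  dimensionless length at voxel boundaries, so heterogeneous media need no
  rejection.
- **Absorption**: at each interaction a fraction $\mu_a/\mu_t$ of the
  packet weight is deposited; trajectories therefore sample the
  $\mu_t$ dynamics and detected weights carry the absorption correction.
- **Scattering**: Henyey–Greenstein deflection via the analytic inverse
  CDF, uniform azimuth.
- **Termination**: Russian roulette below weight 1e-4 with survival
  probability 0.1 (weight-unbiased); exit through the top or bottom face;
  laterally the medium is unbounded by default (`lateral = "escape"`
  restores absorbing side walls).
- **Detection**: circular aperture (0.3 cm diameter) on a face. NA = 1 is
  read as accept-all-angles, since the refractive index is uniform and no
  exterior medium exists; an optional NA-derived angular cut
  (`detector_spec(angular_cut = TRUE)`) is provided but is not part of the
  study configuration — enabling it was found to slightly worsen agreement
  of the attenuation decomposition while barely moving path-length
  statistics.
- **Tallies**: detected weight sum (DC), per-detected-photon records
  (exit weight, total optical path length, maximum depth), per-voxel
  fluence by the path-length estimator (optional), and the absorbed /
  exited energy budget. Energy is conserved to machine precision modulo
  roulette, which is unbiased.

Every photon gets its own RNG substream keyed by (seed, photon index)
(xoshiro256++ seeded through splitmix64). Besides making runs
reproducible regardless of how many draws each photon consumes, this
makes paired runs at the same seed *common-random-number* pairs: in a
diastole/systole pair, a photon's trajectory is identical until its first
interaction inside an artery, so most Monte Carlo noise cancels from the
small AC difference. Measured at 10⁵ photons this cuts the standard
deviation of the transmission perfusion index by roughly a factor of
eight relative to a shared-stream implementation.

The kernel was validated against the classic one-layer benchmark
(μa = 10 cm⁻¹, μs = 90 cm⁻¹, g = 0.75, thickness 0.02 cm, matched
boundaries): diffuse reflectance 0.0970 vs. the published 0.09734 and
total transmittance 0.6613 vs. 0.66096 at 3 × 10⁵ photons, both within
Monte Carlo error, with exact energy balance. Beer–Lambert ballistic
transmission, the Henyey–Greenstein moment ⟨cos θ⟩ = g, and the 1/e²
beam fraction 1 − e⁻² are exercised in the test suite.

## Experiments

`run_study()` sweeps (skin tone × SaO2 × wavelength × repeat), simulating
both cardiac phases per cell with a shared derived seed, and returns tidy
metric tables. Optode placement:

- *transmission*: source top center, detector bottom center;
- *reflection (central)*: both at top center (the nominal 1 µm detector
  offset has no physical role in this engine);
- *reflection at separation s*: the separation is split symmetrically,
  source at (−s/2, 0) and detector at (+s/2, 0). The alternative of
  keeping the source at the origin and moving only the detector was
  evaluated and gives markedly lower perfusion indices at finite
  separations (the detected photon cloud is then centered off the artery
  plane); the symmetric split reproduces the expected behavior — PI
  rising with separation, and at the largest separation equal AC/DC
  attenuation factors and tone-independent R, matching transmission.

Downstream summaries: `attenuation_factors()` computes the fractional
AC/DC attenuations of dark relative to light skin (a, b, c, d) at one
saturation; `compare_tones()` pairs the R samples by (SaO2, repeat) and
applies a two-sided Wilcoxon signed-rank test (exact sign-flip
enumeration up to 20 pairs, average ranks for ties) plus Euclidean
distances between repeat-averaged PI curves; `calibration_curve()` and
`estimate_spo2()` formalize the clinical reading error of applying a
light-skin calibration to a dark-skin R value.

## Design choices

**Epidermis on the detection face.** The published transmission-mode
attenuation of dark relative to light skin (0.89 at red, 0.51 at
infrared, SaO2 90%) exceeds the reflection-mode values (0.81–0.90).
Transmitted photons that cross the epidermis once cannot be attenuated
more than reflected photons that cross it twice; with a single epidermal
layer our engine yields 0.62/0.27. A 0.015 cm epidermis at both faces —
the physically sensible finger — reproduces 0.89/0.51 directly. We
therefore model symmetric skin; `geometry_spec(bottom_epidermis_thickness
= 0)` restores the single-sided variant.

**Laterally unbounded tissue.** The finger model is described as infinite
in x and y; terminating photons at the side walls introduces an
artificial sink (about 1.5% of launched weight in transmission) and
truncates the long-path tail of detected light. The default continues the
layer structure beyond the grid; the attenuation decomposition is
unchanged between the two conventions.

**Path statistics are unweighted by default.** `path_statistics()`
reports the median/IQR over detected photon records, capped at the first
10,000 in arrival order. With implicit capture the *physical*
distribution of detected optical path lengths weights each record by its
exit weight; `weighted = TRUE` provides this. The unweighted default
matches the operation as specified (a histogram of detected photons); the
two differ visibly (e.g. transmission red, light skin: median ≈ 1.8 cm
unweighted vs. ≈ 1.4 cm weighted), which is worth keeping in mind when
comparing against other engines whose trajectory ensembles differ.

**Wilcoxon pairing.** R samples are paired by (SaO2 level, repeat index),
giving 15 pairs for the default 5-level, 3-repeat design. The exact
pairing behind the published p-values is not stated, so significance
classifications (p above/below 0.05), not exact p-values, are the
reproducible quantity.

**Euclidean curve distances** are computed on repeat-averaged 5-point PI
curves; the "cm" unit sometimes attached to such distances is dropped as
dimensionless.

**Negative AC values** (possible at very low photon counts through Monte
Carlo noise, though largely suppressed by the paired-phase design) are
retained, not clipped, so repeat-level error bars stay unbiased.

## Problem sizes

The study that the acceptance script and test suite run is scaled down
from the original 5 × 10⁷ photons per simulation to sizes a single CPU
handles in minutes, chosen for the precision each quantity needs:

- Point quantities at SaO2 = 90% (attenuation factors, DC ratios) are
  ratios of high-precision DC tallies and are stable from ~5 × 10⁴
  photons.
- Perfusion indices use 10⁵–10⁶ photons with 3 repeats; with the
  paired-phase design the transmission red PI carries a repeat-level
  standard deviation near 0.0007 at 5 × 10⁵ photons, i.e. ~2% of its
  value.
- Full SpO2–R curve comparisons (5 saturations × 3 repeats) use
  2–4 × 10⁴ photons per simulation depending on geometry.

The acceptance script reports scaled-down targets at 10⁶ photons.

## What the generator does and does not emulate

The phantom reproduces the *stated* study conditions: layer geometry,
chromophore compositions, the systolic doubling of arterial volume, the
venous offset, both skin tones, and the 60–100% saturation sweep. It does
not model heterogeneous melanin distribution, chromophores beyond
melanin/water/hemoglobin, refractive-index mismatches, curved finger
surfaces, detector noise, or motion — so a passing suite shows the
optical mechanism (differential red attenuation in reflection geometry
biasing R, vanishing in transmission and at large source–detector
separation), not clinical calibration accuracy. Absolute detected
intensities depend on source/collector conventions that the study text
does not fully pin down; ratio quantities (PI, R, attenuation fractions)
are the robust surface, and our absolute reflection-mode PIs indeed sit
somewhat above the published ones while all ratio-based comparisons
agree.

## Known limitations

- Chromophore spectra are stored only at 660 and 940 nm; other
  wavelengths require a user configuration with extended tables.
- The bone is a single cylinder; real phalanx geometry differs.
- Implicit capture plus roulette leaves a small set of very-low-weight
  detected records; unweighted path statistics treat them equally.
- The Wilcoxon exact enumeration is O(2ⁿ) and falls back to the normal
  approximation above 20 pairs.
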