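---
title: "Fat-water MRI body-fat quantification in zebrafish: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fat-water MRI body-fat quantification in zebrafish: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Diet-induced obesity studies in adult zebrafish need a non-destructive
readout of whole-body fat. One established approach images the sacrificed
fish, fixed in an agarose-filled tube, with a chemical-shift-selective
(CHESS) sequence that acquires two magnitude images per axial slice: one
excited on the fat resonance and one on the water resonance. Summing the
per-voxel fat content over the imaged volume yields a whole-body fat volume
and, with an assumed fat density, a fat mass that can be validated against a
quantitative-NMR body-composition instrument (an EchoMRI-type device).

`zebrafat` implements this quantification chain as reusable, tested
components, together with a digital phantom simulator that provides ground
truth for every stage, and the standard morphometric indices of zebrafish
obesity phenotyping.

## Signal model

Magnitude MR images carry Rician noise: the acquired value is
$M = \sqrt{(S + n_1)^2 + n_2^2}$, where $S$ is the noise-free signal
(including the receiver gain) and $n_1, n_2$ are independent zero-mean
Gaussians of standard deviation $\sigma$. Two consequences drive the
pipeline design:

* at zero signal, $E[M] = \sigma\sqrt{\pi/2} \approx 1.2533\,\sigma$ and
  $E[M^2] = 2\sigma^2$ — background is biased upward, never zero;
* at any signal, $E[M^2] = S^2 + 2\sigma^2$ — the *squared* magnitude is
  biased by an additive constant that can be removed exactly.

### Noise estimation

`estimate_noise_sigma()` uses the second-moment estimator
$\hat\sigma = \sqrt{\overline{M^2}/2}$ over signal-free background voxels.
By default (`background = "auto"`) the four in-plane corner blocks of every
slice are used; they lie outside the agarose tube in any sensible
fish-in-tube acquisition. The corner block edge defaults to 10% of the
in-plane matrix (at least 4 px), giving tens of thousands of background
voxels for the full protocol; a minimum of 100 voxels is enforced.

### Bias correction

`correct_rician_bias()` applies power subtraction,
$M_\mathrm{corr} = \sqrt{\max(M^2 - 2\hat\sigma^2,\, 0)}$, which makes the
corrected squared intensity unbiased for $S^2$. Numerically the operand is
factored as $(M - \hat\sigma\sqrt{2})(M + \hat\sigma\sqrt{2})$ so that a
voxel sitting exactly at the subtraction boundary maps to exactly zero
rather than to a rounding residue.

### Gain normalization and the fat fraction

Each CHESS channel is acquired at its own receiver gain, so intensities are
divided by the recorded gain (`normalize_receiver_gain()`) before the
channels are compared; the attached noise estimate is rescaled with them.
The whole pipeline is therefore invariant under rescaling any channel's
intensities together with its recorded gain — a property the test suite
checks explicitly.

On the corrected, normalized pair the per-voxel fat content is expressed as
the *fat signal fraction* $F/(F+W)$, which is bounded in $[0,1]$ and is the
standard quantity of fat-fraction mapping; the classical unbounded ratio
$F/W$ is available via `ratio = "fw"` for inspection but cannot be
integrated into a volume. Voxels are foreground when their total signal
$F + W$ exceeds $k \cdot \max(\hat\sigma_F, \hat\sigma_W)$, with $k = 3$ by
default.

### The fat-channel noise gate

Power subtraction is unbiased in the squared domain but leaves a positive
residue in the magnitude domain wherever the true fat signal is zero: the
corrected fat value of a water-only voxel has expectation
$\approx 0.46\,\hat\sigma$ rather than zero. A fish occupies only a few
percent of the imaged volume, while the agarose compartment and the
threshold-passing tail of pure-noise air voxels are vast; integrating
$F/(F+W)$ over them turns this per-voxel residue into a spurious fat volume
that can exceed the fish's true fat content several-fold. The pipeline
therefore completes the background correction with a *noise gate*: voxels
whose corrected fat-channel signal does not exceed $k \cdot \hat\sigma_F$ —
i.e. is indistinguishable from rectified noise — carry fat fraction 0. The
gate uses the same multiplier $k$ as the foreground threshold, vanishes as
$\hat\sigma \to 0$ (the noise-free identity is exact), commutes with gain
rescaling, and is on by default (`fat_gate = FALSE` restores the plain
thresholded ratio). The price is sensitivity to genuinely fat-poor tissue:
voxels whose true fat signal sits below the noise floor (lean tissue at a
few percent fat fraction, at low SNR) are zeroed too, so low partial-volume
fat is undercounted. The fat-free-phantom and parameter-recovery tests
quantify both sides of this trade-off.

### From fraction to mass

`quantify_fat()` integrates the fraction map: fat volume
$= \sum_\mathrm{voxels} f_i \cdot V_\mathrm{voxel}$, and fat mass = volume
× density. The default density, 0.9 mg/mm³, is the conventional
triglyceride density; it is a parameter because the conversion from signal
volume to mass is an assumption, not a measurement. `quantify_pair()`
composes the full chain — per-channel noise estimation, bias correction,
gain normalization, fraction map, integration — and reports both channels'
noise estimates alongside the totals.

## The digital phantom

The simulator provides what live-animal data cannot: known per-voxel truth.
It models the magnitude images directly — no k-space, pulse-profile or
relaxation simulation — because the quantification chain only ever sees
magnitude stacks.

* **Grid**: the printed small-animal protocol, 16 × 16 mm in-plane FOV,
  128 × 128 matrix, 50 axial slices of 0.5 mm (voxel 0.125 × 0.125 ×
  0.5 mm = 7.8125 × 10⁻³ mm³). The slice-derived 25 mm axial span is used
  as the imaged depth.
* **Fish**: a body ellipsoid, default semi-axes 4.0 × 3.2 × 11.0 mm
  (≈ 0.6 cm³, a plump adult), carrying a subcutaneous shell depot (inner
  scale 0.90 of the surface over 80% of the body length) and a visceral
  ellipsoid depot (2.0 × 1.5 × 5.0 mm semi-axes). Depot tissue is 90% fat
  signal, lean tissue 5% — plausible adipose/lean values, configurable.
  The default truth is ≈ 180 mg fat, a realistically obese fish.
* **Agarose**: the tube (radius 5.5 mm) is water-signal only at the tissue
  water level — agarose gel is essentially water to the scanner — so it
  contributes no true fat and the quantification needs no fish mask.
* **Noise**: Rician, via two Gaussian quadrature channels; default
  $\sigma = 5$ against a signal scale of 100, i.e. peak SNR 20.
  `sigma_for_peak_snr()` converts a desired peak SNR into a sigma.
* **Reference readout**: the EchoMRI-like instrument is modelled as truth
  × (1 + e), e ~ N(0, cv²), default cv 2% — a typical precision class for
  quantitative-NMR fat measurement.

`cohort_specs()`/`make_cohort()` build validation cohorts: depot linear
dimensions are rescaled per animal (the lean compartment is untouched) so
the true fat masses hit `n` equally spaced targets; the scale factor is
solved by bisection against the voxelized truth. The default range,
40–220 mg over 8 animals, spans the ≥5-fold spread a lean-to-obese cohort
exhibits. Because the geometry work is seed-independent it can be computed
once and reused across noise realisations.

What the phantom does *not* emulate — and what passing tests therefore do
not establish about real acquisitions: coil sensitivity inhomogeneity,
chemical-shift displacement and imperfect fat/water excitation selectivity,
relaxation-weighting differences between tissues, motion or susceptibility
artefacts, and continuous tissue boundaries (truth is defined on the
acquisition grid, so partial-volume behaviour at depot edges is idealized).

## Method-comparison statistics

`validate_cohort()` reproduces the validation design of the original
experiment: quantify every phantom, pair the result with the reference
readout, and summarise agreement — squared Pearson correlation (with its
exact t-transform p-value), least-squares slope/intercept of reference on
pipeline, and the mean relative difference over positive values. The
squared correlation is the headline statistic because that is what the
original comparison reported; slope and intercept expose calibration
offsets that a correlation alone hides.

## Morphometry

* **BMI** = weight / length², g/cm² — the zebrafish-literature convention.
* **Fulton's condition index** K = 100 · weight / length³ (g, cm) — the
  fisheries convention; the factor 100 brings typical zebrafish values
  near 2.
* **Body fat %** = 100 · fat mass (g) / body weight (g).
* **Adipocyte morphometry**: traced outlines are simple polygons; area is
  the shoelace formula times the squared pixel size, orientation
  independent; self-intersecting or degenerate traces are rejected rather
  than silently measured. `adipocyte_summary()` reports per-depot counts
  per field of view and cell-area distributions, the quantities behind
  hypertrophy/hyperplasia comparisons.
* **Ration energy**: Atwater coefficients 9/4/4 kcal/g for
  fat/protein/carbohydrate, configurable. Under 9/4/4 the normal-fat
  overfeeding ration (60 mg artemia, 0.2628 kcal/day) and the high-fat
  ration (5 mg artemia + 30 mg egg yolk, 0.2220 kcal/day) differ by ~16%,
  so the package computes both and asserts no equality between them; the
  design's energy-matching claim depends on coefficients it does not state.

## Numerical choices and edge cases

* Foreground/gate multiplier `k = 3` balances noise rejection against
  sensitivity; the residual-noise fat on a pure-noise stack falls
  monotonically as `k` grows (a tested property).
* `0/0` fractions cannot arise on the foreground (total signal is strictly
  positive there); masked voxels are defined as fraction 0.
* Cohort depot scaling uses `uniroot` on the voxelized fat mass (tolerance
  1e-4 on the scale factor); achieved masses track targets to well under a
  percent at full resolution, more coarsely on toy grids where single-voxel
  granularity dominates.
* All simulation entry points take explicit integer seeds and restore the
  caller's RNG state; identical seeds give bit-identical stacks.
* NIfTI storage is 64-bit float and round-trips bit-exactly; TIFF storage
  is 32-bit samples of intensity/scale with a power-of-two scale recorded
  in the sidecar (quantization 2⁻³² of the scale). Sidecars are JSON with a
  fixed key set; missing keys are rejected by name.

## Validation problem sizes

The shipped tests exercise unit-level contracts on small grids (32 × 32 ×
10) and the end-to-end properties on the full printed protocol: noise-free
identity and gain invariance on the default phantom; fat-mass recovery at
peak SNR 20 averaged over 10 noise realisations; and the 8-phantom cohort
against the 2%-cv reference across 100 cohort seeds, requiring r² ≥ 0.95 in
at least 95% of them. `scripts/acceptance.R` recomputes all of these from
scratch at the same sizes.

## Limitations

The package quantifies fat from idealized magnitude pairs; it does not
separate water and fat from phase data (Dixon methods), model multi-peak
fat spectra, or correct relaxation weighting. The fat-mass conversion
assumes a single fat density. The phantom's realism limits are listed
above; conclusions about scanner-specific behaviour require real
acquisitions.
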