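---
title: "Estimating leaf nitrogen from reflectance indices and fluorescence ratios: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf nitrogen from reflectance indices and fluorescence ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncspec)
```

## The problem

Leaf nitrogen content (LNC, mass percent N in dry leaf tissue) is the
standard indicator used to steer nitrogen fertilization in paddy rice.
Two optical modalities track it non-destructively at the leaf scale:

* **Reflectance spectra** (350–2500 nm): nitrogen acts on leaf pigments,
  chiefly chlorophyll, which deepens the blue (~450 nm) and red (~670 nm)
  absorption wells and shifts the red edge — the steep rise between ~680
  and ~760 nm. Decades of work have distilled this into *vegetation
  indices* (VIs), arithmetic combinations of a few bands designed to
  track pigment or structure while suppressing confounders.
* **Laser-induced fluorescence** (LIF, 360–800 nm under UV excitation):
  the emission shows a blue peak near 460 nm, a red chlorophyll-a peak
  near 685 nm and a far-red peak near 735–740 nm. Ratios of these peak
  intensities (e.g. F685/F460) respond to nitrogen status through
  chlorophyll content and re-absorption.

This package implements the full comparison pipeline: a registry of 67
published VIs, the seven published fluorescence ratio parameters,
wavelet denoising, support-vector regression (SVR) with the ANOVA
kernel under 4-fold cross-validation, single-feature skill ranking, and
a three-way comparison of VI-only, fluorescence-only and combined
feature sets.

## Data model and ingest

A `Spectrum` is a strictly increasing wavelength grid plus intensities
with a declared kind (`radiance`, `reflectance`, `fluorescence`).
Reflectance is obtained from raw leaf radiance by ratio against a
near-99 % diffuse whiteboard measured under the same illumination
(`compute_reflectance`); pairing leaf and reference is the caller's
concern, since the data model carries no timestamps. Reflectance values
slightly above 1 (possible with a near-perfect panel) are kept with a
warning up to 1.5, never clipped — clipping would bias every index that
touches the affected band.

A `SampleRecord` groups the replicate spectra of one leaf (3 reflectance
and 5 fluorescence replicates under the emulated protocol) with its LNC
label and treatment metadata. Replicates are averaged pointwise before
any feature is computed.

## Wavelet denoising

The emulated study states only that spectra were "denoised and
smoothened through wavelet transform", naming no family, level or
threshold. The defaults here are ordinary 1-D denoising practice, all
exposed in `denoise_config()` so a run is reproducible from its config:

* **Wavelet**: `sym4`, the least-asymmetric orthogonal Daubechies filter
  with 4 vanishing moments (option: `db4`).
* **Level**: `floor(log2(n)) - 4`, clamped to [1, 6].
* **Threshold**: universal soft threshold `sigma * sqrt(2 log n)`, with
  `sigma` the median absolute deviation of the finest-scale detail
  coefficients divided by 0.6745.
* **Boundaries**: the signal is extended by symmetric reflection (32
  samples per side) and then transformed with a *periodized* orthogonal
  DWT. Periodization gives exact perfect reconstruction with critically
  sampled coefficients; the reflection pad keeps the two physical ends
  of the spectrum from being wrapped against each other, which would
  otherwise leak the 350 nm/2500 nm discontinuity into edge
  coefficients. Odd-length signals are padded by repeating the last
  sample, undone on reconstruction.

Denoising is applied to the replicate-averaged spectrum, not per
replicate, and is enabled by default for reflectance but disabled for
fluorescence (the synthetic emission curves are smooth at instrument
scale); both are switchable independently.

## Band lookup

Every index formula refers to bands like R670. Band values are resolved
by nearest-wavelength lookup with tolerance 1.5× the median grid
spacing, so integer-nm requests resolve on both the 1 nm reflectance and
0.5 nm fluorescence grids without interpolation, which the source
protocols never mention. Ties break toward the lower wavelength.
Derivative bands (R′, used by SR19 and SR20) are central differences,
exact for quadratics on a uniform grid, one-sided at the ends.

## The index registry

`builtin_index_catalog()` returns 67 definitions: 59 singleton indices
plus the ratio families TCARI/OSAVI, CARI/OSAVI and MCARI/OSAVI expanded
over both OSAVI variants (59 + 2 + 2 + 4 = 67). Each definition declares
its bands and evaluates a plain arithmetic expression; the test suite
checks every definition against an independently hand-coded evaluation
of the printed formulas on random spectra (agreement to 1e−12 relative).

Printed-formula ambiguities are handled explicitly rather than silently:

* **MSR1/MSR2** are printed without the radical that defines the
  modified simple ratio; the canonical `(ρ − 1)/sqrt(ρ + 1)` is the
  default and a `literal` catalog mode implements the printed
  `(ρ − 1)/(ρ + 1)`.
* **REP** (red-edge position by linear interpolation) is printed with a
  `+` in the denominator, which destroys its interpolation meaning; the
  canonical `R760 − R710` is the default, the printed form available as
  `literal`. On physically shaped spectra the canonical REP stays inside
  the 700–760 nm red edge.
* **OSAVI1** is printed with `R700` in the denominator where its
  numerator and its companion OSAVI2 use matched band pairs; this is
  read as a typo for `R800` and the canonical form is implemented (the
  reading is recorded in the catalog audit dump, `catalog_dump()`).
* **SR12–SR14** keep their printed band-product denominators and
  **NDI5/NDI6** their printed difference denominators: these match
  their original publications and are not treated as typos.

Undefined values (zero denominator, negative radicand) become `NA`
sentinels with a warning — in batch computation a degenerate spectrum
can never abort the other 66 columns, and coverage gaps (e.g. a spectrum
truncated at 1200 nm cannot supply R1720) likewise yield sentinels.
Downstream model assembly drops sentinel rows per feature subset only.

## Fluorescence parameters

Band intensity is the mean over a ±2.5 nm window (11 channels at
0.5 nm) rather than a single channel, for robustness to single-channel
noise; a half-window below the grid spacing degenerates to the nearest
channel, recovering the single-channel convention some source studies
may have used. The seven parameters are the five ratios F_fr/F685,
F_fr/F460, F685/F460, F685/F525, F_fr/F525 and the two normalized
differences (F460 − F685)/(F460 + F685), (F460 − F_fr)/(F460 + F_fr).
The far-red center `F_fr` defaults to 740 nm but the literature names
both 735 and 740 for this peak, so the center is a config alias and the
feature names record the value used. All five ratios are scale-invariant
and the two normalized differences are bounded in [−1, 1] for positive
spectra — both properties are tested.

`detect_peaks()` searches the windows 440–465, 680–690 and 730–740 nm
for maxima of a lightly smoothed (5-point running mean) curve and keeps
only strict local maxima, so monotone spectra yield no peaks.

## Synthetic data: the stated world

No field measurements are deposited, so the pipeline is exercised on a
generator whose structure mirrors what the optical literature says the
data look like. Per sample, LNC is drawn uniformly on 1.5–4.0 % N and
mapped to a latent relative chlorophyll level (affine in LNC, scaled by
a `coupling` knob, default 0.8, with lognormal biological scatter).
Chlorophyll then drives:

* **Reflectance** (350–2500 nm, 1 nm): visible baseline 0.10, logistic
  red edge rising to a NIR plateau near 0.48, whose center shifts from
  708 to 722 nm with chlorophyll; Gaussian absorption wells at 450 and
  670 nm whose depths grow with chlorophyll; fixed water dips at 1450
  and 1940 nm; additive channel noise (sd 0.005) per replicate; values
  clipped to (0.001, 0.999).
* **Fluorescence** (360–800 nm, 0.5 nm): three Gaussians at 460, 685,
  735 nm (widths 12, 9, 14 nm) over a weak broad background; the blue
  amplitude is fixed while A685/A460 and A735/A460 increase with LNC;
  multiplicative lognormal channel noise (relative sd 0.02) per
  replicate.

Design choices worth spelling out:

* **One noise knob per modality.** Replicate-level instrument noise and
  sample-level biological scatter are yoked: the chlorophyll scatter sd
  is 36× the reflectance noise sd and the peak-ratio scatter sd 5× the
  fluorescence noise sd. This keeps "noise → 0" meaningful — it
  silences every stochastic term at once, so the zero-noise monotonicity
  properties are exact — and makes the noise dose-response test a single
  axis. The multipliers were fixed once, before the acceptance tests
  were first run, so that single-feature skill lands in the 0.7–0.9 R²
  regime published for leaf-scale nitrogen spectroscopy rather than at
  the ceiling; with channel noise largely removed by replicate averaging
  and denoising, this scatter is what limits attainable accuracy.
* **Independent modality noise.** Reflectance and fluorescence scatter
  are drawn independently, so combining modalities genuinely adds
  information; the combined-model advantage measured by the acceptance
  tests is a property of the world, not an arithmetic tautology.
* **Null case.** `coupling = 0` severs both links; every feature's
  association with LNC then reflects only sampling noise, which the
  null-control acceptance test bounds.

What the generator does **not** emulate: radiative-transfer leaf optics,
canopy geometry, instrument line shapes, fluorescence re-absorption, or
correlated noise across wavelengths. A green acceptance suite therefore
establishes that the pipeline recovers the structure this world encodes
— not that the published field-data accuracies are reproduced; those
rest on undeposited measurements.

## Modeling

The SVR uses the ANOVA kernel
`K(x, y) = (Σ_i exp(−γ (x_i − y_i)²))^d`, symmetric with diagonal `p^d`
and positive semidefinite for `d = 1`. The ε-insensitive dual is solved
by sequential minimal optimization (maximal-violating-pair selection,
implemented in C++), since no SVM package is assumed in the
environment. Hyperparameters are unprinted in the emulated study; the
frozen defaults are `C = 10`, `ε = 0.1` (on the %N scale), `d = 1`,
`γ = 1/p`, with per-feature standardization whose statistics come from
training rows only.

Cross-validation is one seeded random partition into 4 balanced folds;
out-of-fold predictions are pooled and each sample is predicted exactly
once. The headline R² is the squared Pearson correlation of pooled
predictions with observations (the "regression of predicted on
measured" convention); the identity-line form 1 − SS_res/SS_tot is also
reported as `r2_identity`. RMSE is in %N; RE = 100·RMSE/mean(observed).
The three default feature sets — `vi4` = {TVI, MTVI1, MTVI2, MSAVI},
`fluor2` = {F740/F460, F685/F460}, `combined` = their union — share one
fold assignment so comparisons are paired.

Degenerate inputs are contracts, not accidents: constant labels produce
constant predictions with a warning; zero-variance predictions give
r2 = 0 by convention; sentinel rows are dropped per subset with a
recorded count, so subsets may differ in n.

## Worked example

```{r example, eval = FALSE}
ds  <- generate_dataset(synthetic_config(n_samples = 60, seed = 1))
ft  <- assemble_features(ds)
res <- run_experiment(features = ft, labels = sample_labels(ds), seed = 2)
res$combined
```

On the frozen default world this prints R² near 0.94 for the combined
set against roughly 0.85 (vi4) and 0.87 (fluor2) — the same qualitative
ordering, combined > either single modality, that motivates fusing the
two measurements.

## Known limitations

* The SMO stopping tolerance (1e−3 on the gradient gap) is adequate for
  the %N label scale but is not adaptive; rescale labels if you work in
  very different units.
* For `d > 1` the ANOVA kernel is not guaranteed positive semidefinite;
  the solver guards the pair curvature but no spectral correction is
  applied.
* The wavelet threshold assumes roughly homoskedastic channel noise;
  strongly wavelength-dependent noise would need a level-dependent
  threshold, which is not implemented.
* `read_spectrum` expects two-column text; vendor binary formats are out
  of scope by design.
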