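---
title: "Methods: spectral preprocessing, band statistics and classification in fgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral preprocessing, band statistics and classification in fgrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`fgrs` implements the data-analysis half of fluorescence-guided Raman
spectroscopy (FGRS): single-cell Raman spectra, acquired at locations
pinpointed by a fluorescently tagged protein (Connexin 43, Cx43), are
preprocessed, compared band by band between cells with high and low Cx43
content, reduced to the most discriminative wavenumbers, and classified
with Gaussian-kernel support vector machines. Because raw single-cell
spectra of this kind are rarely public, the package pairs the pipeline
with a synthetic spectrum generator whose band-level effect sizes are
*calibrated through the full pipeline*, so that every stage can be
validated quantitatively on data with known ground truth.

```{r setup, message = FALSE}
library(fgrs)
```

## Preprocessing model

A measured spectrum is modeled as Raman bands on top of a broad
fluorescence background with additive detector noise and occasional
cosmic-ray spikes. The chain runs in fixed order: crop, baseline, despike,
normalize.

**Fingerprint crop.** Analysis is restricted to 400–1800 cm⁻¹, the region
carrying most biomolecular vibrational information. The axis is data, not a
constant: instrument axes are non-uniform at roughly 2–3 cm⁻¹ per CCD
pixel, so every file carries its own wavenumber column.

**Asymmetric least squares (AsLS) baseline.** The baseline `z` minimizes

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_j (\Delta^2 z_j)^2,$$

iterating `w_i <- p` if `y_i > z_i`, else `1 - p`. Positive excursions
(Raman bands) are nearly ignored (`p = 0.01`) while the smooth background
is tracked; `lambda = 1e5` sets the baseline stiffness on the ~2.5 cm⁻¹
channel spacing of a fingerprint axis. Defaults (`lam = 1e5`,
`asym_p = 0.01`, `max_iter = 20`, `tol = 1e-6`) are the values
practitioners use for fingerprint Raman; none are data-fitted. The
pentadiagonal normal equations are solved by a banded LDLᵀ factorization in
C++ with one step of iterative refinement — for small `p` and large
`lambda` the system's condition number approaches 1e8, and refinement keeps
the constant-spectrum fixed point exact to below 1e-8. The solver is
verified against a dense `solve()` of the same normal equations.

**Cosmic-ray rejection.** Cosmic rays are sharp spikes whose intensity
exceeds anything Raman-physical in a cell spectrum. The rule: a local
maximum is removed when (a) its full width at half *prominence* spans at
most 3 channels, and (b) both its height and its topographic prominence
exceed the Amide I reference intensity, the window maximum over
1640–1680 cm⁻¹. Requiring prominence as well as height matters: on spectra
whose global maximum (the CH₂ band near 1449 cm⁻¹) is taller than Amide I,
noise wiggles riding on that peak's flank have height above the reference
but negligible prominence, and a height-only rule would clip them. The
reference is computed with all sharp candidate spans excluded from the
window, so a spike landing inside the Amide window cannot mask itself.
Spikes are replaced by linear interpolation across their span and the scan
repeats until stable, which makes the operation idempotent. Despiking runs
after baseline removal and *before* normalization, so the threshold lives
on the physical (baseline-corrected) intensity scale.

**Normalization.** Each spectrum is divided by its greatest intensity, so
the maximum is exactly 1. The phrase "vector normalized to the greatest
spectral intensity" conflates two conventions; the package implements
max-normalization as the default and exposes unit-L2 (`method = "l2"`)
without asserting which a given instrument pipeline used. A consequence
worth knowing: the band containing the normalization maximum has intensity
exactly 1 in every spectrum, so its between-class effect size is 0 by
construction — `band_stats_table()` reports 0 rather than failing there.

## Peak analysis

Peaks are local maxima ranked by topographic prominence: the height above
the higher of the two lowest saddles separating the peak from higher
terrain (or the signal ends). Plateau maxima take the leftmost channel, a
deterministic tie-break. The implementation is checked against an
exhaustive oracle on thousands of random signals. Mean spectra are
compared at a prominence threshold of 0.01 (transfected vs control lines)
or 0.05 (noisier wild-type cell lines), on the normalized intensity scale;
`compare_peak_presence()` matches peak centers within 5 cm⁻¹, reflecting
that corresponding bands in different cell states print a few cm⁻¹ apart
(e.g. 746/750).

Band intensities are the maximum over the band's window: the printed range
for range bands (e.g. 1235–1240), a ±4 cm⁻¹ window for point bands. The
half-window is a package default (the extraction window is rarely printed
in papers); with ~2.5 cm⁻¹ spacing it covers 3–4 channels.

## Band statistics and channel selection

Per band, the two classes are compared with the Mann–Whitney U test
(midranks; exact enumeration of all group assignments when both groups
have at most 8 samples, ties included; otherwise a tie-corrected normal
approximation with continuity correction) and the pooled-SD Cohen's d

$$d = \frac{\bar{x}_1 - \bar{x}_2}{s_p}, \qquad
s_p^2 = \frac{(n_1 - 1) s_1^2 + (n_2 - 1) s_2^2}{n_1 + n_2 - 2}.$$

Tables report |d|; the sign is kept internally. Stars encode `* p < 0.05`,
`** p ≤ 1e-2`, `*** p ≤ 1e-3`, two-sided, with no multiple-testing
correction (the band panel is small and fixed a priori). p-values are
cross-checked against `wilcox.test()` and full enumeration.

The double-SD channel selection uses a *scalar* threshold: twice the
across-channel standard deviation of the absolute difference spectrum
|mean_high − mean_low|. A single horizontal cutoff is what a dashed
threshold line over a difference spectrum depicts; the alternative
per-channel pooled-SD rule is available (`method = "per_channel"`) but is
not the default, since a per-channel rule cannot be drawn as one line and
selects a qualitatively different channel set.

## Classification

Binary soft-margin SVMs with the Gaussian kernel
`K(u, v) = exp(-||u - v||² / s²)` are trained on either all channels or the
double-SD-selected subset. The kernel scale follows the medium/coarse
convention: `s = sqrt(P)` (medium) or `4 sqrt(P)` (coarse) for `P`
predictors, i.e. `gamma = 1/s²`; features are standardized with training
means/SDs (SD floor 1e-8 for constant channels) and the box constraint is
C = 1 — the classifier-app presets that accompany this convention. Fitting
is delegated to libsvm via `e1071::svm()`; the package fixes the score
orientation so that a positive decision value always predicts the
high-Cx43 class, with ties at exactly 0 going to the negative class.

The protocol balances classes by seeded subsampling to the smaller class
size, splits 80/20 stratified, and reports "training" metrics as stratified
five-fold cross-validation pooled over folds on the 80% portion. The
original protocol sentence — 80% training, 20% "held out for a five-fold
cross validation" — cannot mean CV on the 20%; pooled CV on the training
portion is the standard reading, and the 20% holdout remains available as
an untouched evaluation set. Each testing scenario pools its low-class
groups and subsamples (seeded) to match the high-class count, so reported
metrics are never inflated by imbalance. ROC curves sweep all decision
thresholds (tied scores grouped); AUC is the trapezoidal area, equal to the
tie-adjusted rank statistic and invariant under monotone score transforms,
cross-checked against `pROC`.

## The synthetic generator and its calibration

Each synthetic spectrum is

> background + Σ pseudo-Voigt band lines + iid Gaussian noise(0, σ) +
> Poisson cosmic-ray spikes,

with the high-Cx43 class receiving an additive amplitude contrast `delta`
on each driven band. Study conditions are fixed in `synth_config()`: 571
uniform channels over 400–1800 cm⁻¹, 95 spectra per class, σ = 0.01 a.u.
(~1% of the strongest band — a realistic SNR for 30 s single-cell
integrations), flat 0.2 a.u. backgrounds for both classes (a
blue-emitting tag contributes no fluorescence to the 532 nm Raman window;
an eGFP-like broad hump is available for robustness experiments), spike
rate 0.05 per spectrum at twice the Amide I intensity.

Band shapes are pseudo-Voigt (η = 0.5) with 12 cm⁻¹ FWHM for isolated
bands. Three band pairs overlap in their extraction windows (750 with
752–760; 1580 with 1582; the amide I range 1654–1660 with the lipid C=C
band at 1660) yet carry different published effect sizes. With
max-over-window extraction, two windows whose maxima fall on the same
channel recover *identical* d — no contrast assignment can separate them.
The generator therefore realizes these pairs as narrower lines (6–8 cm⁻¹)
placed so that each window's maximum lands on its own band's line (amide I
near 1655, the lipid line near 1662.5; both inside their windows), with
amplitude ratios chosen so the argmax assignment is stable against noise.
This is the one place where the generator's geometry is driven by the
needs of the recovery analysis rather than spectroscopic convention, and
it is documented as such.

The CH₂ deformation band at 1449 cm⁻¹ is the tallest band (amplitude 1.0),
as in real cell spectra, and therefore serves as the normalization
reference; its programmed contrast is 0.

**Calibration.** `delta` values cannot be set analytically because the
pipeline itself (baseline residuals, despiking, max-normalization,
max-over-window extraction) reshapes both signal and noise.
`calibrate_band_deltas()` therefore measures the recovered mean |d|
through the *full* pipeline and iterates the proportional update
`delta <- delta * target / recovered`, which converges quickly because the
recovered d is nearly linear in delta (the extraction argmax is a fixed
channel). Rounds use 24/48/96/160 replicates; the growing schedule spends
replicates where they matter, leaving a final Monte-Carlo calibration SE
of about 0.015 in d units. The headline validation then measures the mean
|d| per band over 200 *fresh* replicates — deliberately not the
calibration seeds — with tolerance ±0.05; total Monte-Carlo error is
≈ 0.02 SD, so the check is demanding but stable.

**What the generator does not emulate.** Channel noise is independent;
real spectra have correlated baseline residuals and multiplicative
(shot-noise) components. Cell-to-cell biological variation is reduced to
band-amplitude contrasts plus (for the cell-line profiles) fixed per-line
multipliers and background shifts. Passing recovery tests therefore shows
that the *pipeline's statistics are unbiased under the stated noise
model* — not that the pipeline is robust to every artifact of real
instruments. The cell-line suite (`make_cell_line_profiles()`, seven sets:
transfected/control for training, a background-shifted wildtype for
testing 1, one high-like and three low-like lines for testing 2) exists to
probe transfer across moderate distribution shift, with perturbation sizes
(5% amplitude jitter, 0.1 a.u. background hump) chosen to be noticeable
but not class-destroying.

## Numerical choices and degenerate inputs

* Exact Mann–Whitney enumeration switches on at group sizes ≤ 8
  (C(16,8) = 12 870 assignments — still instant); above that the
  tie-corrected normal approximation agrees with the exact p to < 0.02.
* `cohens_d()` refuses a zero pooled SD; the band-table wrapper maps the
  all-constant case (the normalization band) to d = 0.
* Despiking treats axis-boundary channels as candidate spikes (a cosmic
  ray on the first or last channel is bounded by its one real side);
  `find_peaks()` itself reports interior peaks only, per the topographic
  definition.
* All randomness flows through explicit seeds; derived child seeds stay
  below 2³¹. Reruns of `run_pipeline()` with one config and seed are
  byte-identical across CSV outputs (the manifest's timing block is the
  only run-dependent field).
* Problem sizes in the shipped validation suite: 200 replicates of
  95 + 95 spectra for effect-size recovery, 20 seeds for classifier
  null/contrast behaviour, 1000 random signals for the prominence oracle,
  exhaustive enumeration up to 8 + 8 for the rank-sum test. These sizes
  were chosen so the whole suite completes in minutes on one CPU while
  keeping Monte-Carlo error well inside the stated tolerances.

## Known limitations

* The double-SD rule's scalar threshold is one of two defensible readings
  of "exceeded the double standard deviation"; with unreleased raw data
  the printed count of 82 selected channels cannot adjudicate, so the
  package ships both and defaults to the scalar rule.
* Prominence thresholds (0.01/0.05) are applied to mean spectra, the usage
  that matches presence/absence comparisons; per-spectrum peak calling is
  possible but noisier.
* The generator's crowded-band geometry (see above) trades spectroscopic
  literalism for identifiable band-level ground truth.
* No multiple-testing correction, wavelet/polynomial baselines, peak
  fitting, or probability calibration — all deliberately out of scope.
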