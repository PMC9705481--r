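---
title: "Multicenter DWI/T2w harmonization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicenter DWI/T2w harmonization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcDWI)
```

`mcDWI` implements the analysis chain of a multicenter quantitative MRI
harmonization study: central ADC mapping, temperature-corrected phantom QA,
ROI-level reproducibility statistics, and a radiomics
selection/classification chain, all exercised on a seeded synthetic
multi-site generator. This vignette explains the underlying models, the
tunable parameters, and the design decisions that were genuinely open.

## The diffusion signal model and the central ADC fit

The simulator draws per-voxel DWI magnitude signals from a two-compartment
(IVIM-like) decay,

$$S(b) = g \cdot \beta(x)\, S_0 \left[(1-f)\,e^{-b\,\mathrm{ADC}} +
  f\,e^{-b\,D^*}\right],$$

with ADC and the pseudo-diffusion coefficient $D^*$ in µm²/s (converted to
mm²/s against $b$ in s/mm²), a per-site global gain $g$, a smooth
multiplicative bias field $\beta(x)$, and Rician noise of scale
$\sigma/\sqrt{\text{averages}_b}$ added per $b$-volume (magnitude MR noise;
the division reflects per-$b$ signal averaging, default 1/6/23 averages at
$b$ = 100/500/900 s/mm²).

The central estimator (`computeADCMap()`) is deliberately simpler than the
generator: an unweighted ordinary least-squares fit of $\ln S(b)$ against
$b$, per voxel, with ADC = −slope. Three choices deserve explanation:

- **b = 0 is omitted by default.** With a perfusion fraction $f > 0$ and
  $D^* \gg \mathrm{ADC}$, the perfusion compartment contributes
  appreciably only near $b = 0$; including it steepens the apparent decay
  and biases the ADC upward. Fitting on $b \ge 100$ restores comparability
  with sites whose scanner software could not drop $b = 0$. The package
  reproduces this mechanism (the `includes_b0` site flag, and a
  `perfusion_b0_adc_increase_pct` around +13 % on the default IVIM tissue
  in the acceptance script).
- **Unweighted log-space OLS, no clamping.** Signal averages affect only
  the synthesis noise, not fit weights; voxels with any non-positive
  signal are excluded entirely (a validity mask keeps exclusions
  auditable) rather than clamped, which would bias the log transform.
  Negative fitted slopes are retained so QA statistics see the raw
  estimator.
- **Units.** ADC is reported in µm²/s (1 µm²/s = 10⁻⁶ mm²/s) throughout.

## Phantom QA and temperature correction

The phantom scenario emulates a 200 mm PVP-solution sphere whose true ADC
follows a linear temperature model
$\mathrm{ADC}(T) = \mathrm{ADC}_{20}(1 + \alpha(T-20))$. The correction
(`temperatureCorrect()`) divides each measured site mean by the same ratio,
so the simulate-at-$T$/correct-at-$T$ round trip is exact by construction —
the point of the three-step procedure is precisely that a phantom need not
be in thermal equilibrium. The slope defaults to α = 0.024 /°C (a
water-like value) and is a configuration parameter (`calibrationCurve()`,
or YAML via `readCalibrationCurve()`) to be replaced by the phantom
manufacturer's calibration; the validity range defaults to 15–30 °C.

The automatic phantom ROI is a disc of fixed 60 mm diameter (large enough
for stable statistics, small enough to avoid edge/partial-volume voxels of
a 200 mm sphere) centered on the intensity centroid of the central slice,
rasterized as a fixed pixel count so its area is identical across sites
with equal spacing.

Cross-site dispersion uses the sample SD ($n-1$): `crossSiteStats()`
reports mean, SD, CoV = SD/mean and the maximum deviation
(max − min)/mean·100. The denominator of the maximum deviation is the
cross-site mean — a stipulation, since only the numerator is standard.
Because the printed ± values of phantom summaries can be read either as
cross-site SDs or within-ROI SDs, `phantomQA()` reports both
(`central_sd`/`scanner_sd` per site, plus the cross-site statistics).

## ROI scheme and reproducibility statistics

Volunteer-style analyses use 11 circular 2D ROIs of 250 mm²
(radius $\sqrt{250/\pi} \approx 8.92$ mm) in 5 organ classes: left/right
kidney, liver segments 4/7/8, two spleen positions, left/right quadratus
lumborum, lumbar vertebrae 1/2. Discs are rasterized as the
`round(area/pixelArea)` pixel centers nearest the disc center, which keeps
the rasterized area within half a pixel of 250 mm² for any in-plane
spacing up to the disc radius (the naive center-inclusion rule can drift
outside a ±5 % band at coarse spacing).

Bland–Altman percentage differences use the pair mean as denominator
(`100(m_2-m_1)/((m_1+m_2)/2)`), the standard form for relative
Bland–Altman plots; the first-measurement denominator is reported
alongside. Traveling-volunteer deviations are anchored at the reference
site (`(m_{site}-m_{ref})/m_{ref}`), whose own rows are exactly zero.

`pairedWilcoxon()` drops zero differences (Wilcoxon's original rule), uses
the exact signed-rank null distribution for ≤ 25 untied pairs and a
tie-corrected normal approximation otherwise, and applies the
Bonferroni-adjusted significance level 0.007.

## Radiomics chain

**Resampling.** Volumes are resampled to 1×1×1 mm by separable trilinear
interpolation (nearest-neighbor for masks and labels), center-aligned, the
physical extent preserved within one voxel.

**Histogram matching** (T2w only, by default). Foreground voxels (above
the volume mean — mirroring the referenced filter's threshold-at-mean
default) are summarized by a 128-level histogram; 10 evenly spaced
quantile landmarks of the source are mapped to the reference landmarks by
a monotone piecewise-linear transfer, extended linearly beyond the outer
landmarks so that an affine intensity distortion stays corrected in the
tails. ADC is already a quantitative scale, so its stream skips matching
by default (configurable).

**Features.** The built-in extractor computes 18 first-order and 8
co-occurrence features per ROI (26 columns). Conventions, chosen so the
hand-computed test oracles agree and documented here because definitions
vary across radiomics software: population ($n$) variance; skewness and
kurtosis of constant ROIs set to 0; entropy/uniformity on a fixed 32-bin
discretization of the ROI range; GLCM with symmetric accumulation over the
13 unique distance-1 3D offsets, features averaged over offsets, and the
degenerate single-level correlation set to 1. Fixed bin *count* (not
width) keeps bins aligned across sites after histogram matching. External
extractors can substitute any table with the same key columns.

**Two-stage selection.** Stage one scores each feature by the mean
absolute Pearson correlation, over all unordered site pairs, of the
per-site vectors of feature values indexed by anatomical position. This is
the reading of "stability across sites for each anatomical position" that
yields a per-feature correlation from a single traveling volunteer, and it
is recorded prominently because other readings exist. Pearson invariance
under per-site affine rescaling is the designed reason the score tolerates
vendor gain differences. Features scoring ≥ 0.75 survive (the threshold
itself survives); zero-variance site vectors contribute $|r| = 0$ with a
logged message. Stage two ranks survivors by one-way ANOVA F against the
organ class and keeps the top 15, ties broken lexicographically. For
test–retest selection, time-1 rows only are used.

## Classification and distance analysis

Random forests (1000 trees, depth 10) run 10 leave-one-site-out rounds and
5 test–retest rounds, each repetition with its own sub-seed; accuracy SD
is computed across repetitions per site, and a shared-seed mode
(`perRunSeeds = FALSE`) reproduces exactly-zero SDs for comparison. ROC
curves are one-vs-rest per organ, linearly interpolated on a fixed
101-point FPR grid, anchored at (0, 0), and macro-averaged over runs ×
organs × sites.

The first Wasserstein distance between ROI intensity samples is computed
exactly as the integral of the absolute ECDF difference (bin-free; binned
input works too since a histogram is itself a sample with weights).
Matrices are min–max normalized over off-diagonal entries with the
diagonal forced to zero. The t-SNE embedding (exact, seeded, perplexity
auto-shrunk to $(n-1)/3$ when rows are few) is visualization-only and its
units are arbitrary.

## What the synthetic generator emulates — and what it does not

Per site the generator draws a gain (0.6–1.8), a Rician noise scale
(10–25 intensity units), and a bias-field amplitude (0.02–0.18); one site
is the reference, and one site (when ≥ 7 are generated) requires b = 0 in
its inline fit. Organs are axis-aligned ellipsoids on a 5 mm-slice grid
(52×52×10 voxels at 2.6×2.6×5 mm for volunteers; 84×84×16 for the
phantom); anatomy realism is out of scope because only ROI statistics
matter downstream. Organ parameters: liver ADC 965 µm²/s with 22 %
voxelwise heterogeneity and liver T2w gray value 480 anchor the
simulation in the regime of healthy upper-abdominal measurements; the
remaining organ values (kidney 1900, spleen 880, muscle 1500, vertebra
550 µm²/s, with analogous T2w/S0/perfusion entries) are documented
stipulations chosen once for realistic, distinct contrasts — they are not
measured facts. Test–retest re-seeds the noise and jitters ROI centers by
≤ 3 mm (re-positioning surrogate); different sites get volunteers with
±5 % organ-level offsets; the traveling volunteer is one fixed tissue map
imaged under every site profile.

The default ROI layout keeps same-slice centers ≥ 2·radius + 2·jitter
apart and organ in-plane semi-axes at 12.5 mm ≥ 8.92 + 3 mm, so jittered
discs can neither overlap nor leave their organ — the no-systematic-offset
property of test–retest differences holds by construction. Because the
jitter is drawn per site, ROI pairs within a site are correlated; the
no-offset check therefore replicates over generator seeds rather than
treating the 77 pairs as independent.

Passing tests on these data show that the estimators, the correction, the
selection logic and the classifiers behave as designed under the stated
noise model. They do not show robustness to real-world effects the
generator omits: EPI distortion and eddy currents, motion, k-space
artifacts, field-strength-dependent relaxation, vendor reconstruction
pipelines, partial-volume anatomy, or inter-observer ROI placement. On the
default synthetic volunteer the organ classes are fully separable from
ADC features (LOSO accuracy 1.0), which is cleaner than any in-vivo
setting; the informative comparisons are relative ones — corrected vs
uncorrected CoV, b0-inclusive vs b0-free fits, ADC vs unmatched T2w
accuracy, within- vs between-organ distances.

## Numerical choices and degenerate inputs

- Sub-seeds for noise volumes, scenarios and classifier runs are derived
  deterministically from the master seed (kept below 2³¹).
- Non-positive signals: voxel excluded from the ADC fit (masked), never
  clamped; empty ROIs are flagged rows, not silent NaNs.
- Constant volumes make histogram matching degenerate → error; constant
  features get F = 0 and can never outrank a varying feature; all-zero
  difference vectors give Wilcoxon p = 1 with a warning.
- Tie-breaks: feature ranking ties resolve lexicographically; forest
  prediction ties resolve by first class index (seeded, hence
  reproducible).
- Problem sizes used by the test suite and the acceptance script (chosen
  as the package's default study size): 7 sites, 11 ROIs, 52×52×10
  volunteer grids, 10⁴-voxel bias checks, 10 LOSO / 5 test–retest
  repetitions, 10 seeds for recovery properties.

## Known limitations

- The built-in extractor is a compact, defined 26-feature set, not a full
  radiomics library; wavelet/LoG-filtered and shape features are out of
  scope (fixed circular ROIs make shape uninformative).
- The calibration slope is a single linear coefficient; curved
  temperature dependencies need an external calibration table.
- The Wilcoxon implementation switches to a normal approximation whenever
  absolute differences tie, even for small n.
- DICOM ingestion, acquisition physics and DCE-MRI are out of scope;
  input is NIfTI (one file per b-value) plus a JSON index.
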