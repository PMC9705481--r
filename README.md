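# mcDWI — multicenter DWI/T2w harmonization and reproducibility analysis

Quantitative diffusion-weighted MRI (DWI) is a candidate response biomarker
for oncologic multicenter trials, but apparent diffusion coefficient (ADC)
values measured on scanners from different vendors disagree unless
acquisition and post-processing are harmonized. `mcDWI` implements the full
analysis chain of a multicenter harmonization study for researchers running
(or simulating) multi-site quantitative MRI comparisons:

- **Central ADC computation** — per voxel, ln S(b) is fitted to a linear
  function of b by ordinary least squares and ADC = −slope (in µm²/s,
  ≡ 10⁻⁶ mm²/s), omitting b = 0 s/mm² so that perfusion (IVIM) effects do
  not inflate the estimate: S(b) ≈ S₀·e^(−b·ADC).
- **Phantom QA** — automatic fixed-size ROI placement on a PVP-sphere
  phantom, normalization of each site's ADC to 20 °C via a calibration
  curve ADC(T) = ADC₂₀·(1 + α(T − 20)), and cross-site dispersion
  statistics: mean, SD, CoV = SD/mean, and maximum deviation
  (max − min)/mean.
- **Reproducibility statistics** — ROI means over 11 anatomical positions
  (250 mm² discs in kidney, liver, spleen, muscle, vertebra), Bland–Altman
  test–retest analysis with pair-mean percentage differences, reference-site
  anchored traveling-volunteer deviations, and an exact paired Wilcoxon
  signed-rank test evaluated at a Bonferroni-adjusted level (p < 0.007).
- **Radiomics harmonization chain** — isotropic 1 mm resampling, landmark
  histogram matching (10 match points, 128 levels) to a reference site,
  a built-in 26-feature extractor (18 first-order + 8 GLCM), and two-stage
  feature selection: cross-site stability filtering (mean |Pearson r| over
  site pairs, threshold 0.75) followed by one-way ANOVA F ranking (N = 15).
- **Classification experiments** — seeded random forests (1000 trees,
  depth 10) in 10-run leave-one-site-out cross-validation and 5-run
  test–retest prediction, macro-averaged one-vs-rest ROC/AUC, a seeded
  t-SNE embedding, and first-Wasserstein distance matrices between ROI
  intensity histograms (min–max normalized to [0, 1]).
- **Synthetic multi-site generator** — seeded phantom, test–retest and
  traveling-volunteer study designs with per-site gain, Rician noise, bias
  fields and an optional perfusion component, so the whole pipeline is
  testable end to end without any scanner data.

## Worked example

Seven-site phantom QA on synthetic data:

```r
library(mcDWI)
manifest <- generateSiteManifest(7, seed = 1)
study    <- generateStudy(manifest, "phantom", seed = 1)   # 7 sites, 18-24 °C
qa       <- phantomQA(study, calibrationCurve(alpha = 0.024))
qa$stats$central_raw
#> Cross-site ADC: 1682 +/- 65 um^2/s (CoV 0.0386, max dev 11.1%)
qa$stats$central_corrected
#> Cross-site ADC: 1600 +/- 1 um^2/s (CoV 0.0005, max dev 0.1%)
```

Before temperature correction the seven sites disagree by 11 % (their
phantoms sit at different temperatures, 18–24 °C); transporting every ADC to
the common 20 °C reference with the calibration curve collapses the spread
to 0.1 %, recovering the nominal 1600 µm²/s of the phantom solution.

The volunteer-style chain (traveling volunteer, ADC stream):

```r
traveling <- generateStudy(manifest, "traveling_volunteer", seed = 1)
feats <- studyFeatures(traveling, "adc")      # resample, extract 26 features
sel   <- selectFeatures(feats)                # stability >= 0.75, top-15 by F
rep   <- losoCV(feats, sel$selected, nRuns = 10, seed = 1)
rep$overall_accuracy
#> [1] 1
```

On the default synthetic volunteer the five organ classes are fully
separable from site-stable ADC features, so leave-one-site-out accuracy is
1.0; T2w features without histogram matching score lower — the qualitative
ordering the harmonization is designed to produce.

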