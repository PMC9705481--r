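Package: mcDWI
Title: Multicenter Diffusion-Weighted MRI Harmonization and Reproducibility Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and reducing cross-vendor variation in
    multicenter diffusion-weighted MRI (DWI) and single-shot T2-weighted
    imaging. Implements central apparent diffusion coefficient (ADC) map
    computation from multi-b-value DWI, temperature-corrected phantom quality
    assurance with cross-site dispersion statistics, ROI-level test-retest and
    traveling-volunteer reproducibility analysis (Bland-Altman, coefficient of
    variation, exact paired Wilcoxon tests), and a radiomics harmonization
    chain: isotropic resampling, landmark-based histogram matching, first-order
    and gray-level co-occurrence feature extraction, two-stage stability and
    ANOVA feature selection, leave-one-site-out random-forest classification,
    ROC averaging, t-SNE embedding, and Wasserstein histogram-distance
    analysis. A seeded synthetic multi-site data generator emulating phantom,
    test-retest, and traveling-volunteer study designs makes the full pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    ranger,
    pROC
Suggests: testthat (>= 3.0.0), yaml, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
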