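Package: dectexture
Title: Texture and Spectral Quantification for Dual-Energy CT Virtual
    Monochromatic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiparametric analysis of thyroid nodules on dual-energy CT
    virtual monochromatic images (VMIs). Computes 41 texture features per
    nodule and energy (12 histogram, 5 gray-level co-occurrence, 11
    gray-level run-length, 4 gray-level gradient, 9 Laws energy features),
    quantifies region-of-interest iodine concentration and the slope of the
    Hounsfield-unit attenuation curve across VMI energies, and compares
    benign and malignant groups with variance-gated pooled/Satterthwaite
    two-sample t-tests and empirical ROC analysis with Youden-optimal
    cut-offs. Includes a synthetic DECT phantom generator with
    class-dependent iodine content and spatial heterogeneity so the full
    pipeline can be exercised and validated without patient data, plus NIfTI
    cohort I/O and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
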