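# dectexture

Quantitative dual-energy CT (DECT) analysis of thyroid nodules in R:
multiparametric texture features on virtual monochromatic images (VMIs),
iodine and spectral-slope quantification, and benign-versus-malignant group
statistics — with a synthetic DECT phantom so the whole pipeline can be
exercised and validated without patient data.

## What it computes

Most thyroid nodules found incidentally on CT are benign; DECT offers two
non-invasive quantitative handles for triaging them:

1. **Spectral arm** — per-nodule iodine concentration (ROI mean of the
   iodine-density map, mg/mL) and the attenuation-curve slope: the
   least-squares slope of ROI mean HU against VMI energy over 40–190 keV,
   reported as a magnitude and as a normalized variant
   (|slope| / |HU(190 keV)|). Malignant follicular tissue retains less
   iodine, so both should in principle separate the classes.
2. **Texture arm** — 41 features per nodule at 40, 60 and 80 keV, computed
   in 2D per axial slice and averaged across slices:
   12 histogram (first-order), 5 gray-level co-occurrence (GLCM: contrast,
   correlation, energy, homogeneity, entropy), 11 gray-level run-length
   (GLRL: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE),
   4 gray-level gradient (GLGM: MGR, VGR, skewness, kurtosis) and 9 Laws
   energy features (3 × 3 L3/E3/S3 outer products).

Groups are compared feature-by-feature with the SAS/Stata-style
variance-gated two-sample t-test — a two-sided F test for equality of
variances chooses between the pooled test,

    t = (m1 − m2) / (sp · √(1/n1 + 1/n2)),   sp² = ((n1−1)s1² + (n2−1)s2²) / (n1+n2−2),

and the Satterthwaite (Welch) test with
df = (s1²/n1 + s2²/n2)² / ((s1²/n1)²/(n1−1) + (s2²/n2)²/(n2−1)) — and with
empirical ROC analysis: midrank Mann–Whitney AUC, orientation so AUC ≥ 0.5,
and the Youden-optimal cut-off with sensitivity (malignant) and specificity
(benign).

The phantom generator renders ellipsoidal nodules whose in-ROI intensity is
`base(E) + iodine · enhancement(E) + texture + noise`, with class-dependent
iodine content and a Gaussian-random-field heterogeneity whose correlation
length and amplitude differ by class. Ground truth is known, so parameter
recovery (iodine AUC, texture detection power, test calibration) is testable.

## Worked example

```r
library(dectexture)

cfg <- phantom_config(rng_seed = 20260927)   # 14 benign / 20 malignant study design
cfg
#> <phantom_config>
#>   grid 64x64x5 voxels at 1x1x3 mm, 16 energies (40-190 keV)
#>   cohort 14 benign / 20 malignant; iodine 0.540 / 0.437 (SD 0.37) mg/mL

run <- run_pipeline(file.path(tempdir(), "demo"), cfg)
rep <- run$report
rep[rep$feature %in% c("histogram.median", "glgm.MGR", "iodine_content") &
    (is.na(rep$energy_keV) | rep$energy_keV == 80),
    c("feature", "benign_mean", "malignant_mean", "method", "p",
      "cutoff_direction", "cutoff", "sensitivity_pct", "specificity_pct", "auc")]
#>           feature benign_mean malignant_mean method         p cutoff_direction    cutoff sensitivity_pct specificity_pct   auc
#>  histogram.median   1064.4876      1064.1755 pooled 9.325e-01                > 1062.9308              60            57.1 0.511
#>          glgm.MGR     14.5805        20.2076 pooled 3.322e-19                >   17.3239             100           100.0 1.000
#>    iodine_content      0.3917         0.3886 pooled 9.774e-01                <    0.4742              75            50.0 0.511
```

Reading the rows: under the default study conditions the classes share their
intensity scale (histogram median p = 0.93, AUC 0.51) and their iodine
dispersion drowns the 0.10 mg/mL mean difference (p = 0.98) — the spectral
arm is underpowered at n = 14/20, exactly the published in vivo outcome —
while the class-distinct heterogeneity shows up sharply in the gradient
features (MGR 14.6 vs 20.2 HU/mm, p ≈ 3e-19, AUC 1.00; the phantom's
configured texture separation is deliberately strong). The run directory
contains the NIfTI volumes, `manifest.csv`, `features_wide.csv`,
`features_long.csv`, `spectral.csv`, `report.csv`, `config.yaml` and
`log.txt`; rerunning the same configuration reproduces every CSV
bit-identically.

Summary-statistic inference works without images, e.g. recomputing a
published benchmark row (benign 1086.7 ± 18.6, n = 14 vs malignant
1071.9 ± 9.5, n = 20):

```r
two_sample_t_from_summary(1086.7, 18.6, 14, 1071.9, 9.5, 20)
#> two-sample t-test (satterthwaite): t = 2.738, df = 17.78, p = 0.01356 *
```

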