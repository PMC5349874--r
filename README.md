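# ipmnrad

Radiogenomic prediction of malignant IPMN pathology: 2D CT radiomics, a
5-miRNA plasma classifier, and integrated logistic diagnostic models.

Intraductal papillary mucinous neoplasms (IPMNs) are cystic pancreatic
cancer precursors; the clinical question is which lesions carry high-grade
or invasive pathology and need surgery. `ipmnrad` implements, as a tested
and reusable R pipeline, the full analysis stack for that question:

* **Radiomics** — a fixed 112-feature catalog per segmented 2D lesion
  (intensity + binary ROI mask): 18 size/shape/location features, 10
  histogram statistics, 16 gray-level co-occurrence + 11 run-length
  features (G = 64, distance-1 offsets, 0° runs), 25 Laws texture energies
  and 32 wavelet subband statistics (Daubechies-2, 3 levels).
* **Composite scoring** — greedy Pearson redundancy filter (|r| > 0.90),
  per-feature simple logistic screening (per-SD odds ratios, Wald CIs,
  Firth fallback under separation), selection at p < 0.05, and PC1 of the
  selected features ("Features PC1"); the miRNA genomic classifier (MGC)
  is PC1 of five plasma miRNA log2 expressions (miR-200a-3p, miR-1185-5p,
  miR-33a-5p, miR-574-3p, miR-663b).
* **Evaluation** — Mann–Whitney AUC with DeLong variance/CI and paired
  DeLong tests, Youden-index cutpoints, confusion-matrix metrics
  (sensitivity, specificity, PPV, NPV, accuracy), a nine-model suite
  (demographic, high-risk stigmata, worrisome features, MGC, Features
  PC1, and their combinations), and repeated stratified 10-fold
  cross-validation in which *all* data-dependent steps (filter,
  screening, PCA loadings, logistic fits) are re-estimated inside each
  training fold.
* **Synthetic phantom cohorts** — a first-class generator reproducing the
  published class-conditional structure of a 20-benign / 18-malignant
  cohort (lesion size distributions, clinical-flag prevalences, 2.5-fold
  miRNA down-shift in malignancy, and texture/shape heterogeneity that
  separates the classes), so the whole pipeline runs and is tested with
  no patient data.

In the field's standard notation: for scores the AUC is the normalized
Mann–Whitney statistic P(X_mal > X_ben) + ½P(=); the Youden cutpoint
maximizes J = Se + Sp − 1; the MGC and Features PC1 are first principal
components of z-scored blocks with a loading-sum-positive sign convention;
two independent binormal markers with standardized separations d₁, d₂
combine under logistic regression to an asymptotic AUC of
Φ(√(d₁² + d₂²)/√2), which the package reproduces empirically.

## Worked example

```r
library(ipmnrad)

cfg <- run_config(cohort = cohort_config(seed = 7), cv_reps = 50,
                  output_dir = "run1")
run <- run_pipeline(cfg)
print(run)
#> <pipeline_run> 38 cases, 38 with features; 21 significant features; PC1 51% variance
#>                        model  n  auc sens spec  ppv  npv
#> 1       demographic_clinical 38 0.66 0.44 0.90 0.80 0.64
#> 2         high_risk_stigmata 38 0.82 0.83 0.80 0.79 0.84
#> 3                        mgc 38 0.69 0.67 0.70 0.67 0.70
#> 4         high_risk_plus_mgc 38 0.86 0.83 0.90 0.88 0.86
#> 5         worrisome_features 38 0.54 0.28 0.80 0.56 0.55
#> 6         worrisome_plus_mgc 38 0.70 0.78 0.55 0.61 0.73
#> 7               radiomic_pc1 38 1.00 1.00 0.95 0.95 1.00
#> 8      radiomic_pc1_plus_mgc 38 1.00 1.00 0.95 0.95 1.00
#> 9 worrisome_radiomic_pc1_mgc 38 1.00 1.00 1.00 1.00 1.00

print(run$cv[[1]])
#> <cv_result> radiomic_pc1_plus_mgc: 50 x 10-fold CV, mean AUC 0.993 (95% CI 0.989-0.997), seed 1
```

Reading the output: each row is one logistic model of malignant pathology
on the synthetic 38-case cohort, with its in-sample AUC, Youden-cutpoint
sensitivity/specificity/PPV/NPV, and effective n. On phantoms the
radiomic composite separates nearly perfectly (the programmed texture
differences are present in every malignant lesion); worrisome features
hover near chance (AUC ≈ 0.54), as configured. The `cv` entry is the
repeated 10-fold cross-validated performance of the combined radiomic +
MGC model, with every selection step refit per fold. Artifacts (feature
table, screening table mirroring the per-feature odds-ratio report, model
report, CV report, association tests, catalog JSON, run manifest) are
written under `output_dir`.

A thin command-line wrapper lives at `inst/cli/ipmnrad-pipeline.R`:

```sh
Rscript inst/cli/ipmnrad-pipeline.R --out run2 --seed 3 --cv-reps 100
Rscript inst/cli/ipmnrad-pipeline.R --stage simulate --out cohort_dir --seed 3
```

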