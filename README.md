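# kneeSSM

Statistical shape modelling (SSM) of the tibiofemoral joint, and a
morphology-based prediction of response to partial medial meniscectomy.

Persistent pain after arthroscopic partial medial meniscectomy (medial
postmeniscectomy syndrome, MPMS) affects a sizeable minority of patients,
and 3D bone morphology is a candidate risk factor. This package provides
the full analysis chain a morphometrics study of that question needs:
reading triangular bone meshes, establishing dense anatomical
correspondence by deforming a template (rigid, then elastic), rigid
generalized Procrustes alignment *without scaling* (so overall size is
retained as a mode of variation), PCA shape models of the distal femur,
proximal tibia and combined tibiofemoral joint, group statistics on
demographics and principal-component (PC) weights, and a leave-one-out
logistic classifier for the response-to-treatment label with bootstrap
confidence intervals. Since no patient imaging ships with the package, a
synthetic cohort generator plants known modes of shape variation
(overall size, intercondylar notch width, medial condyle width) so every
stage can be validated against ground truth.

## The model in brief

Aligned, corresponded shapes $x_i \in \mathbb{R}^{3V}$ are decomposed as

$$x_i \approx \bar{x} + \sum_{k=1}^{m} b_{ik}\,\phi_k ,$$

where $\bar x$ is the mean shape, $\phi_k$ the orthonormal modes of
shape variation (eigenvectors of the sample covariance, divisor $n-1$)
and $b_{ik}$ the PC weights. Modes are retained up to 98% cumulative
explained variance. Model quality is reported as compactness (cumulative
explained variance vs mode count) and generalization (exhaustive
leave-one-out reconstruction RMSE in mm). PC weights are compared
between outcome groups with Welch's t test and fed to a ridge-penalized
logistic regression evaluated by leave-one-out cross-validation
(sensitivity/specificity for detecting each class, ROC-AUC as the
pairwise concordance probability, stratified percentile bootstrap CIs,
1000 draws).

## Worked example

```r
library(kneeSSM)

# a small synthetic study: 10 patients per group, coarse meshes
cfg <- pipelineConfig(outDir = "report",
                      cohort = cohortSpec(nR = 10, nMPMS = 10,
                                          resolution = 10, seed = 11),
                      nBoot = 200, maxGenModes = 8)
res <- runPipeline(cfg)

res$models$joint
#> ShapeModel 'femur_template:crop+tibia_template:crop': 160 vertices, 20 training shapes, 19 modes
#>   total variance 121.6 mm^2; 98% of variance in 3 modes

res$predictions$joint
#> PredictionResult (joint): n = 20, threshold 0.50, 200 bootstrap draws
#>   sensitivity_mpms   0.700 (95% CI 0.400-1.000)
#>   specificity_mpms   0.700 (95% CI 0.400-0.900)
#>   sensitivity_rtt    0.700 (95% CI 0.400-0.900)
#>   specificity_rtt    0.700 (95% CI 0.400-1.000)
#>   auc                0.770 (95% CI 0.520-0.960)
```

The report directory contains, per shape model, the compactness and
generalization curves, mode shapes at ±2 SD (PLY), per-patient PC
weights, the demographic comparison table, Welch tests on the first
three modes, the masked Pearson correlation matrix, per-patient LOO
probabilities, ROC curves, and prediction metrics with CIs — all as
plain CSV/JSON, byte-identical across re-runs of the same configuration
(timings live only in `log.txt` and `manifest.json`).

The 20-patient toy run above is small on purpose; its wide intervals are
what honest uncertainty at that size looks like. At the reference scale
(120 patients per group, the condition all full-cohort results in the
test suite are computed at), the joint-model classifier reaches a
leave-one-out AUC of about 0.83 and Welch tests on the first three PC
weights recover the planted group differences — smaller, wider-notched,
narrower-condyled MPMS knees — with the correct signs.

## Package layout

* `R/` — S4 classes (`TriangleMesh`, `CorrespondedShape`, `ShapeModel`,
  `AlignedSet`, `PredictionResult`) and the analysis functions.
* `src/` — C++ closest-point-on-mesh kernel (Rcpp).
* `vignettes/kneeSSM-methods.Rmd` — the methods vignette: model,
  assumptions, parameter defaults, synthetic-generator design, numerical
  choices, limitations.
* `inst/scripts/run_pipeline.R` — command-line wrapper over
  `runPipeline()`.
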