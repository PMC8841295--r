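# dkiclass

Identification of epilepsy-like microstructural change from diffusion
kurtosis imaging (DKI), using the **full tensor components** — not only the
derived scalars FA, MD and MK — as the classification biomarker. The
package is aimed at neuroimaging researchers who want a self-contained,
reproducible implementation of the tensor-feature classification pipeline:
per-voxel tensor estimation from multi-shell diffusion MRI, hippocampus-style
ROI feature matrices, elastic-net feature selection, SVM classification, and
a calibrated synthetic cohort generator so everything runs without clinical
data.

## The model

The diffusion-weighted log-signal follows the fourth-order cumulant
expansion

```
ln S(b, n) = ln S0 − b Σᵢⱼ nᵢnⱼ Dᵢⱼ + (b² D̄²/6) Σᵢⱼₖₗ nᵢnⱼnₖnₗ Wᵢⱼₖₗ
```

with `D` the diffusion tensor (6 independent components, mm²/s), `W` the
kurtosis tensor (15 independent components, dimensionless) and `D̄` the mean
diffusivity — 21 tensor components plus `ln S0`. Per voxel, the package
solves the linearization in the composite variable `B = D̄²·W` by
signal-weighted least squares and rescales `W = B/D̄²`. Subject feature
matrices (6 × V and 15 × V over the V mask voxels) are pruned of rows and
columns that are zero in every subject, flattened, passed through the
combined L1+L2 penalty

```
(1/N)‖Y − Xβ‖² + λρ‖β‖₁ + λ(1−ρ)/2 ‖β‖²
```

for feature selection, and classified with a soft-margin SVM. Reports carry
accuracy, precision, sensitivity, specificity and trapezoidal AUC.

## Worked example

The bundled demo configuration simulates a small two-group cohort
(6 controls + 6 patients, ~65-voxel ellipsoidal ROI, Rician SNR 50,
two-shell b = 1000/2000 s/mm² acquisition), fits every voxel, builds DT and
KT feature matrices, and runs the selection + SVM experiment:

```r
library(dkiclass)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml", package = "dkiclass"))
res <- run_pipeline(cfg)
print(res$experiment)
#> experiment_result (selection = L1L2 , seed = 42 )
#>  item train_acc test_acc precision sensitivity specificity auc n_features cost
#>    DT         1     0.75    0.6667           1         0.5   1          8 0.01
#>    KT         1     1.00    1.0000           1         1.0   1         23 0.01
```

Each row is one biomarker: train/test accuracy, test-set precision,
sensitivity, specificity and AUC, plus the number of features surviving
selection and the cross-validated SVM cost. On this toy cohort the kurtosis
tensor separates the held-out subjects perfectly (test_acc 1.00) while the
diffusion tensor does not (0.75) — the direction of the effect the pipeline
is designed to expose, though a 3-subject test set carries wide error bars.

Two-group tests on the per-subject KT summary statistics of the same run:

```r
print(res$summary_tests$KT, digits = 3)
#>   statistic     t   df     p_t     f      p_f
#> 1       max  4.62 8.70 0.00136 21.38 0.000945
#> 2       min -1.01 6.99 0.34832  1.01 0.338488
#> 3       avg  2.32 5.70 0.06168  5.38 0.042757
```

(`t`/`p_t`: Welch t-test; `f`/`p_f`: one-way ANOVA.) At the full default
cohort size (30 + 30 subjects, ~500-voxel ROI) the per-subject KT average
separates the groups at p ~ 1e-9.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dki-pipeline.R", package = "dkiclass"))')" \
  --config my_config.yaml --seed 7 --out results/
```

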