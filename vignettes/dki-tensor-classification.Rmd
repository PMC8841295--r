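---
title: "Diffusion-kurtosis tensor features for patient/control classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-kurtosis tensor features for patient/control classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Conventional structural MRI is normal in a large fraction of epilepsy
patients, yet the microstructure of affected regions — the hippocampus in
particular — is altered at a scale diffusion imaging can see. Diffusion
kurtosis imaging (DKI) quantifies non-Gaussian water diffusion and is
sensitive to such alterations. `dkiclass` implements a complete
identification pipeline: per-voxel tensor estimation from multi-shell
diffusion-weighted volumes, region-of-interest (ROI) feature construction,
penalized feature selection, and support-vector-machine classification of
patients versus controls, with the full-tensor components — not only the
scalar summaries FA, MD and MK — as the biomarker.

Because clinical diffusion cohorts are rarely shareable, the package also
ships a calibrated synthetic cohort generator, so every stage is testable
end-to-end without any data download.

## Signal model and tensor estimation

For a measurement with b-value $b$ and unit gradient direction
$\hat n$, the log-signal is modeled by the fourth-order cumulant
expansion

$$\ln S(b,\hat n) \;=\; \ln S_0 \;-\; b \sum_{ij} n_i n_j D_{ij}
\;+\; \frac{b^2 \bar D^2}{6} \sum_{ijkl} n_i n_j n_k n_l\, W_{ijkl},$$

with $D$ the symmetric diffusion tensor (6 independent components,
mm²/s), $W$ the fully symmetric kurtosis tensor (15 independent
components, dimensionless) and $\bar D$ the mean diffusivity. Directional
diffusivity and kurtosis are

$$D(\hat n) = \sum_{ij} n_i n_j D_{ij}, \qquad
K(\hat n) = \frac{\bar D^2}{D(\hat n)^2} \sum_{ijkl} n_i n_j n_k n_l\, W_{ijkl}.$$

$D(\hat n)$ is implemented as the *signed* quadratic form: a physical
tensor is positive-semidefinite, so a negative value is a fit pathology
worth seeing, not hiding behind an absolute value.

The model is nonlinear in $(D, W)$ only through the $\bar D^2$ factor.
`fit_voxel()`/`fit_volume()` therefore solve for the composite vector
$(\ln S_0,\, D,\, B)$ with $B = \bar D^2 W$, which the log-signal depends
on linearly, and recover $W = B/\bar D^2$ afterwards. Estimation is
two-stage: an ordinary least-squares solve over all voxels at once,
followed by one signal-weighted refinement pass per voxel (weights equal
to the squared predicted signals), the standard correction for the
heteroscedasticity the log transform introduces. Ordinary least squares
remains available through `fit_options(weighting = "ordinary")`.

Numerical safeguards, all configurable through `fit_options()`:

* non-positive signals are clipped to `signal_floor` (default $10^{-6}
  \times$ the voxel's maximum signal) before the log transform and the
  voxel is flagged `clipped`;
* voxels with $\bar D^2$ below `min_mean_diffusivity` (default
  $10^{-12}$ (mm²/s)²) cannot support the $W$ rescaling; they are flagged
  `degenerate` and report $W = 0$;
* the design matrix's condition number is checked against
  `max_condition` (default $10^8$); the 22-parameter model needs at least
  two distinct nonzero shells and enough well-spread directions (the
  standard two-shell, 50-direction protocol has condition number
  $\sim 3\times 10^6$);
* no positivity or kurtosis-range constraint is imposed; out-of-range
  estimates are visible to the caller rather than silently clipped.

A single canonical component ordering —
(D11, D22, D33, D12, D13, D23) and (W1111, W2222, W3333, W1112, W1113,
W1222, W2223, W1333, W2333, W1122, W1133, W2233, W1123, W1223, W1233) —
is shared by the design matrix, the tensor maps and every feature matrix.
Off-diagonal design columns carry their index-multiset multiplicities
(2; and 4/6/12 for the kurtosis monomials) so the solution vector holds
the canonical components directly.

## Scalar maps

* **MD**: trace of $D$ divided by 3.
* **FA**: $\sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert$
  over the eigenvalues $\lambda$ of $D$.
* **MK**: the average of $K(\hat n)$ over a deterministic direction set,
  256 directions by default.

MK deserves a note. $K(\hat n)$ is even in $\hat n$, so any quadrature
should respect the projective (antipodal) symmetry. We evaluated two
deterministic constructions: a hemisphere spiral with explicit antipodes,
and the plain full-sphere Fibonacci spiral. At equal direction counts the
full-sphere spiral converges roughly an order of magnitude faster
(relative error $\sim 3\times 10^{-4}$ at 256 directions against a
$10^4$-direction reference, versus $\sim 1.4\times 10^{-3}$ for the
paired construction), because the pairing halves the number of distinct
nodes. `mean_kurtosis()` therefore integrates over the full-sphere spiral;
since the integrand is even this equals the antipodally symmetrized
average exactly. `antipodal_directions()` remains available and is used in
the test suite as an *independent* quadrature for cross-checking. The
exact closed-form MK is out of scope; the directional average is the
common numerical surrogate and its quadrature error is far below the
biological variability the pipeline works with.

## ROI feature matrices

`extract_subject_matrix()` arranges the in-mask voxel values as a
components × voxels matrix (6 × V for the diffusion tensor, 15 × V for
the kurtosis tensor, 1 × V for scalars). Columns enumerate mask voxels in
a fixed grid-scan order (first axis fastest), identical for every subject
fitted on one cohort mask, so feature spaces align column-by-column.

Out-of-mask voxels hold exact zeros by construction, and
`prune_zero_rows_columns()` removes rows and columns that are zero in
**every** subject. Pruning is cohort-wide rather than per subject: per-
subject pruning would give subjects different feature spaces and break
classification alignment. The zero tolerance defaults to 0 because the
zeros being pruned are structural, not numerical. `flatten_features()`
concatenates rows (components outer loop, voxels inner), a documented
deterministic order so that two subjects' vectors align feature-by-feature.

Per-subject summaries (max, min, average of all matrix entries) feed
`cohort_summary_tests()`: a Welch two-sided t-test and a one-way ANOVA
per statistic. Welch is the default because equal group variances cannot
be assumed (the calibrated cohorts are strongly heteroscedastic); with two
groups the ANOVA F equals the pooled-variance $t^2$, which the test suite
checks numerically.

## Feature selection and classification

Selection minimizes

$$\frac{1}{N}\lVert Y - X\beta\rVert_2^2
\;+\; \lambda\rho\lVert\beta\rVert_1
\;+\; \frac{\lambda(1-\rho)}{2}\lVert\beta\rVert_2^2,$$

with the group labels coded 0/1 as the regression response. The solver is
glmnet; the objective above maps onto glmnet's parameterization exactly
via `alpha` $= \rho$ and `lambda` $= \lambda/2$ (the test suite verifies
the pure-LASSO case against a hand-written coordinate descent). Defaults:
$\rho = 0.5$, $\lambda$ chosen from a 50-point log grid by 5-fold
stratified cross-validation. The L1-budget (constraint) form is honored
through the Lagrangian path: the least-penalized path solution whose L1
norm fits the budget. If every candidate penalty empties the model, the
selection falls back to all features with a warning and an
`empty_selection` flag — an empty feature set is never silently passed on.

Classification is a soft-margin SVM (e1071). The default kernel is
linear — with features far outnumbering subjects a nonlinear map has
little to gain and much to overfit — with an RBF option. The cost
parameter is tuned on a log grid from 0.01 to 100 by stratified
cross-validation *on the training split only*. `run_experiment()` wires
the stages together per biomarker (DT, KT, FA, MD, MK, or the FA+MK
concatenation): stratified 75/25 train/test split, optional selection
(`none`, `L1`, `PCA` keeping 95% variance, or the combined `L1L2`),
cost search, and a held-out report with accuracy, precision, sensitivity,
specificity and trapezoidal AUC. Metrics with zero denominators are
reported as `NA`, never as 0. Nothing fitted ever sees test-side labels;
a contract test permutes the held-out labels and asserts the fitted
selection, cost and coefficients are bit-identical.

## The synthetic cohort generator

The generator emulates the statistical skeleton the analysis relies on:
two groups of subjects, each an ellipsoidal "hippocampus-like" ROI of
per-voxel $(D, W)$ pairs, converted to noisy multi-shell signals through
the forward model above.

Calibration works backwards from published group summary statistics of
the per-subject feature-matrix averages. For an isotropic kurtosis tensor
at level $K$, the 15-component average is $4K/15$; for a randomly
oriented diffusion tensor with mean diffusivity MD, the 6-component
average is MD/2 in expectation. Subject-level draws therefore use
$K_s \sim N(15/4 \cdot \text{kt\_avg})$ and
$MD_s \sim N(2 \cdot \text{dt\_avg})$, with defaults

| group   | dt_avg (10⁻³ mm²/s) | kt_avg (–)       |
|---------|---------------------|------------------|
| control | 0.5116 ± 0.1563     | 0.2402 ± 0.0441  |
| patient | 0.7025 ± 0.1048     | 0.1743 ± 0.0089  |

Remaining knobs, with the reasoning behind each default:

* **Within-subject (voxelwise) variation**: smooth random fields scaled
  to 20% of the between-subject sd. Published summaries constrain only
  between-subject spread, so this is a declared free parameter, kept
  small enough that subject identity dominates.
* **Anisotropy** 0.15: relative eigenvalue jitter of $D$ about the voxel
  MD under a per-voxel random rotation, yielding gray-matter-like FA of
  roughly 0.1–0.3. $D$ stays positive-definite by construction and each
  voxel's MD is preserved exactly.
* **Kurtosis tensor**: exactly isotropic per voxel by default
  (`w_perturbation = 0`), which keeps the calibration identity exact;
  a relative jitter is available.
* **Noise**: Rician at SNR 50 on $S_0$ (magnitude of a complex Gaussian
  perturbation), the realistic magnitude-MRI model; Gaussian available
  for debugging, `Inf` disables noise for exact round-trip tests.
* **Acquisition**: 2 unweighted scans plus shells at b = 1000 and
  2000 s/mm² with 50 directions each, a standard clinical DKI protocol.
* **ROI size**: ~500 voxels (semi-axes 6×5×4 on a 15×13×11 grid) —
  deliberately desk-scale; real hippocampus masks are orders of magnitude
  larger, and every size is configurable. The test suite and the
  acceptance script run cohorts of 30+30 subjects at this ROI size.

Everything is a pure function of `(design, seed)`; per-subject seeds are
derived from the design seed, and the ground-truth tensor fields are
returned alongside the signals for parameter-recovery scoring.

## What passing tests do and do not show

The generator reproduces the *distributional* structure of a two-group
tensor cohort, not its anatomy. No partial-volume effects, motion or
eddy-current artifacts, spatially varying noise, registration error, or
hemispheric asymmetry are modeled; the ROI is a convex ellipsoid, not a
hippocampus. Passing the pipeline tests shows the estimation, selection
and classification machinery is correct and leak-free under the modeled
conditions — it does not certify performance on clinical data.

One consequence deserves emphasis. Because the generator is calibrated
only to per-subject summary statistics, all between-group kurtosis signal
is carried by a single subject-level scalar, and the two calibrated
distributions overlap. The acceptance script quantifies the resulting
ceiling: alongside the pipeline's test accuracy it reports the accuracy
of a two-group Gaussian likelihood-ratio rule applied to the *true*
subject kurtosis levels with parameters fitted on the training split —
the best any classifier could do from these cohorts. Published
classification figures obtained on real cohorts of similar size exceed
what this summary-calibrated simulation supports, which says something
about the information content of real voxel-level data, not about the
pipeline.

## Reproducibility notes

* All stochastic functions take explicit seeds and restore the caller's
  RNG state on exit; cohorts, experiments and pipeline runs are
  bit-reproducible for a given configuration.
* `run_pipeline()` persists metrics, summaries, ROC coordinates, the
  gradient table, the mask and a manifest (seeds, selected-feature
  counts, input hashes for file-based runs) as plain text.
* Gradient tables use the FSL bval/bvec dialect; volumes are NIfTI on a
  shared grid, checked — never resampled — by the pipeline.
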