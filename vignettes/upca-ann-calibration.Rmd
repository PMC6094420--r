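---
title: "Second-order fluorescence calibration with unfolded PCA and neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order fluorescence calibration with unfolded PCA and neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcalib)
```

## The problem

Excitation–emission matrix (EEM) fluorescence records, for one sample, an
intensity surface over a grid of excitation and emission wavelengths. It is
*second-order* data: one matrix per sample, so a set of samples forms a
three-way cube (samples × λex × λem). EEMs are attractive for drug
quantification in biological fluids — here the emulated system is ibuprofen
extracted from human serum into chloroform, with a native fluorescence
maximum at 251 nm excitation and 362.5 nm emission — because fluorescence is
sensitive, but serum components co-fluoresce and overlap the analyte band, so
a univariate peak read-out is not selective.

`eemcalib` implements the UPCA-ANN strategy for this situation:

1. **Unfold** the cube into a samples × (λex·λem) matrix (matricization;
   emission varies fastest within each excitation block). On the default
   30 × 401 grid, 61 samples give a 61 × 12030 matrix.
2. **Compress** with column-mean-centred PCA, \(A = T P^\top + E\), keeping
   the leading scores \(T\) as features. The serum background contributes
   extra independent spectral patterns, so the useful dimension exceeds the
   single analyte.
3. **Calibrate** concentration from the scores with a one-hidden-layer
   feed-forward network trained by backpropagation with momentum and
   validation-based early stopping — the nonlinearity absorbs matrix effects
   that a linear score regression would miss.
4. **Validate** with a Kennard–Stone calibration/validation/test split,
   leave-one-out cross-validation for the number of components, and
   multivariate figures of merit.

Unfolding deliberately discards trilinearity; this is a first-order model on
flattened second-order data, not a PARAFAC-style decomposition, and it makes
no second-order-advantage claim: every analyte/background pattern must be
spanned by the calibration set.

## The model pieces and their assumptions

### PCA on the unfolded matrix

`fit_pca()` centres columns (no unit-variance scaling — standard for
spectral data, where the intensity scale is physically meaningful) and takes
the SVD. Eigenvalues use the sample-covariance convention
\(\lambda_j = d_j^2/(m-1)\); explained-variance percentages are relative to
the total variance of the centred matrix, so `variance_table()` running sums
are exact prefix sums and reach 100 % at full rank. The unfold order is
arbitrary but fixed and recorded in `column_map`; PCA is invariant to column
permutations, so results do not depend on it.

Score-plot screening (`flag_score_outliers()`) replaces the visual
inspection traditionally used on PC1–PC2 score plots with a reproducible
rule: a robust z-score on the Euclidean distances from the componentwise
median of the (PC1, PC2) scores, flagging samples beyond 3 scaled MADs
(threshold configurable). In designs where PC1 tracks concentration, the
extremes of a wide concentration ladder can legitimately exceed the robust
band; flagged samples are therefore *reported*, never removed — consistent
with the observation that refitting without them changes little.

### Kennard–Stone splitting

`ks_rank()` is the classic maximin ordering: start from the mutually most
distant pair, then repeatedly add the sample farthest from the selected set
(ties to the lowest index — the ordering is fully deterministic).
`three_way_split()` assigns the ranking head to calibration, then
validation, then test; calibration receives the most design-covering
samples, including both maximin extremes, so validation and test samples lie
inside the calibrated span. Set sizes are `round(f·m)` for validation and
test with the remainder to calibration, which reproduces the 40/9/12 layout
for 61 samples at fractions (0.65, 0.15, 0.20).

The split operates on the PC scores of *all* samples, matching the workflow
this package emulates (PCA before splitting). That choice leaks test-sample
variance into the PCA — not into the regression — which is common
chemometric practice but slightly optimistic; fitting PCA on the calibration
rows of the unfolded matrix and projecting the rest with
`project_scores()` is the leak-free alternative the API supports directly.

### The network

`init_network()` builds an \(n_i\)-\(n_h\)-1 multilayer perceptron: logistic
sigmoid hidden units, linear output,
\[
y = \sum_J W_J\, f\!\Big(\sum_I W_{JI} x_I + b_J\Big) + b_0 .
\]
Training (`train_step()`) is full-batch gradient descent on the half-mean
squared error with the conventional momentum form
\(\Delta w_n = -\mu\, \partial E/\partial w + \alpha\, \Delta w_{n-1}\)
(learning rate \(\mu\), momentum \(\alpha\)); one epoch is one full-batch
update. With \(\mu = 0\) the parameters are a fixed point: the network does
not learn. Early stopping (`train_network()`) evaluates validation MSE every
epoch, stops after `patience` epochs without improvement (default 50), and
restores the state from the best validation epoch.

Numerical choices:

* **Weight initialisation**: uniform on \([-0.3, 0.3]\), seeded — small and
  symmetric so the sigmoids start in their linear regime; everything
  downstream is reproducible from the seed.
* **Input scaling**: PC scores standardised to zero mean / unit variance on
  the calibration set only.
* **Target scaling**: concentrations min–max mapped to \([0.1, 0.9]\), the
  sigmoid-era convention that leaves headroom at both ends of the training
  range. A side effect worth knowing: predictions cannot stray far outside
  the calibration concentration range, which stabilises blank predictions
  (good for LOD) but makes genuine extrapolation impossible.

### Model selection

The number of components fed to the network is chosen by leave-one-out
cross-validation on the calibration set (`select_n_pcs()`): for each
candidate count, train on all-but-one sample (the held-out sample doubling
as the early-stopping monitor for that fold), predict it, and take the
candidate with minimal RMSECV, ties to the smaller model. This supersedes
stepwise subset selection over individual components; an ordered
leading-\(n\) family is better matched to variance-ranked PCs and keeps the
search one-dimensional.

`surface_scan()` implements the response-surface search over
(hidden nodes × epochs) and (learning rate × momentum): one model per grid
cell with a per-cell derived seed, scored by test-set MSE, argmin with
ties broken toward the smaller/slower model by scanning axis values in
ascending order and displacing the incumbent only on strictly smaller MSE.
The classical operating point — 5 hidden nodes, 300 epochs, \(\mu = 0.7\),
\(\alpha = 0.2\), giving a 6-5-1 net at 6 components — is the default when
scanning is disabled. Default scan grids span hidden nodes 1–10, epochs
100–1000 (step 100) and \(\mu, \alpha \in \{0.1, \dots, 0.9\}\); the
pipeline accepts reduced grids, and the shipped test and acceptance runs use
2–3 values per axis to keep full runs in the tens of seconds.

### Figures of merit

* RMSE per set; RMSECV from the LOO fold predictions.
* REP% in **two** conventions, both provided because the field uses both
  under one name: per-sample signed error \(100(\hat y - y)/y\)
  (`rep_per_sample()`, the result-table convention) and the aggregate
  \(100\cdot\mathrm{RMSE}/\bar y\) (`rep_aggregate()`).
* \(R^2\), the standard coefficient of determination
  \(1 - SS_{res}/SS_{tot}\).
* LOD = \(3 S_b\) and LOQ = \(10 S_b\), where \(S_b\) is the standard
  deviation of the concentrations predicted for blank samples projected
  onto the calibration PCA. The \(10 S_b\) quantification limit is adopted
  because the reference LOQ/LOD ratio (0.099/0.03 ≈ 3.3) matches 10/3.
* The dynamic range is reported as the calibration design's concentration
  span; it is a design property, not an estimated quantity.

## The simulator: what it emulates and what it does not

`simulate_cube()` builds each sample as a sum of rank-one Gaussian bands —
analyte intensity \(c_i\cdot q\cdot g_{ex}\otimes g_{em}\) plus
per-sample-random levels of broad interferent bands plus additive Gaussian
noise. `ibuprofen_serum_design()` fixes the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| grid | 30 × 401 (λex 236–265 nm step 1; λem 300–500 nm step 0.5) | instrument acquisition settings; 30 excitation channels match recorded cube shapes even though the quoted range at 1 nm would give 31 |
| concentrations | fixed 61-level ladder, 0.1–47 × 10⁻⁷ M | the emulated study design |
| analyte band | ex 251 ± 6 nm, em 362.5 ± 22 nm, 1.7 × 10⁸ intensity·M⁻¹ | band maxima from the analyte's spectra; widths and quantum scale chosen to give smooth unimodal landscapes with a ~800-unit peak at the top of the ladder |
| interferents | two broad bands (ex 245/em 335, ex 259/em 420), levels U(20, 60) and U(5, 30) | serum residue after chloroform extraction: weak, broad, sample-to-sample variable; two bands force the useful PCA dimension above 1, as observed in real serum work |
| noise | additive Gaussian, SD 4 ≈ 0.5 % of full scale | typical photomultiplier noise floor; heteroscedastic option available |
| blanks | 5 extra zero-analyte samples | LOD estimation replicates |

The simulator is deliberately idealised: no inner-filter effects, no
quenching, no Rayleigh/Raman scatter by default (a diagonal ridge is
available as `scatter_height` for stress tests), and interferent *shapes*
are fixed while only their levels vary. Passing the end-to-end tests
therefore shows that the pipeline recovers concentrations when the bilinear
low-rank-plus-noise model holds — it does not certify performance on real
serum EEMs, where scatter, band shifts, and correlated backgrounds violate
those assumptions to varying degrees. The published reference statistics
shipped in `reference_predictions()` / `reference_variance()` are used only
for arithmetic cross-checks: the underlying spectra were never deposited, so
the original trained model (its absolute RMSE, LOD, eigenvalues, or outlier
identities) is not reproducible and is not a test target.

## Degenerate inputs and tie-breaks

* Cubes must be non-empty with consistent axes and unique sample ids;
  intensities may be negative (detector noise) but not non-finite.
* `fit_pca()` refuses constant matrices (zero total variance) and
  out-of-range component counts.
* Kennard–Stone tie-breaks are lowest-index everywhere, so duplicated
  points still yield a deterministic permutation.
* LOO selection and surface scans break ties toward the smaller model.
* `lod_loq()` requires at least two blanks; the pipeline skips LOD when
  fewer are present.

## Problem sizes

The shipped test suite runs entirely on synthetic data generated at test
time: unit tests use grids from 2 × 2 up to 13 × 46 and 15–24 samples;
property suites use 20-point Kennard–Stone orderings against exhaustive
search, ≤ 20 × 20 PCA matrices against `eigen(cov(X))`, and 3-4-1 networks
against central finite differences. The end-to-end runs use the full
61-sample, 30 × 401 default design with LOO candidates 1–6 at 200 epochs and
2–3-value scan grids — about 10 s on one CPU; the full default scan grids
(10 × 10 and 9 × 9) are practical but take correspondingly longer.

## Known limitations

* Unfolded PCA has no second-order advantage: unseen interferents in a test
  sample bias predictions silently.
* The MLP is a 1-output, 1-hidden-layer design by construction; no RBF
  networks, multiple hidden layers, or mini-batch training.
* Early stopping with small validation sets (9 samples here) is noisy; the
  best-state restoration bounds the damage but cannot remove it.
* The robust outlier rule flags by score distance only; a leverage/residual
  diagnostic would catch outliers orthogonal to the first two components.
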