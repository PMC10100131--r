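---
title: "Methods: glioma frequency mapping, lesion-symptom analysis and location-based prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glioma frequency mapping, lesion-symptom analysis and location-based prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliofreq)
```

`gliofreq` implements a population-level analysis of glioma location: where
tumors of different grades occur, which locations associate with grade and
survival, how the spatial distribution of tumors relates to the molecular
architecture of the healthy brain, and how much prognostic information
tumor location carries. This vignette records the models behind each
stage, the parameters that matter, the numerical conventions, and the
choices made where the design was genuinely open.

## Reference space and conventions

All stages operate on a `brain_space`: a regular 3-D grid with voxel sizes
in mm, a binary brain mask, an integer parcellation of `R` regions with
mm centroids, and a ventricle mask used as the subventricular-zone (SVZ)
proxy. Voxel indices are 0-based internally with
`world mm = origin + index * voxel_size`; distances are always mm, volumes
cm^3 (`voxel count x voxel volume / 1000`). Masks and maps are read and
written as NIfTI-1 through RNifti, so round trips are bit-exact. Missing
clinical fields are flagged per row, never dropped silently; each stage
works on its own complete-case subset and logs the exclusion count
(enable `options(gliofreq.verbose = TRUE)` to see the log).

## Frequency maps and predilection sites

The frequency map of a cohort subset is the voxelwise proportion of
patients whose binary lesion mask covers the voxel — equivalently the
mean of the per-patient masks, with each patient weighted equally. The
*predilection-site mask* keeps the top fraction `q` (default 0.10) of the
voxels with nonzero frequency. Two conventions needed fixing:

* **Base set.** The fraction is taken over nonzero-frequency voxels, not
  the whole brain; a whole-brain base would make the mask grow with brain
  size rather than with tumor data. The whole-brain variant is available
  via `base = "brain"`.
* **Ties.** All voxels tied with the cutoff value are included, which is
  deterministic and order-independent; the realized fraction can then
  exceed `q` and is logged when it does.

Per-patient overlap with a target mask reports both the absolute overlap
volume and the proportion, with the individual tumor's volume as the
default denominator (the target-mask denominator is available).
Patients can be ranked by either metric with ties broken by patient id,
and the top/bottom 20% flagged positionally.

## Voxelwise lesion-symptom mapping

At each voxel lesioned in at least `min_coverage` patients (and spared by
at least as many; default 5, chosen to avoid degenerate cells — the
analysis is meaningless at voxels nearly constant across patients), the
package fits ordinary least squares of the outcome on
`[lesion indicator, covariates, intercept]` and takes the *t* statistic
of the lesion coefficient. For a binary outcome (GBM vs LGG) this is a
linear probability model — the default continuous machinery of VLSM
toolboxes; per-voxel logistic fits were rejected because they are
unstable at low coverage. The implementation residualizes both the
outcome and the voxelwise lesion indicators against the shared covariate
design (Frisch–Waugh), which is algebraically identical to the full
per-voxel fit and turns the whole map, and its permutation null, into
matrix products. Voxels whose residualized lesion indicator is
numerically zero (collinear with a covariate) are excluded and logged.

Significance uses permutation. The null follows the **Freedman–Lane**
scheme: residuals of the covariate-only model are permuted and refitted
per voxel, so covariate effects are not destroyed by the shuffle (naive
outcome permutation is available behind `scheme = "naive"`). Two
thresholding modes are exposed because published descriptions of "t
values higher than those from more than 95% of permutations" are
ambiguous between them:

* `maxstat` (default): the threshold is the 95th percentile of the
  per-permutation *maximum* statistic over tested voxels — familywise
  error control, the conservative reading;
* `voxelwise`: each voxel is thresholded at the 95th percentile of its
  own null.

Both use type-7 quantiles of the stored null, and the directional
statistic is |t|, +t or −t (`direction`), since grade-associated regions
are defined by the positive tail and short-survival regions by the
negative one. `derive_rois` packages the two standard runs — ROI1 from
the GBM-vs-LGG contrast, ROI2 from overall survival among GBM patients —
both adjusted for age, sex and tumor volume. Overall survival enters the
ROI2 regression in months as observed, without a censoring adjustment;
this mirrors common VLSM practice but is a known limitation, and the
quartile log-rank machinery below is the censoring-aware counterpart.

## Imaging transcriptomics (PLS with spatial nulls)

The regional analysis correlates the parcellated tumor frequency with a
region-by-gene expression matrix. The response is the z-scored **square
root** of the regional frequency (frequencies are right-skewed;
the square root symmetrizes them), and gene columns are z-scored. The
partial-least-squares step is the SVD of the cross-covariance matrix
`t(X) y / (R - 1)`; with a single response all cross-covariance structure
is rank one, so component 1's gene loadings are exactly the normalized
vector `X'y` and the singular value its norm — the `1/(R-1)` scaling is
stated so singular values are comparable across runs. Genes are ranked
by signed loading; gene-set enrichment compares member versus non-member
loadings with a two-sample t statistic, set-size-preserving label
resampling (two-sided), and Benjamini–Hochberg adjustment across sets.

**Spatial null.** Regional maps are spatially autocorrelated, so naive
permutation overstates significance. A spherical "spin" is undefined for
a volumetric parcellation that includes subcortex, so the package uses
**Moran spectral randomization**: the map is expanded in the orthonormal
eigenbasis of the doubly centered Gaussian kernel over region centroids
(bandwidth: half the median pairwise distance), and surrogates randomly
sign-flip the expansion coefficients. Sign flips preserve the map's mean,
variance and squared coefficient spectrum — hence its spatial frequency
content — exactly, and under independence of expression and tumor map
the projections of the expression matrix onto the eigenvectors have
symmetric signs, which is precisely the exchangeability the test needs.
A variogram-regression surrogate family (smoothed permutation plus fitted
nugget) was implemented first and measured to be miscalibrated in one
direction or the other depending on its bandwidth ladder; the spectral
construction replaced it because its null spin *p* distribution is
empirically uniform in the package's calibration suite. The trade-off:
pure sign flips keep surrogates on the original map's orbit, so
individual surrogates can rank-correlate noticeably with the original;
`block_size > 1` additionally permutes coefficients among adjacent
eigenvalues, decorrelating the surrogates at a small cost in spectral
fidelity (and, measurably, in calibration). Only the tumor map is
randomized; expression is held fixed.

The spin *p*-value per component is the +1-corrected exceedance
proportion `(1 + #[S_null >= S_obs]) / (n_null + 1)`, so the smallest
attainable value is `1/(n_null+1)` and ties count against significance.
Receptor maps are compared by Spearman correlation with the same
surrogates (two-sided), and a panel of receptors is BH-adjusted.

**Known limitation.** Calibration is demonstrated for multi-focal
occurrence fields (the package's calibration suite uses 8-focus worlds
on 60 regions). A map dominated by a single smooth bump concentrates its
energy on one or two eigencomponents whose coefficient signs are *not*
exchangeable across realizations, and no autocorrelation-preserving null
family is well calibrated there; treat spin *p*-values for such
near-degenerate maps with caution.

## Location features and survival

Distances use an exact Euclidean distance transform with anisotropic
voxel sizes (separable lower-envelope algorithm, compiled); applied to
the ventricle mask it yields the concentric periventricular distance
map, and a tumor's SVZ distance is the mean of that map over its voxels.
ROI distances are measured to a small sphere at the ROI's voxel-rounded
center of mass (default radius: two voxels — the published "center mask"
has no stated size, and a small sphere keeps it point-like but
nonempty). The feature table assembles tumor volume, overlap
volume/proportion with the predilection mask and both ROIs, and mean
distance to the ROI centers and SVZ; empty ROIs yield flagged NA
columns rather than silent zeros.

Survival comparisons use the Kaplan–Meier product-limit estimator and
the standard two-group log-rank test (through the survival package, with
an independent risk-set-table computation as test oracle). Quartile
groups are defined by type-7 (linear-interpolation) quantiles — stated
because the boundary convention changes membership — with boundary ties
included in their group and logged. The six-gene risk score is the
published linear combination of expression values; it is scale-agnostic
(log-transforming expression rescales the score but the median split and
ROC are rank-based in spirit). Ties at the median go to the low-risk
group, deterministically. The time-dependent ROC uses the
inverse-probability-of-censoring-weighted cumulative-case/dynamic-control
estimator with a Kaplan–Meier censoring model; with no censoring it
reduces exactly to the rank-sum AUC of the event indicator.

## One-year survival prediction

Labels: died before 12 months → 1; alive at 12 months (event or later
censoring) → 0; censored before 12 months → excluded and flagged, since
their status is genuinely unknown. Each of the `n_repeats` (default 100)
repeats draws 80% of each dataset, stratified by label, pools the draws
for training, standardizes features with training statistics only,
selects the SVM cost (and radial width) by stratified 10-fold
cross-validation maximizing AUC on the training pool (default grids:
cost `2^-5..2^5`, width `2^-7..2^3`), refits, and scores the pooled
held-out patients. Results aggregate the per-repeat test AUCs
(mean ± SD), and the whole procedure is bit-reproducible from one seed.
Feature importance is permutation importance on the held-out split (mean
AUC drop over 10 shuffles, averaged over repeats) — a reproducible
realization of a "conditional importance score". No class reweighting is
applied; the intended cohorts are near-balanced at the 1-year horizon.

## The synthetic-data generator

The generator exists so every stage is testable and calibratable without
patient data; it emulates the *statistical structure* the analysis
assumes, not glioma biology. Defaults are fixed at study-like
conditions: 396 GBM and 190 LGG patients; log-normal lesion volumes
(`mu = 3.1`, `sigma = 0.75` on the cm^3 log scale, matching a ~30 cm^3
mean with a long right tail); male fraction 0.54; KPS normal (mean 82,
SD 14) rounded to tens and clipped; ages ~N(60, 13) for GBM and
~N(43, 14) for LGG; exponential survival with median 14 months for GBM
at covariate means and a −1.1 log-hazard offset for LGG; censoring as an
independent coin flip at rate 0.2 with uniform censoring times.
Log-hazard is linear in centered volume (+0.02 per cm^3), mean SVZ
distance (−0.04 per mm; closer to the ventricles is worse) and age
(+0.02 per year). Lesions grow by stochastic dilation from a
field-weighted seed voxel — each boundary voxel is accepted with
probability proportional to the occurrence field — the simplest
generator of connected, irregular, tumor-like blobs. Grade-location
coupling tilts the GBM field by `exp(-beta * SVZ distance)` so GBM
lesions sit nearer the ventricles, while grade counts stay fixed.
Expression matrices plant `n_assoc` genes at a chosen correlation with
the regional frequency among spatially smooth noise genes (kernel-
smoothed over centroid distances); receptor maps use a Gaussian copula
with deterministic retries until the realized Spearman correlation is
within 0.075 of target.

What the generator does **not** emulate: MRI intensities, registration
error, scanner heterogeneity, multifocal tumors, realistic gene-gene
correlation structure, or any mechanistic growth model. Passing tests
therefore demonstrate that the *methods* are correct and calibrated
under their stated assumptions, not that real glioma data satisfy those
assumptions.

## Numerical choices and problem sizes

Deterministic seeding runs through a single helper that derives child
seeds below 2^31 from one master seed; every stochastic operation logs
its seed. Degenerate fits return 0/0 t statistics as 0 (zero effect with
zero residual variance) and mark truly rank-deficient voxels NA.
Frequency-map arithmetic is validated to 1e-12 against per-patient mask
means; PLS singular values to 1e-10 against dense SVD; distance maps to
1e-9 against an O(V^2) search; log-rank to 1e-10 against the risk-set
table. The calibration and recovery suites run at deliberately modest
sizes — 16^3 grids with 60-patient null worlds (200 permutations, 200
worlds) for the familywise error rate; 60-region, 100-gene worlds with
100 surrogates (200 replicates) for spin-test uniformity; 300-patient
cohorts for ROI and hazard-coupling recovery — sizes at which the Monte
Carlo error of the checked rates is a few percent and the whole suite
remains comfortably rerunnable during development.
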