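---
title: "Network-based radiomic signature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based radiomic signature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

## The problem

Locally recurrent rectal cancer (LRRC) is pelvic regrowth after resection of
a primary rectal tumour. On follow-up PET/CT, suspected recurrences are
delineated as a volume of interest (VOI); radiomics then summarises the
lesion by hundreds to thousands of quantitative descriptors — intensity
statistics, 3D shape, and texture-matrix features. With cohorts of a few
dozen patients and feature counts above a thousand, the selection of a small,
interpretable feature subset (a *signature*) dominates the quality of any
downstream classifier. `radsig` implements that workflow end to end:
voxel-level PET standardization, VOI transfer between grids, feature
extraction, pairwise network-based selection, and fold-averaged evaluation.

## PET voxel standardization

PET voxel activity is made comparable across scans by rescaling with injected
dose, decay since injection, and patient weight:

$$v' = v \cdot d \cdot e^{-(t - t_i)/\tau} / w$$

with dose $d$ (MBq), acquisition time $t$, injection time $t_i$, half-life
$\tau$ (s) and weight $w$ (kg). Two conventions are exposed. The default
(`"plain"`) evaluates the exponent exactly as written above. Physically,
when $\tau$ is a half-life the exponent should carry a $\ln 2$ factor so
that activity halves every $\tau$ seconds; `decay_convention = "ln2"`
selects that reading. We default to the plain form because it is the
relation as commonly printed in the clinical radiomics literature this
pipeline follows; the physical convention is one flag away. Note the
relation *multiplies* by dose and *divides* by weight — the inverse of the
conventional SUV body-weight formula; since the downstream per-fold z-scoring
absorbs any monotone affine rescaling, the choice does not affect selection
or classification, only the stored intensities.

Group placement of $w$ is ambiguous in some renderings of this relation; we
divide by $w$, the only dimensionally sensible reading (activity per unit
body mass).

## VOI transfer and the no-interpolation policy

Lesions are segmented on the PET grid and transferred to the CT grid by
nearest-neighbour lookup in world coordinates (0-based voxel indices, world
$= \mathrm{origin} + D\,(\mathrm{spacing} \circ \mathrm{index})$ with
orthonormal direction matrix $D$, i.e. the NIfTI affine). Nearest-neighbour
is the only rule that preserves binarity exactly, and no intensity
interpolation is performed anywhere: features are always computed on native
grids. The transfer is idempotent on a fixed grid and exactly
brute-force-checkable, which the test suite exploits.

## The feature registry: 7 classes, 3 filters, 1223 features

Per image/mask pair the engine computes:

| class | count | on filtered images? |
|---|---|---|
| first-order statistics | 18 | yes |
| 3D shape | 14 | no (geometry only) |
| GLCM (co-occurrence) | 24 | yes |
| GLRLM (run length) | 16 | yes |
| GLSZM (size zone) | 16 | yes |
| NGTDM (gray-tone difference) | 5 | yes |
| GLDM (dependence) | 14 | yes |

Original image: $18+14+24+16+16+5+14 = 107$ features. Filtered images carry
the 93 non-shape features each. The default filter bank is one undecimated
3D coif1 wavelet level (8 same-size sub-bands) plus Laplacian-of-Gaussian at
4 scales, $\sigma \in \{1,2,3,4\}$ mm, giving
$107 + 93\times(8+4) = 1223$ features. The four LoG scales are the unique
choice consistent with that total given one wavelet level; the scales
themselves (1–4 mm) are conventional lesion-texture scales. The wavelet is
undecimated so sub-bands stay on the mask's grid; boundary handling is
half-sample symmetric reflection. The LoG is scale-normalized
($\sigma^2 \nabla^2 G_\sigma$) with per-axis $\sigma$ in voxel units, so
anisotropic spacing is respected.

Texture matrices follow the IBSI formulations with these fixed conventions:

* **Discretization** — consecutive integer gray levels from 1; either a
  fixed bin count over the masked range (default 64, the PET-style default)
  or a fixed bin width anchored at the masked minimum (25 intensity units is
  the CT-style setting). Equal-width half-open bins, top edge closed;
  constant regions map to one level.
* **GLCM/GLRLM** — 13 unique 3D directions; GLCM symmetric; GLRLM matrices
  summed over directions before statistics.
* **GLDM** — dependence counted at tolerance $\alpha = 0$ over the
  26-neighbourhood with the centre voxel included in its own count, so the
  minimum dependence is 1 and Large Dependence Emphasis is $\geq 1$ on any
  nonempty mask.
* **NGTDM** — mean over available 26-neighbours; voxels with no in-mask
  neighbour are excluded.
* **Shape** — voxel-based, not meshed: surface area is the summed area of
  exposed voxel faces, volume is voxel count times voxel volume, diameters
  are distances between voxel centres (computed on surface voxels), axis
  lengths are $4\sqrt{\lambda}$ from the PCA of voxel-centre coordinates.
  These deliberately diverge from mesh-based definitions (by up to roughly
  the voxel scale) in exchange for being exactly checkable by brute force.

The four texture statistics and two shape statistics that form the
published-style signatures (first-order Entropy, GLDM Large Dependence
Emphasis, GLRLM Run Variance, NGTDM Strength, Maximum 3D Diameter, Surface
to Volume Ratio) additionally have independent first-principles reference
implementations (`reference_texture_feature()`, `reference_shape_feature()`)
written as plain loops with no shared code with the compiled engine; the
suite keeps the two paths within $10^{-6}$ relative on random phantoms.

Samples whose feature vector contains any non-finite value are dropped from
assembled tables with a warning naming the features — never imputed.

## Pairwise network selection

Given a table of $n$ samples by $p$ features with binary labels:

1. **Pair scoring.** Every unordered feature pair is scored by the mean
   across stratified $K$-fold cross-validation (default $K = 10$) of the
   test-fold Matthews correlation coefficient of a classifier trained on the
   pair's two columns. Columns are z-scored with training-fold means and SDs
   only, so scores are invariant to affine rescaling of any feature and no
   information leaks from test folds. One fold assignment, drawn from the
   seed, is shared by all pairs; a fixed seed gives bit-identical scores.
2. **Network.** Pairs with score $\geq \theta \cdot \max$ score (default
   $\theta = 0.95$), and always at least the top 10 pairs, become edges of a
   graph over features. The floor guarantees a nonempty network; both knobs
   are configurable, as no canonical retention rule exists. Nodes carry
   their degree and a category tag (co-occurrence/"haralick", gray-level,
   shape) for visualization.
3. **Signatures.** Each connected component is a putative signature,
   re-scored by the fold-averaged MCC of the classifier on all its features,
   and ranked by score; ties prefer fewer features (parsimony), then
   lexicographic order (determinism). Optional pendant-node pruning
   (degree-1 nodes in components larger than two) is off by default.

The scoring classifier defaults to the same SVC used for final evaluation.
For large $p$ the quadratic pair scan with an SVC is slow, so a
closed-form pooled-covariance linear discriminant (`kind = "lda"`, compiled)
is provided; it uses the identical folds, standardization and MCC. The
suite pins both paths to a naive per-pair refit oracle exactly.

## Evaluation

Metrics are the printed definitions: sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, $BAS = (\mathrm{sens}+\mathrm{spec})/2$, and

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with the standard convention $MCC = 0$ when any denominator factor is zero
(keeps rankings total). MCC equals the Pearson correlation between the
implied binary truth and prediction vectors, which the tests verify by an
exhaustive sweep.

Cross-validation is stratified and mandatory: with $n = 44$ at
$K = 10$ and a roughly 2:1 class ratio, folds hold 4–5 samples with 1–2
minority samples each, so both classes appear in every training and test
split; the fold maker refuses configurations where the minority class is
smaller than $K$. Metrics are computed per fold on held-out samples only and
arithmetically averaged ("averaged out", not pooled); pooled-count metrics
are retained in the report for audit. The SVC uses the RBF kernel with
backend defaults (cost 1, $\gamma = 1/p$ on standardized columns) and class
weights inversely proportional to class frequencies; hyperparameters are
echoed verbatim into every report, and there is deliberately no tuning loop.
The three-model experiment evaluates the best CT signature, the best PET
signature, and their column union on id-aligned tables, mirroring the
published three-row layout.

## What the synthetic data does and does not emulate

Because the patient data is access-restricted, the package ships a
generator for each input type.

**Feature tables.** 44 samples, 29 positive (prevalence 29/44), planted
pairs plus standard-normal noise features. A planted pair with effect size
$\delta$ and correlation $\rho$ has class means at $\pm(\delta/2)$ along
$(1,-1)/\sqrt 2$ and covariance with variance $1+\rho$ along
$(1,1)/\sqrt 2$ and $1-\rho$ across it (unit marginal variances). Jointly
the classes are $\delta/\sqrt{1-\rho}$ SD apart; each marginal alone is
only $\delta/\sqrt 2$ SD apart. At the default $(\delta, \rho) = (2.5,
0.7)$ the joint separation is ~4.6 SD while marginals sit at ~1.8 SD —
informative pairs beyond their marginals, which is precisely the regime the
selection method targets. Note the two strengths scale together: at large
$\delta$ the marginals are themselves strong, so single planted features
also form high-scoring pairs with noise; genuinely weak marginals with a
strong pair require small $\delta$ and $\rho$ near 1 (e.g. $\delta = 1$,
$\rho = 0.95$, which the property tests use).

**Phantoms.** Ellipsoidal lesions on a CT-like absolute intensity scale
(base 100, texture SD = the `heterogeneity` parameter, default 30 for
recurrent-like vs ~7.5 for homogeneous lesions, white noise SD 5). Texture
is a two-scale smoothed Gaussian field, so heterogeneity is spatially
structured rather than voxelwise. The PET-like sibling is the same lesion
smoothed (σ = 2.5 voxels) and rescaled, emulating lower PET resolution.
Discretizing CT-like phantoms with fixed 25-unit bins makes first-order
entropy sensitive to heterogeneity; with fixed-bin-*count* discretization,
entropy is nearly scale-free and would not separate the classes — a useful
reminder that discretization policy is part of the feature definition.

The generators emulate the *statistical* structure the pipeline assumes —
class imbalance, jointly-informative pairs, texture-contrast classes — and
none of the physics: no anatomy, attenuation, partial-volume or scanner
effects. Tests passing on synthetic data therefore validate the machinery
(formulas, folds, determinism, selection behaviour), not clinical
performance; the published real-data metrics are not reproducible without
the restricted cohort.

## Numerical and degenerate-input choices

* Constant features are dropped (with a warning) before pairing; constant
  columns inside a fold standardize with SD fixed to 1.
* A singular 2×2 pooled covariance in the LDA scorer gets a $10^{-6}$ ridge.
* GLCM correlation is defined as 1 for a single occupied gray level;
  skewness/kurtosis of constant regions are 0; NGTDM coarseness is capped
  at $10^6$; elongation/flatness of a single voxel are 1.
* Empty masks, geometry mismatches, non-positive dose/weight/half-life and
  acquisition before injection are rejected with parameter errors.
* All randomness flows from explicit integer seeds (fold assignment,
  generators); the pipeline fans one global seed out to stage seeds by
  fixed offsets, so stages are independently reproducible.

## Problem sizes used in the shipped experiments

The bundled analysis scripts and the acceptance script run at the study's
cohort shape (44 × ~100 features per modality table, 10-fold CV), 50-seed
recovery experiments, 100-permutation nulls, 100 random 4³ phantoms for the
reference-feature cross-checks, and a 32³ phantom for the full
1223-feature extraction — sizes chosen so the whole battery completes in
minutes on a laptop while still exercising every code path at the cohort's
actual dimensions.

## Known limitations

* Only the six signature features have independent native references; the
  remaining registry features follow IBSI formulas but are validated by
  invariants (count accounting, padding invariance, filter stability)
  rather than per-feature oracles.
* Shape features use voxel conventions, not meshes; values differ from
  mesh-based implementations by up to the voxel scale.
* The wavelet is a single undecimated level; deeper decompositions are
  supported by à-trous filter dilation but untested beyond level 2.
* The retention rule ($\theta$, floor) has no canonical published value;
  defaults aim for a handful of small components at this cohort scale and
  are explicitly configurable and logged.
* No DICOM ingestion, no segmentation tooling (masks are inputs), no
  ROC/calibration analysis, and no hyperparameter search, by design.
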