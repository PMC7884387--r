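---
title: "Methods: quantitative attribution of an isolated molar and a lithic assemblage"
author: "paleoattrib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative attribution of an isolated molar and a lithic assemblage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoattrib)
```

## Scope and model of the problem

`paleoattrib` implements the quantitative chain by which an isolated
hominin molar — and, secondarily, an associated stone-tool assemblage —
is attributed to a population when no destructive sampling is possible:

1. **Metric comparison** of single-specimen crown/root measurements
   against comparative group summaries via prediction-interval scaled
   ("adjusted") Z-scores.
2. **3D tissue quantification** on a segmented voxel volume: lateral
   enamel thickness (LAET/LRET) and the volumetric bifurcation index
   (VBI) of taurodontism.
3. **Shape analysis** of semilandmark configurations on the
   enamel–dentine junction (EDJ): generalized Procrustes analysis (GPA),
   PCA, between-group PCA (bgPCA) with leave-one-out cross-validation,
   canonical variate analysis (CVA), and a-posteriori projection of the
   unknown specimen.
4. **Lithic attribute analysis**: morphological indices, rank-based
   normalization, PCA ordination, and convex-hull overlap summaries.

Because the comparative fossil scans and artefact tables behind such
studies are typically not deposited, the package ships synthetic
generators that emulate the statistical structure each stage assumes;
every generator carries closed-form ground truth, so the whole pipeline
is testable end to end without any external data.

## Adjusted Z-scores

A single specimen `x` is scored against a comparative group with mean
$\bar{X}$, sample standard deviation $SD$ (denominator $n-1$) and size
$n$ as

$$z_{adj} = \frac{x - \bar{X}}{t_{1-\alpha/2,\,n-1}\sqrt{SD^2 (1 + 1/n)}}.$$

The denominator is the half-width of the two-sided Student-t
*prediction* interval for one new draw from the group's population, so
at the default $\alpha = 0.05$ the event $|z_{adj}| \le 1$ means "inside
the interval expected to contain 95% of the group's variation". The
$\sqrt{1+1/n}$ term propagates the uncertainty of the group mean; as
$n \to \infty$ the score tends to the classical z-score divided by
$z_{0.975} \approx 1.96$. The construction is exact: the pivot
$(x - \bar{X})/(SD\sqrt{1+1/n})$ is $t_{n-1}$-distributed, so coverage
is 95% at *any* $n \ge 2$ — the property the acceptance suite verifies
by Monte Carlo at $n \in \{5, 10, 20, 50\}$.

`sd = 0` with `x != mean` returns signed infinity rather than an error:
a degenerate comparative sample cannot contain any deviating specimen.
Wear adjustment of the mesiodistal length is deliberately *not*
implemented; where crowns are interproximally worn, the caller supplies
an already-adjusted length (the adjustment methods in the literature are
tied to tooth class and wear stage, and inventing one here would
fabricate data semantics).

## Tissue quantification

All voxel operations use 0-based, half-open index semantics: a voxel of
edge `voxel_size` (mm) is counted wholly by its center, and a center
exactly on a cut plane belongs to the side below the plane (along the
plane normal). This makes consecutive crops and the stem/branch split
*conservation-exact* at the voxel-count level — `v_cervix + v_branch`
equals the total root tissue volume identically, which the tests assert.

* **HMH threshold**: the midpoint of two material intensities, the
  standard segmentation threshold at a material interface.
* **Cervical plane**: total-least-squares fit (SVD) to digitized cervix
  points, with the normal oriented toward a declared occlusal direction.
* **LAET/LRET**: `LAET = V_enamel / S_EDJ` (mm) on the lateral crown
  volume between the cervical plane and the last-enamel occlusal plane;
  `LRET = 100 · LAET / V_dentine+pulp^(1/3)` (dimensionless). The
  denominator of LRET is the lateral coronal dentine-plus-pulp volume —
  recorded here as an explicit assumption, since published tissue
  studies inherit the formula from cited protocols without restating it.
* **EDJ surface area**: naive counting of enamel–dentine voxel faces
  overestimates oblique and curved surfaces (a plane tilted 45° in two
  axes by a factor $\sqrt{3}$; a vertical cylinder by $4/\pi$). The
  package's default estimator weights each boundary face by
  $|\hat{n}\cdot\hat{e}|$, where $\hat{n}$ is the local surface normal
  estimated from a box-smoothed mask gradient (window 5 voxels) — exact
  for planar interfaces and accurate to ~1–2% on smooth curved phantoms.
  Plain face counting with a configurable correction factor (default the
  classical orientation-averaged 2/3) remains available as
  `area_method = "face_count"`, but note that a single fixed factor
  cannot be accurate for all orientations: for a vertical cylindrical
  EDJ it underestimates the area by ~15%, which is why it is not the
  default.
* **VBI**: `100 · Vcervix / (Vcervix + Vbranch)` with the bifurcation
  plane parallel to the cervical plane at the interradicular surface.
  By default the interradicular level is located automatically as the
  most occlusal slab in which the root cross-section splits into two or
  more connected components; since no published algorithm exists for
  this placement, the level can always be supplied explicitly. The
  automatic rule requires an axis-aligned cervical normal (its slab scan
  is grid-based); arbitrary planes require the explicit level.
* **Stem volume** counts all root tissues (dentine + pulp) by default;
  whether published stem volumes include the pulp canal is not stated in
  the protocols this follows, so the tissue set is configurable
  (`tissue_labels`).

## Shape analysis

**Resampling.** Digitized outline curves are resampled to fixed
semilandmark counts by arc length, endpoints preserved. No semilandmark
sliding is applied: the emulated protocol describes fixed curve
semilandmarks and names no sliding criterion, and introducing
bending-energy machinery would add unverifiable free parameters.

**GPA.** Iterative: center, scale to unit centroid size, rotate to the
consensus by the Kabsch solution with reflections disallowed
(anatomical configurations are side-specific); the consensus is
re-estimated until it moves less than `1e-10`. A Procrustes solution is
defined only up to one global rotation, so the converged constellation
is rotated to the consensus's principal axes with deterministic signs —
this makes residuals bitwise comparable across runs and is what the
"invariance under pre-applied rigid motions" tests check to `1e-8`.
Centroid sizes are taken before scaling.

**bgPCA.** Axes are the principal components of the group-mean residual
vectors — unweighted by default (every group counts equally, a flag
enables size weighting; the emulated protocol does not say which it
used) — with all specimens projected onto them; at most $g-1$
informative axes. bgPCA is prone to *spurious separation* when variables
outnumber specimens, so classification claims rest on leave-one-out
cross-validation (`cv_bgpca`): group means and axes are re-estimated
without the held-out specimen in every fold. The Procrustes alignment is
*not* re-run per fold by default (alignment is a whole-sample geometric
normalization; re-running it per fold is available via `refit_gpa` and
changes results negligibly at these sample sizes).

**Classification.** Mahalanobis distances to group means use the pooled
within-group covariance, ridge-regularized by
$\lambda = 10^{-8}\,\mathrm{tr}(W)/m$ (configurable) because small
samples with many variables make singularity routine. Posteriors are the
equal-prior Gaussian form $\propto \exp(-d_g^2/2)$; chi-square
"typicality" tail probabilities are reported alongside, since either
convention appears in the morphometric literature. By default distances
use the Gaussian *predictive* scaling $d_g^2/(1 + 1/n_g)$, which
accounts for the sampling error of each estimated group mean. This
matters in leave-one-out runs: with plug-in distances the held-out
specimen's own group (one specimen smaller) is systematically
disadvantaged, biasing null-data accuracy below chance; the predictive
form removes the asymmetry. Ties are broken deterministically by
group-name order and flagged.

**CVA.** Canonical axes from $W^{-1}B$ on the first $m$ PC scores, with
$m$ chosen as the smallest count whose cumulative explained variance
reaches 90% (`select_pcs`), subject to $m \le n - g$. Axes carry
Mahalanobis scaling (unit within-group variance); with spherical
within-group covariance they coincide with the bgPCA axes, an algebraic
identity the tests verify to `1e-6`. Leave-one-out classification refits
the CVA in every fold.

**Unknown projection.** The unknown is aligned to the *training*
consensus by ordinary Procrustes (center, unit centroid size, optimal
rotation) and its residual is projected onto the trained axes; training
scores are untouched. Projecting a training specimen reproduces its
scores to `1e-9`, and projecting the consensus lands at the origin.

**Allometry.** Per-axis OLS regression of score on centroid size (or its
log), reporting slope, $R^2$ and the F-test p-value; numerically exact
fits are flagged rather than warned about.

## Lithic analysis

Indices follow the callipered-attribute conventions: elongation =
length / medial width; proximal shape = proximal / medial width; distal
shape = medial / distal width; flattening = medial width / medial
thickness; TCSA = distal width × distal thickness (mm²). TCSA is the
plain product by design fidelity; the lenticular-section convention
0.5·w·t is available behind `tcsa_half` and clearly named. Zero or
missing denominators yield `NA` with a warning — batch processing of
museum assemblages must not abort on one broken artefact.

Normalization is the rank-based ordered-quantile transform
(`qnorm((r - 0.5)/n)`, average ranks for ties), the transform a
best-normalizing search nearly always selects for right-skewed metric
data, followed by centering and unit scaling; fitted value/score pairs
are stored so held-out rows map into the same space by monotone
interpolation with linear tail extrapolation. Log and no-op transforms
are selectable. Ordination is plain centered/scaled PCA on a
complete-case basis with the exclusion count reported; categorical
columns are never entered (the emulated biplots are metric, and mixing
would require unstated encodings). Convex-hull overlap in a chosen score
plane is Jaccard area overlap (intersection over union, via exact convex
polygon clipping), with centroid distances and a "falls within" flag.

## Synthetic generators and what they do not show

* `simulate_shape_groups()` builds specimens as template + group
  deformation + optional allometric term + i.i.d. Gaussian landmark
  noise, then applies random similarity transforms. Group deformations
  are smooth random vectors *orthogonalized against the similarity
  directions* (translations, rotations, scaling), so the injected
  between-group difference is pure shape of known magnitude. The default
  template is a closed five-peaked rim of 116 semilandmarks in five
  curves (24, 23, 23, 23, 23) mimicking an EDJ marginal outline; only
  the total of 116 is anchored in the emulated protocol, the per-curve
  split is a recorded free choice. Defaults — three groups, n = 20 per
  group, noise SD 0.01 mm, effect magnitude 0.1 mm (10× noise), centroid
  size log-SD 0.05 — are the separation regime under which published
  EDJ classifications operate; they are fixed study conditions, not
  tuning knobs.
* `simulate_tooth_phantom()` and `phantom_shell()` are constructive
  solid geometry with exact closed-form compartment volumes and areas;
  ground truth is computed from the parameters, never measured from the
  voxelization. Feature under-resolution (any feature thinner than 3
  voxels) is an error naming the required voxel size.
* `simulate_lithic_assemblages()` draws lognormal metrics (positive
  support, exact class means by construction) with a common coefficient
  of variation, default 0.15 — mid-range for callipered artefact
  dimensions.

What passing tests on these generators *do not* show: real EDJ shape
spaces are not isotropic Gaussian perturbations of one template; real
enamel caps are not cylinders; real artefact attributes correlate
beyond a shared scale. The generators validate the estimators'
correctness and calibration, not any empirical claim about fossils. In
particular, published classification percentages for specific fossil
samples cannot be reproduced without the original comparative scans,
which are not deposited; the package's acceptance checks therefore
substitute property-based criteria (parameter recovery under strong
separation, chance-level accuracy under label permutation, exact
invariances).

## Numerical choices

* GPA convergence `1e-10` on the consensus; canonical principal-axis
  orientation with sign fixed by the largest-magnitude coordinate and
  determinant +1.
* Plane parallelism tolerance `1e-6` rad; voxel-center tie-break to the
  lower side.
* Ridge $\lambda = 10^{-8}\,\mathrm{tr}(W)/m$; when a degenerate sample
  has zero within-group scatter the ridge falls back to the overall
  score scale so $W$ stays invertible.
* Posterior ties flagged at relative difference `1e-9`; underflow
  avoided by log-sum-exp.
* Box-smoothing window for surface normals: 5 voxels.
* All randomness flows through explicit `seed` arguments (default
  20210215); generators restore the global RNG state.

## Problem sizes used by the test and acceptance suites

Monte-Carlo coverage uses 100,000 replicates per comparative sample
size; phantom recovery uses voxel sizes of 0.04–0.12 mm on features of
1.8–5 mm (tissue volumes within 2%, LAET within 5%); shape-recovery
simulations use 20 specimens per group with 116 3D semilandmarks; the
spurious-separation guard uses a 30 × 150 homogeneous Gaussian matrix
with permuted two-group labels, mirroring the two-group metameric
design. These sizes were chosen so every property is measured well
inside its stated tolerance while the full suite runs in well under a
minute of compute per module.

## Known limitations

* No semilandmark sliding; no mesh (surface) file formats, DICOM, or
  image registration; no interactive segmentation.
* Whole-crown (cuspal) enamel thickness is out of scope — the lateral
  restriction exists precisely because worn crowns lose cuspal enamel.
* Automatic bifurcation detection requires an axis-aligned cervical
  plane and a genuinely bifurcated root (a single-branch root is
  reported as such, with the VBI left undefined).
* The TPS dialect is minimal (LM/LM3, IMAGE, ID); unknown keys warn and
  are ignored. NRRD support covers text encodings only.
* Non-metric trait scoring (ASUDAS) and wear staging are out of scope.
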