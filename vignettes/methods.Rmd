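---
title: "Methods: marker extraction and two-stage grading of liver tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker extraction and two-stage grading of liver tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hepatocellular carcinoma surveillance grades focal liver lesions on the
LI-RADS scale, from LR1 (definitely benign) to LR5 (definitely malignant),
using four-phase contrast-enhanced imaging: pre-contrast, late arterial
(~35 s), portal venous (~50 s) and delayed (~180 s) acquisitions.
`hepatocad` implements a complete computer-aided pipeline for this task:
given the four co-registered phase volumes and a binary tumor mask, it
derives 249 quantitative markers per tumor — 70 morphological, 176
textural, 3 functional — selects informative subsets, and grades the tumor
with a two-stage random-forest classifier (first
benign/intermediate/malignant, then LR1 vs LR2 and LR4 vs LR5 within the
outer groups).  A grade-conditioned phantom generator makes every stage
testable without clinical data.

## Morphological markers: spherical-harmonic reconstruction errors

The biological premise is that malignant tumors grow faster and present
more complex, spiculated surfaces.  The pipeline quantifies this as
follows.

1. **Surface extraction.** The mask's boundary voxel faces are
   triangulated into a closed genus-0 mesh (vertices in mm) and smoothed
   with 10 iterations of Laplacian averaging at step 0.5.  Meshes that are
   not closed 2-manifolds (fragmented or pinched masks) are rejected as
   degenerate rather than repaired, since the spherical parameterization
   below requires spherical topology.

2. **Spherical parameterization.** The mesh is mapped one-to-one onto the
   unit sphere by an attraction–repulsion iteration.  Each node is pulled
   toward its mesh neighbours by a term with a cubic long-range component
   and a constant-magnitude short-range component (weights `CA1 = 0.003`,
   `CA2 = 0.3`), inflated away from all other nodes by a pairwise
   repulsion proportional to the inverse squared distance (`CR = 1`,
   scaled by `1/(2I)`), and re-projected onto the sphere.  Iterations stop
   when no node moves more than `T = 1e-4`, or at `max_iters` (5000 by
   default).  The constants are not dictated by theory; these values
   converge stably on icosphere fixtures and are exposed in the
   configuration.  Two reading choices deserve note: the repulsion
   displacement is oriented to push nodes *apart* (the stated purpose of
   the step), and it is recomputed from the post-attraction positions so
   that it counteracts the attraction just applied; a `literal_alpha`
   switch reverts to pre-attraction positions.  The initial map is the
   radial projection about the node centroid, which is adequate for
   near-star-shaped tumors; strongly folded surfaces may need more
   iterations and are a known limitation.

3. **Harmonic expansion.** With each node assigned spherical angles, the
   three Cartesian coordinate functions are least-squares fitted with real
   orthonormal spherical harmonics (no Condon–Shortley phase) of degree at
   most d, for d = 1..70.  The fit is coordinate-wise rather than radial
   so that non-star-shaped surfaces remain well defined.  The marker
   `SH_err_d` is the summed Euclidean distance between the mesh nodes and
   their degree-d reconstruction.  A smooth quasi-ellipsoidal tumor is
   captured by a handful of degrees; a spiculated one leaves error mass at
   high degrees.

Numerical choices: when the mesh has fewer than `(L+1)^2` nodes the mesh
and map are midpoint-subdivided together (new sphere points are normalized
edge midpoints) until the system is overdetermined — midpoint rather than
full Loop subdivision because repositioning vertices would change the very
geometry whose reconstruction error is being measured.  All 70 nested fits
come from a single Cholesky factor of the Gram matrix of the degree-ordered
basis: the leading k×k block of the factor is the factor of every prefix
model, so no per-degree refactorization is needed.  A vanishing pivot is
handled with a jitter of `1e-10 * mean(diag(G))`.  Because the error is a
sum of unsquared node distances, nestedness guarantees monotonicity only of
the squared-error curve; the distance sum can rise by a sliver (observed
up to ~0.05% on adversarial symmetric surfaces), which is why the tests
allow a 0.2% tolerance on monotonicity.  One analytic subtlety: a pure
degree-6 *radial* bump on the sphere has coordinate-function content at
degrees 5 and 7, not 6 (parity selection in the product with the degree-1
direction field), so error curves collapse after degree 7 for that
surface.

## Textural markers

All texture is computed on the mask voxels only, after an affine min–max
quantization of the per-phase intensities to integers 0..255 (a constant
region maps to zero).  Quantizing per tumor and per phase makes every
texture marker invariant to affine intensity rescaling, which stands in
for the absent inter-patient intensity standardization of the acquisition.

* **First order (26 per phase):** mean, variance, standard deviation,
  skewness, kurtosis and Shannon entropy (bits) of the normalized level
  histogram; the histogram CDF at the ten thresholds `k*25.5`; and the ten
  percentile levels at cumulative probabilities 10%..100%.  Population
  moments are used; zero-variance regions take skewness = kurtosis = 0.
* **GLCM (6 per phase):** one pooled 3D co-occurrence matrix over all 18
  voxel offsets of Euclidean length 1 or √2 (both orders, hence symmetric;
  the √3 corner offsets are excluded).  Pooling every direction makes the
  matrix exactly invariant under the octahedral symmetries of the grid,
  which is the rotation-invariance claim the tests verify bit-for-bit.
  Markers: contrast, dissimilarity, homogeneity, angular second moment,
  energy, correlation (1 by convention at zero marginal variance).
* **GLRLM (12 per phase):** maximal constant-level runs pooled over the
  two in-plane axes and the through-plane axis (D = 3).  The matrix has
  256 rows and as many columns as the largest mask bounding-box extent.
  The twelve standard statistics use gray-level weights g+1 so the
  low/high gray-level emphases stay finite at level 0, and run percentage
  divides the run count by `D*N`, keeping it in (0, 1] under pooling.

## Functional markers

The enhancement curve is the mean raw mask intensity per phase at the
nominal times (0, 35, 50, 180) s; the three markers are the piecewise
slopes in intensity/s: wash-in (pre → arterial), and the two wash-out
segments (arterial → portal venous, portal venous → delayed).  The mean
was chosen as the aggregation statistic (the source does not specify one);
a relative-enhancement variant `(I - I_pre)/I_pre` is available behind a
configuration switch, default off.

## Marker selection

Three procedures are provided.  The wrapper procedures model the ordinal
class code (0, 1, 2 for the three-group problem) with ordinary least
squares and use partial-F tests — the classical stepwise machinery, chosen
because the source does not name its inner model; a logistic variant was
considered and rejected for the extra separability failure modes on tiny
cohorts.  *Forward selection* adds the candidate with the smallest
p-value while it is below the threshold (0.05 or 0.10 conventionally).
*Bi-directional elimination* adds a backward sweep dropping any included
marker whose drop-one p-value rises above the removal threshold, with a
cycle guard.  *Gini selection* fits the package's random forest and keeps
markers whose normalized mean-decrease-in-impurity importance exceeds the
mean importance — the common default cut-off, since the source reports
only the resulting counts on its private data; in `separate` mode the rule
is applied within the morphological / textural / functional groups
(functional included: the methods text lists it even though one table
caption omits it) and survivors are pooled.

## Two-stage grading

Stage 1 is a three-class classifier on benign (LR1-2) / intermediate (LR3)
/ malignant (LR4-5); stage 2 holds two binary classifiers, LR1 vs LR2 and
LR4 vs LR5, trained on the ground-truth subgroups and applied after
stage-1 routing at inference (training on predicted routing was rejected
as it contaminates the stage-2 labels).  The default classifier is a
random forest of 100 gini trees with balanced class weights, depth cap 30,
minimum 5 samples per leaf and 2 per split, `mtry = floor(sqrt(p))` —
implemented in C++ inside the package because no tree learner exists in
the target environment.  Alternatives behind the same interface: fine kNN
(5 neighbours, Euclidean, uniform weights), polynomial-kernel SVMs (cubic
and quadratic, C = 1, gamma = 0.001) solved as a dual QP with one-vs-one
voting, Gaussian naive Bayes (the Bernoulli smoothing parameters printed
in the source are meaningless for continuous markers), and LDA with the
pooled covariance shrunk toward its average eigenvalue (s = 0.52).

Evaluation follows the bespoke three-group definitions: TP = malignant
subjects predicted malignant, TN = benign predicted benign, FP = benign or
intermediate predicted malignant, FN = malignant or intermediate predicted
benign; sensitivity, specificity and F1 derive from these, alongside the
5×5 confusion matrix and per-grade recall.  Cross-validation schemes:
leave-one-subject-out (fixed folds; only the classifier seed varies across
the 10 repeats) and stratified 10- and 5-fold (folds re-randomized each
repeat, stratified on the three-group label so each fold keeps the
40/20/40% composition).  Any marker selection is re-fitted inside each
training fold; the no-leakage test verifies that shuffling test-fold
labels changes neither the selected subset nor the test predictions.

## The phantom generator: what it emulates, and what a green test means

Each phantom is a star-shaped tumor `r(θ, φ) = r0 (1 + a f(θ, φ))` with
`f` a unit-RMS random combination of spherical harmonics in a
grade-specific degree band, voxelized into a mask; star-shapedness
guarantees a valid spherical parameterization and known harmonic content.
Grade conditioning (defaults, all overridable):

| grade | surface amp `a` | band (degrees) | texture corr. σ (vox) | white fraction | wash-in (int/s) | PV slope | delayed slope |
|------|------|-------|-----|------|------|-------|-------|
| LR1  | 0.015 | 2–4   | 2.5 | 0.10 | 0.6  | −0.10 | −0.02 |
| LR2  | 0.03  | 3–6   | 2.1 | 0.20 | 0.9  | −0.25 | −0.05 |
| LR3  | 0.05  | 5–10  | 1.8 | 0.35 | 1.4  | −0.50 | −0.08 |
| LR4  | 0.07  | 8–16  | 1.4 | 0.50 | 2.0  | −0.90 | −0.12 |
| LR5  | 0.09  | 12–24 | 1.0 | 0.65 | 2.6  | −1.20 | −0.15 |

Kinetic rates and the surface amplitude carry an 8% log-normal per-study
jitter, so a cohort is a sample rather than five points; the pre-contrast
mean is 100 intensity units and phase means follow the piecewise-linear
curve at (0, 35, 50, 180) s.  The texture field is a mixture of
FFT-smoothed Gaussian noise (correlation length = smoothing σ) and white
noise, scaled to the grade's amplitude, shared multiplicatively across
phases and zero-meaned inside the mask — hence generative slopes are
recovered by `enhancement_slopes` to well within 2%.  Note that after
min–max quantization the texture *amplitude* is invisible to the texture
markers (by design, they are affine-invariant); the textural grade signal
is carried by the correlation length and the white-noise fraction.

Two voxelization safeguards keep the generator inside the morphology
module's topology contract: surface degrees beyond ~πr/2 (4-voxel
wavelength) are capped, because finer waves voxelize into tunnels rather
than spikes; and if a sampled surface still folds below voxel resolution,
the amplitude is damped by factors of 0.75 (same random field) until the
boundary is a closed genus-0 surface.  Masks are also repaired
deterministically for edge-only and corner-only voxel contacts, which
would otherwise produce non-manifold boundary meshes.

What the phantoms do *not* emulate: MR physics (bias fields, motion,
partial volume), anatomy around the tumor, non-star-shaped or multifocal
lesions, and realistic inter-marker correlation structure.  A green
end-to-end benchmark therefore establishes that the pipeline wiring,
marker mathematics and evaluation protocol are correct and that the
classifier recovers a grade signal of the stated effect sizes — it does
not certify clinical performance, and the default effect sizes make the
three-group problem clearly solvable (LOSO sensitivity and specificity
≥ 0.9) while the five-grade problem remains imperfect, qualitatively
matching the harder clinical setting.

The acceptance benchmark runs this cohort at desk scale (24-voxel grid,
radius-6 tumors, `L_max = 15`, attraction–repulsion capped at 100
iterations) so twenty full generate–extract–evaluate cycles fit the stated
runtime budget; the generator's grade structure is scale-free, though the
morphological contrast between adjacent grades compresses at small radii
(the high-degree bands hit the resolution cap).  Module-level shape tests
run at radius 8–10 where the bands resolve.

## Known limitations

* The attraction–repulsion iteration is O(I²) per sweep; meshes beyond a
  few thousand nodes dominate extraction time.
* The radial-projection initialization assumes near-star-shaped tumors.
* Marker values at `L_max < 70` are a schema prefix, not a re-fit: degree
  truncation changes nothing below the cut.
* The CSV marker table stores doubles at 17 significant digits; exact
  round-trips rely on that.
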