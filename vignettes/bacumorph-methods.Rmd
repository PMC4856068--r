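---
title: "Landmark-free baculum morphometrics and QTL mapping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free baculum morphometrics and QTL mapping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bacumorph` turns a micro-CT scan of an elongate, landmark-poor bone into
two scalar phenotypes — centroid size and a discriminant shape score — and
maps them across a recombinant inbred panel. This vignette explains the
model behind each stage, the tunable parameters and why their defaults are
what they are, the numerical conventions, and the places where the design
was genuinely open and a choice had to be made. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. Canonical alignment

A segmented bone arrives as an n x 3 point cloud in scanner coordinates
(units: whatever the voxel size is expressed in; the default
`voxelSize = 0.0155` means millimetres for a 15.5 um scan). Alignment is a
composition of proper rigid motions only — reflections are never allowed,
because bacula are chiral and a mirrored bone is a different shape.

1. **Provisional axis.** The two points furthest apart define the
   proximal-distal axis. The diameter is computed exactly on the convex
   hull (the endpoints of a diameter are always hull vertices), with ties
   broken lexicographically so the result is deterministic.
2. **Which end is proximal?** The baculum base is broad and the tip
   narrow, so the end slab with the larger cross-section MBR area is
   taken as proximal. This heuristic can be overridden per specimen
   (`proximalEnd = "low"/"high"`) for unusual material.
3. **End-centroid registration.** The 10% most proximal and distal point
   slabs (`endFrac = 0.10`, measured as fractions of the z extent,
   half-open intervals `[lo, hi)`) are cut out and the centroid of each
   slab's convex hull computed. The transform maps the proximal centroid
   to the origin and the distal centroid onto +z. Two details:
   * *Hull centroid.* The default (`endCentroidMode = "hull_volume"`) is
     the volume-weighted centroid of the hull polyhedron via tetrahedral
     decomposition, which is insensitive to how densely points happen to
     be sampled; the mean of hull vertices (`"hull_vertex"`) and the
     plain slab mean (`"plain"`) are available as options. A degenerate
     (coplanar) slab falls back to the plain centroid with a warning.
   * *Fixed-point iteration.* The slabs are defined along the provisional
     axis, so a single registration still depends on step 1. We iterate
     the registration until the incremental transform is the identity to
     1e-12. The iteration converges in a handful of steps and makes the
     whole alignment idempotent (re-aligning an aligned cloud changes
     coordinates by < 1e-6) and invariant to rigid motions of the input —
     properties the test suite asserts over 100 random poses.
4. **MBR orientation.** The points at 15.00-15.25% of the z extent
   (`mbrBand`) form a cross-section whose minimum-area bounding
   rectangle — computed by rotating calipers over the 2D hull edges —
   defines the x axis (long side) and y axis (short side). The rotation
   applied is the smaller of the two half-turn-equivalent angles. An
   empty band is widened by symmetric thickness doubling, at most five
   times, with a warning.
5. **Dorsoventral sign.** The bone's distal curvature breaks the
   remaining 180-degree ambiguity: if the mean y of the most-distal 25%
   of points (`distalFrac`) is negative, the cloud is rotated by pi about
   z (a proper rotation; the x flip it entails is harmless because the
   MBR long side is defined modulo pi). When the distal mean y is within
   three standard errors of zero the orientation is genuinely ambiguous
   (a straight bone); no flip is applied and a warning is recorded. The
   3-SE criterion was chosen over a fixed epsilon because sampled point
   clouds of a straight bone leave a mean-y residual at the
   standard-error scale, not at machine precision.

## 2. Semilandmarks and centroid size

Fifty slices (`nSlices = 50`), each 0.25% of the z length thick
(`sliceThicknessFrac = 0.0025`), are centered at `(i - 0.5)/50` of the z
range — the half-offset avoids empty half-bands at the tips. Within a
slice of width W, seven lines (`nLines = 7`) are placed at interior
eighths of W; the published recipe does not state the line positions, and
interior eighths were chosen because the slice's extreme x points are
already captured by the leftmost/rightmost landmarks. Points within 4% of
W of a line (`projectionTolFrac = 0.04`) are projected onto it (x set to
the line; y, z kept) and the extreme-y points become the dorsal and
ventral semilandmarks; empty windows double their tolerance up to five
times. All extremal picks break ties by smallest z, then the smallest
remaining coordinate, so extraction is a pure function of (points,
config). With the two tips, a bone yields 50 x 16 + 2 = 802 labeled
points. A band is considered usable once it contains two points with
distinct x; sparse tip bands widen like empty ones.

Centroid size `CS = sqrt(sum_k ||p_k - centroid||^2)` is the size
phenotype: rotation/translation invariant and exactly linear in isotropic
scale (asserted to 1e-9 under random rigid motions).

## 3. Procrustes shape space and the LD1 score

Configurations are centered, scaled to unit centroid size and rotated to
an evolving consensus (optimal rotations from the SVD of the
cross-covariance, determinant-corrected to exclude reflections) until the
consensus moves by less than `tol = 1e-9`. The distance between two
specimens is the Euclidean norm between their final superimposed
unit-size configurations; for two specimens this reduces to the pairwise
optimal superimposition, which the tests assert to 1e-6.

**Sliding.** Semilandmarks are placed by a geometric rule, not homology,
so during superimposition each non-tip landmark may slide to minimize the
thin-plate-spline bending energy (3D kernel -r) between the specimen and
the consensus. No surface mesh exists, so tangent directions come from
neighboring semilandmarks: dorsal/ventral landmarks get a tangent plane
spanned by the within-slice ring direction and the adjacent-slice
direction; leftmost/rightmost landmarks slide only along the lateral
margin (adjacent slices), because sliding them around the ring would
contradict their defining rule; tips are fixed. The slide is the exact
minimizer of the bending-energy quadratic over tangent moves (with a
1e-8 relative ridge for conditioning), so bending energy can only
decrease — the per-pass energies are recorded in `slideDiagnostics` and
the tests assert the monotonicity. Three slide-and-resuperimpose passes
(`slideIter = 3`) are run; the slid points are not projected back onto a
surface (there is none), which is the standard treatment for
point-sampled material. Bending energy was preferred over minimizing
Procrustes distance directly because it penalizes physically implausible
local distortions; this is the conventional objective for sliding
semilandmarks.

**LD1.** The shape summary is a linear discriminant between the two
parental strains. The published description — "LDA on the pairwise
distance matrix" — is ambiguous, because a distance matrix is not a
feature matrix. We embed the *parental block* of the distance matrix by
classical multidimensional scaling (PCoA), retain components up to the
smaller of 95% explained variance and (number of parentals - 2), fit a
two-class LDA there, and score every other specimen by the Gower
out-of-sample extension from its distances to the parental specimens.
The alternative — embedding the full matrix and treating all specimens as
in-sample — was implemented first and rejected: the retained dimension
then always hits the (parentals - 2) cap, the within-class covariance is
at the edge of singularity, and projections of intermediate morphologies
become unstable. With the parental-block embedding, phantoms generated
along a parameter continuum between the two parental shapes score
monotonically in the mixing parameter (Spearman rho > 0.95 in the
acceptance checks). The sign is fixed so the first-listed parent's mean
is lower; training scores are reproduced exactly by projection (1e-9).

## 4. Quantitative genetics

* **Repeatability.** Size: 1 minus the median coefficient of variation
  of CS across replicate-scan groups, with the unbiased (n-1) standard
  deviation. Shape: for each replicate group and each other specimen, the
  CV of replicate-to-specimen Procrustes distances, averaged (mean) over
  all comparisons; "averaging" could equally mean the median, and the
  mean was chosen as the plainer reading.
* **Heritability** is the one-way ANOVA R² of trait on strain, with
  strains under 3 individuals excluded (`minN = 3`). This estimator is
  deliberately the simple SS ratio, not a REML variance component, and it
  inherits that estimator's known small-sample behavior: with k strains
  of n individuals its expectation is E[SSB]/E[SST], which exceeds the
  intraclass correlation because within-strain noise enters the strain
  means (at k = 60, n = 5 and ICC 0.6 the expectation is 0.676, and under
  a pure-noise null it is (k-1)/(N-1) = 0.33). The unit tests assert the
  estimator against these analytic expectations rather than against the
  planted ICC.
* **Environmental input** is a fixed-effects ANOVA with lab nested in
  strain; the lab F statistic is tested against the residual, and the
  lab SS fraction of the total is reported.
* **Size-shape correlation** is the Pearson correlation of per-strain
  mean CS and mean LD1 with the usual two-sided t test.

## 5. QTL scans

RIL genomes are homozygous B or D at every locus, so Haley-Knott
regression needs only one covariate, P(D): `LOD = (n/2) log10(RSS0/RSS1)`
with no dominance term. Missing genotypes get their conditional
expectation under the two-state Markov chain along the marker map, with
per-interval Haldane fractions expanded for sib-mated autosomal RILs
(`r* = 4r/(1+6r)`); interior gaps condition on both flanks (products of
interval transition matrices), chromosome-end gaps on the single nearest
flank, and a fully missing chromosome gets 0.5 with a warning. These
probabilities match a brute-force enumeration of the two-state chain
exactly (a unit test). X-chromosome-specific map expansion is not
special-cased — a documented limitation. Genotype codes outside {B, D}
(residual heterozygosity) are treated as missing. Scans run at the
observed markers only; a pseudomarker grid is future work.

Significance is empirical: the phenotype vector is shuffled against the
strains (equivalent, under exchangeability, to permuting phenotypes and
genotypes jointly), the genome-wide maximum LOD recorded, and the 95th
type-7 quantile of the permutation maxima taken as the threshold,
deterministic given the seed. An observed LOD above all permutations is
reported as P below 1/n_perm. QTL are localized by the 1.5-LOD support
interval whose endpoints are the outermost contiguous markers within the
drop of the chromosome peak, clipped at chromosome ends; a flat curve
returns the whole chromosome with a warning. A perfect fit caps the LOD
at 300 with a flag. Linkage disequilibrium between two QTL markers is the
Pearson chi-square (df = 1, no continuity correction) on the 2x2 table of
strain alleles; the uncorrected statistic is the interpretation consistent
with published strain-count examples of this test.

## 6. What the synthetic data emulate — and what they do not

`generateBone` sweeps superellipse cross-sections (exponent 2 by default,
configurable) along a parabolically bowed centerline, fills the interior
except for a hollow medullary core (`cavityFrac = 0.35`), adds isotropic
Gaussian jitter (`noiseSd = 0.008` mm, about half a voxel), and returns
the cloud in a random rigid pose so alignment is always exercised.
Defaults describe an adult mouse baculum in millimetres: length 6.5,
base 1.3 x 0.9, tip taper 0.5, dorsal bow 0.35 (a curved parental
morphology) versus 0.05 for a straight one. The default 20000 points keep
tests fast; real segmentations run near 175000 points, and the landmark
sampling noise shrinks accordingly — at low densities (a few thousand
points) a 0.25%-thickness slice holds too few points for stable extremal
landmarks, which is visible as inflated within-group shape variance.
Points are uniform in axial position rather than in volume, and no CT
physics (beam hardening, noise spectra, partial-volume effects) is
simulated; passing tests therefore validate the geometry and statistics
of the pipeline, not robustness to scanner artifacts.

`generatePanel` simulates strain genotypes as independent two-state
Markov chains per chromosome with RIL-expanded transition fractions
(defaults: 73 strains, 19 chromosomes, dense markers, 2.2% missing data),
plants additive QTL directly on the strain-mean phenotype, and masks
genotypes at random. Real RIL families deviate from this in known ways —
shared pedigree structure, segregation distortion, non-Markov
recombination under sib mating — none of which are modeled.

## 7. Problem sizes used by the checks

The acceptance checks run, per fixed seeds: structural counts on an
8000-point phantom; geometry oracles at 500 points (diameter), 200 points
x 0.1-degree sweeps (MBR) and a 20000-point ring (slices); 100 random
poses of a 6000-point phantom for rigid-motion invariance; a morph
continuum of nine mixing values against 5 + 5 parental phantoms at 20000
points, two seeds; 400 null panels (70 strains, 5 chromosomes x 20
markers, 200 permutations each) for type-I control; 100 seeded panels
with a planted QTL explaining about half the strain-mean variance for
power and 1.5-LOD coverage; and 50 seeds of 60 strains x 5 for the
heritability estimator. These sizes were chosen as the smallest at which
each property is statistically meaningful.

## 8. Known limitations

* The proximal-end and dorsoventral heuristics assume a tapered, slightly
  curved bone; a perfectly straight or untapered specimen triggers
  explicit warnings rather than silent guesses.
* Sliding is tangent-plane only; without a surface model, slid landmarks
  are not re-projected onto the bone.
* The heritability estimator is the ANOVA R² by design, with the bias
  discussed in section 4.
* Mixed-model scans with kinship correction (needed for advanced
  intercross pedigrees), multi-QTL models, covariates and epistasis are
  out of scope; the scan module targets RIL strain means.
* The X chromosome is treated like an autosome in map expansion.
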