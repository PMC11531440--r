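---
title: "Quantifying the lacunocanalicular network: model, phantoms and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lacunocanalicular network: model, phantoms and pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The lacunocanalicular network (LCN) is the porosity of bone that houses the
osteocytes: ellipsoidal lacunae (cell bodies) connected by sub-micrometre
canaliculi (cell processes). `lcntools` turns 3D image stacks of stained bone
into a spatial network and computes the standard morphometry of that network
-- canalicular density, branching-point density and degree in cubic
subvolumes, lacunar shape descriptors, degree distributions, region-wise
statistics, and the gray-level-to-calcium calibration of quantitative
backscattered electron imaging (qBEI). Because confocal LCN datasets are
rarely public, the package is built around a synthetic phantom generator
with exact ground truth; every stage of the pipeline is validated against
what the generator knows to be true.

## The network model

A network here is a graph embedded in 3D: nodes are lacunae, canalicular
intersections ("junctions") and free branch ends ("endpoints"); edges are
canaliculi carrying their full 3D path and arc length. The measured
parameters follow the field's nomenclature:

* **Can.Dn** (um/um^3): total canalicular length per tissue volume,
  evaluated by clipping edge paths exactly to cubic subvolumes of 400 um^3
  (edge length 400^(1/3) = 7.37 um, half-open intervals, cells fully inside
  the region of interest). Exact clipping makes the map conservative: the
  cell densities times the cell volume sum to the clipped length exactly.
* **Nd.Nr** (um^-3): junctions plus lacunae per volume. Endpoints are not
  counted (a free end is not a branching point); whether endpoint nodes
  should count is genuinely ambiguous in the field's definitions, so they
  are reported separately.
* **Nd.Dg**: mean degree of *genuine* nodes -- junctions of degree >= 3,
  lacunae excluded. Cells without genuine nodes have an undefined Nd.Dg and
  are excluded from degree summaries but kept for Can.Dn and Nd.Nr.
* **Lc.V, Lc.St, Lc.Ob**: describing each lacuna as the ellipsoid matching
  the second central moments of its voxel cloud (semi-axis = sqrt(5 lambda),
  exact for a solid ellipsoid; the voxel self-covariance spacing^2/12 is
  added first), stretch is `1 - c/a` and oblateness `2(b - c)/(a - c) - 1`
  (-1 = rod, +1 = plate, set to 0 when `a - c` vanishes). These formulas are
  this package's operationalisation; they reproduce the conventional ranges
  (stretch ~0.3-0.8, negative oblateness for rod-like lacunae).
* **Lc.Dg**: number of canaliculi emanating from a lacuna.
* The cumulative degree distribution C(x) = P(degree >= x) over genuine
  nodes is fitted with `exp(-beta (x - 3))` by least squares of `-log C`
  against `x - 3` through the origin (C(3) = 1 is forced by construction),
  using observed degrees with C > 0.

Statistics follow the conventions of small-animal studies: Student's
t-tests (paired across limbs of the same animal, independent across
strains), least-squares linear and log-log power-law regressions reported
with Pearson's R, Gaussian-kernel-smoothed normalized histograms
(sigma = 1 bin), and the variability decomposition *inter* = SD of
per-sample means vs *intra* = mean of per-sample SDs (n-1 denominators
throughout).

## The phantom generator

`generate_ground_truth()` builds a network whose *realized* statistics are
known exactly, then `rasterize()` and `degrade()` turn it into a
confocal-like image stack (anisotropic voxels 0.379 x 0.379 x 0.340 um,
Gaussian PSF, linear background ramp, additive noise). Default targets are
the architecture of adult mouse cortical bone: Can.Dn 0.21 um/um^3, 0.05
junctions/um^3, a degree distribution concentrated at 3 with an exponential
tail, lacunae of ~350 um^3 with ~50 emanating canaliculi, and an unordered
(woven-bone remnant) band occupying ~30% of the volume. Two presets,
`balbc_like` and `c57_like` (Can.Dn 0.23, Nd.Nr 0.059), encode the strain
contrast, with `c57_like` strictly denser.

Construction, with all randomness drawn from one seed in a documented
order (lacunae, junctions, degrees, matching order, dangling directions,
edge perturbations):

1. **Lacunae** are ellipsoids with fixed axis ratios (4 : 2.2 : 1.5, i.e.
   stretch 0.62 and oblateness -0.44, rod-like), linear size factors uniform
   in [0.7, 1.3], placed by a hard-core process (minimum separation twice
   the mean long axis). Lacunar degree is surface area divided by a fixed
   area per canaliculus (5.75 um^2, chosen so the mean degree is ~47);
   that constant-area rule makes volume scale with degree to the 3/2 power,
   which is the package's self-contained acceptance quantity.
2. **Junctions** follow a Poisson count at the target density, thinned to a
   1.2 um hard core and placed preferentially in the ordered region (the
   unordered slab gets 0.65 of the ordered intensity, which reproduces the
   observed ordered/unordered density contrast).
3. **Degrees** are `3 + Geometric(1 - exp(-beta))`, whose survival function
   is exactly `exp(-beta (k - 3))`.
4. **Edges** pair "stubs" (each junction exposes degree-many, each lacuna
   one per surface anchor point) greedily by spatial proximity to a target
   chord length, subject to: no duplicate node pairs, a minimum clearance
   of 1.2 um between non-adjacent canaliculi, no passage through lacunae,
   and no crossing of a configured interface plane. Unmatched stubs become
   dangling branches to free endpoints so realized degrees match the
   sampled ones. The target chord length is calibrated by a deterministic
   fixed-point iteration so the realized Can.Dn lands on target (within
   ~10%); a resolvability floor keeps every chord above ~4 voxels.
5. **Tortuosity** bends each edge with a half-wave perpendicular bump whose
   amplitude is looked up so the discrete arc/chord ratio equals
   `tortuosity_factor` (default 1.1 -- a choice, not a literature value;
   reported tortuosities for canaliculi are scarce).

Three generator properties deserve emphasis because they are *modelling
decisions*, not conveniences:

* **The phantom is the resolved network.** Published density values are
  measured through ~0.4 um voxels and a PSF; junction pairs or parallel
  canaliculi closer than the resolution would be observed as one. A phantom
  that claims Can.Dn = 0.21 as ground truth while containing sub-resolution
  near-misses would carry a ground truth that no imaging could confirm.
  Hence the junction hard core and edge clearance at 1.2 um.
* **Alignment is preferential, not strict.** In the ordered region,
  partners within 20 degrees of the alignment axis are chosen whenever one
  is available and dangling branches run along the axis, but scarcity of
  in-cone partners under the clearance and density constraints means
  off-cone edges remain. Ordered-region mean |cos| to the axis is ~0.6
  against the isotropic 0.5. Forcing a hard cone produces parallel combs
  that fuse under the PSF and destroy extraction fidelity.
* **A resolved internal tension:** a degree tail with beta = 1 implies a
  mean genuine degree of 3.58, which is not jointly consistent with
  Can.Dn = 0.21 and Nd.Nr = 0.05 at achievable edge lengths. The defaults
  use beta = 1.2, which keeps the tail exponent "close to 1", makes exactly
  70% of genuine nodes degree-3, and lets all density targets be realized
  simultaneously.

Cohorts (`generate_cohort()`) jitter the density targets per animal by a
lognormal factor with 4% coefficient of variation and give both limbs of an
animal the same targets with different seeds; that makes between-animal
variability much smaller than the subvolume-to-subvolume variability within
a sample, as in the real study design.

## The extraction pipeline

`extract_network()` chains five steps:

1. **Binarization** by difference of Gaussians: the image is filtered at
   two scales (converted per axis to voxels so anisotropic spacing is
   respected) and thresholded at `tau = mean + k SD` of the positive
   band-pass response, computed on the image interior (within the large
   filter's support of a face, boundary reflection distorts the response).
   Defaults sigma_small = 0.15 um, sigma_large = 0.8 um, k = 0.1: the
   positive-response pool is dominated by low-amplitude ripple, so a small
   k sits just above it while keeping faint, partial-volume canalicular
   segments; these values were calibrated on ground-truthed phantoms
   (Dice against the rasterized truth, then end-to-end recovery), since no
   published values exist for this step. The DoG of a body much larger than
   sigma_large vanishes in its interior, so lacunae binarize as shells;
   enclosed cavities are filled by default.
2. **Segmentation** of lacunae from canaliculi by local thickness: voxels
   whose Euclidean distance transform (um, anisotropic) reaches 1 um seed
   lacuna bodies, reconstructed as the union of maximal inscribed balls and
   filtered at 50 um^3. Everything else is canaliculus.
3. **Skeletonization** by sequential topology-preserving thinning
   (simple-point deletion with endpoint protection; one 26-component of
   foreground in N26 and one 6-component of background in N18 adjacent to
   the centre). Lacuna voxels are anchors: foreground for the topology
   test, never deleted, so branches stay attached. Candidate border voxels
   are collected per direction before deletion -- without that, a curve
   erodes end-to-end in a single pass.
4. **Branch smoothing** with cubic smoothing splines per coordinate against
   cumulative chord length, endpoints pinned, fits rejected and stiffened
   if any point moves more than one voxel diagonal; chains under 4 points
   keep their polyline. Arc length integrates a dense (<= 0.1 um) resampling.
5. **Graph translation**: junction voxel clusters collapse to centroid
   nodes (merged within 0.5 um), lacuna attachments connect to lacuna
   nodes, free ends become endpoints. Because the DoG background estimate
   is inflated next to a bright lacuna, canaliculi binarize with a gap at
   the lacuna surface; endpoint branches within 5 um of a lacuna body that
   approach it radially (not tangentially, which would capture halo
   artifacts) are therefore bridged onto the lacuna. Spurs shorter than
   0.5 um hanging on degree-1 nodes are pruned and degree-2 junctions
   dissolved, so surviving junctions are genuine.

On default noisy phantoms (60 um cube) the pipeline recovers Can.Dn within
~12%, Nd.Nr within ~20%, mean genuine degree within ~0.05, the exact lacuna
count, lacunar volumes within a few percent and lacunar degrees within
~15-20% per lacuna -- the tolerances the test suite asserts. The residual
deficits are informative: canalicular length is lost where tubes run closer
than the resolving limit and where a lost branch demotes a true junction to
a pass-through.

## What the phantoms do and do not establish

The generator reproduces the statistical structure the analysis assumes --
densities, degree law, lacunar shapes, region contrast, blur and noise. It
does not model stitching seams, depth-dependent attenuation, staining
heterogeneity (e.g. overstained newly formed bone), vascular canals or the
fan-shaped architectures near drifting vessels. Passing recovery tests on
phantoms therefore validates the *algorithmic* chain, not performance on
any particular real dataset; on real stacks the binarization scales and
thresholds remain the user's responsibility, which is why every default is
an explicit argument.

Manual judgment is likewise out of scope for region analysis: ordered vs
unordered masks are *ingested* (2D, over the skeleton z-projection,
extruded along z; ties in a cell's footprint go to the sparser unordered
class). An orientation-coherence score (structure-tensor anisotropy) is
provided as a drafting aid only. The phantom's region ground truth is a
slab, so its z-projection is the exact mask -- convenient for testing, but
a simplification of the curved bands seen in cross-sections.

## Numerical choices and degenerate inputs

* Subvolume cells use the exact edge 400^(1/3) um; boundary cells not fully
  inside the domain (or ROI) are invalid and excluded from all summaries.
* Positions live in physical um; voxel (i, j, k) is centred at
  (i - 0.5) spacing. 26-connectivity for foreground and skeleton, 6 for
  background.
* Constant images binarize to an empty mask; empty masks segment and
  skeletonize to empty results; an all-degree-3 graph has an undefined tail
  exponent (returned as NaN with a reason); regressions reject fewer than 3
  finite pairs or zero variance in x; the histogram kernel is renormalized
  at the range boundaries so no mass is lost.
* qBEI calibration: gray level -> backscatter coefficient is the line
  through the carbon and aluminium reference measurements (eta from
  Reuter's polynomial in Z); calcium content is affine in gray level
  through two anchors. The default anchors (0 wt% at the carbon gray
  level, 39.86 wt% -- pure hydroxyapatite -- at the aluminium gray level)
  are a documented convention of this package, not literature constants;
  laboratories calibrate against their own standards and should pass their
  anchors.
* Problem sizes in the shipped tests and analysis scripts (25-66 um cubes,
  1000-lacuna shape populations, 10-sample cohorts) are chosen so each
  stage exercises its estimator with comfortable statistics at desk scale;
  all invariants are size-independent.

## Known limitations

* Pure degree-2 cycles in a skeleton (closed loops without junctions) are
  dropped, with a count reported.
* The thinning is sequential and deterministic but direction-ordered, so
  skeleton positions can be biased by up to a voxel; branch smoothing and
  the 1-voxel-diagonal guard absorb most of it.
* Lacuna attachment bridging can, in principle, attach an unrelated
  fragment that happens to end near a lacuna head-on; at phantom densities
  this is rare and bounded by the radial gate, but on unusual real data the
  radius is the first knob to reduce.
* The generator's matching is greedy; its degree realization is exact only
  up to stubs that can neither pair nor dangle (typically < 1%).
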