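---
title: "Virtual neuropathologic sampling: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual neuropathologic sampling: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neuropathologic assessment samples a handful of small cortical tissue
blocks — typically a 3.8 cm x 3.2 cm footprint on a 4 mm coronal slab —
from standard regions (middle frontal gyrus, middle/superior temporal
gyri, inferior parietal lobule, primary visual cortex), placed by gross
anatomical landmarks such as "the coronal slice containing the anterior
commissure". `brainblocks` simulates that practice on volumetric images
and quantifies two properties of it:

* **precision** — after mapping every subject's block into a common
  template space, how many subjects' blocks cover each voxel
  (`overlap_count_map()`, `overlap_histogram()`);
* **accuracy** — in each subject's own space, what fraction of the
  *reference* block (the intended target region, mapped from the template
  into the subject) the sampled block actually covers
  (`percent_overlap()`, reference denominator).

Two neuroimaging-guided corrections are modeled. The *guided* sample
translates the block by whole slabs along the anterior-posterior (AP)
axis to the slab maximizing overlap with the reference
(`ap_slab_search()`; exhaustive, so never worse than the original). The
*optimal* sample allows a full six-parameter rigid motion — re-positioning
*and* tilting the cutting plane (`rigid_overlap_optimize()`). Because the
guided solution lies in the rigid feasible set and is always evaluated as
a candidate, the ordering `subject_specific <= guided <= optimal` holds by
construction for every subject and region.

The functional consequence of sampling error is measured by seed-based
resting-state connectivity: the Pearson correlation of the block's mean
timeseries to every region of a region set (`fc_profile()`), compared
between the subject-specific and the reference block with a sign-flip
permutation test (`fc_discrepancy_analysis()`).

## Geometry

All geometry lives in world RAS+ millimetres; voxel indices are 0-based
continuous coordinates through a 4x4 affine (`bb_grid`). Coronal slabs
are half-open world-coordinate intervals `[origin + i*t, origin + (i+1)*t)`
along the AP (world y) axis, so every voxel center belongs to exactly one
slab even on grids oblique to the world axes — the physical brain is
sliced in world space, not in array space. Blocks are axis-aligned boxes
(left-right width x inferior-superior height x slab thickness); a voxel
belongs to a block when its center lies inside the box, with no
partial-volume weighting, matching the binary arithmetic of all
downstream overlap statistics.

Masks are moved by trilinear interpolation of the 0/1 field followed by a
0.5 threshold rather than nearest-neighbour lookup: on 4 mm slabs (two
voxels thick at the default 2 mm grid) nearest-neighbour aliasing under
rotation is severe. Transforms compose before resampling; a single
interpolation step is performed.

## The rigid overlap optimizer

The paper-facing objective — percent of reference voxels covered — is
piecewise constant in the transform, and worse, counting coverage at voxel
centers gives the surface a sub-voxel *texture*: how the boundary shell of
a re-voxelized mask lands on the lattice moves the count by 2-3% between
poses a degree or two apart. Overhang is also free under the reference
denominator. The search therefore combines several estimators:

1. informed starts: the whole-slab guided solution, the centroid offset,
   principal-axes (second-moment) registration for every proper sign
   assignment, and the best cells of a coarse exhaustive 5-degree rotation
   grid ranked on subsampled two-way coverage;
2. a two-stage (wide then narrow kernel) Nelder-Mead refinement of a
   pairwise Gaussian kernel correlation between the voxel-center clouds,
   computed exactly point pair by point pair — no lattice field and no
   interpolation, hence none of the lattice-snapping bias that pulls every
   interpolated surrogate toward axis-aligned poses;
3. deterministic refinement maximizing the hard counts: translation-only
   re-optimization on a smoothed symmetric correlation, and a shrinking
   coordinate search;
4. winner selection: among candidates within the re-voxelization band
   (0.8% of the reference count) of the maximal coverage — and never below
   the guided solution — the pose with the best symmetric two-way
   coverage, then the smallest motion.

A subtlety worth recording: with a `>= 0.5` threshold the optimizer would
park poses on exact half-voxel offsets, where the entire interpolated
boundary sits at exactly 0.5 and coverage inflates by a half-voxel shell
for free. Internal counts therefore use a strict `> 0.5`; the returned
mask is still produced with the package-wide `>= 0.5` convention.

**Known limitation.** The argmax of voxelized-mask overlap is not the
transform that generated the pair: with congruent analytically voxelized
boxes we measure poses 1-3 degrees away from the generating rotation that
cover *more* reference voxels than the generating transform itself. Every
similarity we examined (one- and two-way hard coverage, smoothed inner
products, exact kernel correlation, moment matching, closest-point
alignment) has its optimum displaced at the same order by this boundary
texture. Rigid *parameter recovery* is therefore reliable only to roughly
the voxel-to-block-size ratio in angle (about a degree for a 24 mm block
at 1 mm voxels), while the achieved *overlap* — the quantity the sampling
question actually needs — is essentially always within a percent or two of
the attainable maximum.

## Statistics

* `wilcoxon_signed_rank()` drops zero differences (the original
  treatment; a Pratt option exists), mid-ranks ties, and enumerates all
  2^m sign assignments exactly for m <= 12 (tie-safe, unlike the exact
  path of `wilcox.test`), otherwise uses the tie-corrected normal
  approximation with continuity correction.
* `poisson_robust()` models overlap voxel counts with a log link and
  log(reference count) offset via `stats::glm`, with sandwich standard
  errors clustered by subject (each subject contributes one observation
  per method, dependent by design); plain HC0 is available.
* `sign_flip_null()` builds the null by flipping whole subject rows of
  the delta matrix — the exchangeability implied by swapping the two
  sample labels within a subject, preserving dependence across regions.
  The per-region statistic is the signed subject count
  `#(delta>0) - #(delta<0)` (the mean is available); thresholds are the
  empirical 5th/95th percentiles of the null and significance requires
  strictly exceeding them. On a discrete lattice a valid test cannot hit
  5% exactly: at n = 20 subjects the exact per-tail rate is 2-3%, at the
  study-sized n = 35 it is 4.4-4.5%. Calibration checks therefore run at
  n = 35 (or with the continuous mean statistic).

## The synthetic phantom

`make_template()` builds an ellipsoidal brain (semi-axes 65 x 80 x 60 mm,
96 x 120 x 96 voxels at 2 mm) with a sinusoidally gyrified bright cortical
ribbon, an anterior-commissure-like landmark, four protocol target blocks
placed on its 4 mm slab stack, and a ~264-region lattice region set
(15 mm spacing keeps spheres inside the brain and yields 277 regions)
partitioned into six AP-band communities.

`make_subject()` derives a subject by a true rigid motion (per-axis
rotations N(0, 2 deg), translations N(0, 3 mm), clipped at 3 SD) composed
with a smooth product-of-sinusoids displacement field (amplitude <= 3 mm,
wavelength 80 mm — gradient well below the folding limit, verified by a
Jacobian spot check). Reference blocks are the targets mapped through the
*true* transform: the synthetic registration output is exact, isolating
the sampling computations from registration estimation, which is out of
scope. The landmark the "neuropathologist" actually uses is jittered
N(0, 6 mm) along AP and N(0, 3 mm) in plane — AP dominating because
slice selection is where the protocol's ambiguity lies — plus N(0, 2 mm)
of per-region in-plane placement jitter. With 4 mm slabs,
P(|N(0,6)| > 2) is about 0.74, so most subjects sample a slab other than
the one their reference occupies; this makes guided-vs-original
improvements of tens of percentage points, the order the sampling
literature reports. These are modeling defaults, not measured values.

`simulate_bold()` draws latent region signals from the planted community
covariance (within 0.6, between 0.05), smooths them temporally (a common
kernel leaves lag-0 cross-correlations unchanged in expectation), and
gives every brain voxel its nearest region's signal plus white noise, on
a 4 mm functional grid (240 volumes, TR 2.5 s) — resting-state
acquisitions are coarser than structural scans. Anatomy volumes and BOLD
series are not stored in cohort bundles; BOLD is re-simulated on demand
from named per-purpose sub-seeds of one master seed, so every run is
bitwise reproducible.

What passing tests on this phantom do *not* show about real data: there
is no registration error (reference masks are exact), no gyral anatomy
(landmark offsets stand in for anatomical judgment), no fMRI artifact
structure (motion, physiological noise, distortion), and the planted
block-diagonal covariance is far cleaner than cortical connectivity.
The phantom validates the *computations*, not the biology.

## Problem sizes used in validation

Test and acceptance runs use the full default template grid for cohort
analyses with n = 20 subjects (accuracy, precision, end-to-end
direction), n = 6-10 for runs that include the rigid optimizer or BOLD
simulation per subject, and n = 35 for the permutation and connectivity
calibration checks where the discrete statistic needs the study-sized
lattice. The rigid-recovery battery uses 24 x 16 x 12 mm boxes voxelized
analytically at 1 mm, the regime where the transform is identifiable from
binary masks (see the optimizer limitation above).

## A worked example

```{r example}
library(brainblocks)

cohort <- make_cohort(n = 10, seed = 1)
acc <- run_accuracy(cohort, optimal = FALSE)
acc$table$summary
acc$wilcoxon

pr <- run_precision(cohort)
pr$MFG$summary
```
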