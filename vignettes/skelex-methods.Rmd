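---
title: "Skeleton statistics and expression decoding: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton statistics and expression decoding: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skelex)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data design, and the numerical choices behind `skelex`. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The pipeline in one paragraph

Per-animal fractional anisotropy (FA) volumes are affinely aligned to a
common template, averaged, and skeletonized at the FA ≥ 0.2 white-matter
convention. Each animal's FA is projected onto the skeleton by a
perpendicular maximum search, and each sex is tested del/+ vs wild type
with an unpaired pooled-variance t statistic per skeleton voxel, enhanced
by threshold-free cluster enhancement (TFCE) and corrected for
family-wise error with a 500-permutation max-TFCE null, both directions
separately — four contrasts in all. Significant clusters (corrected
p < 0.05) are transported into the coarser expression-atlas space, where
each gene's energy values pooled over a contrast's clusters are compared
to its values over the entire skeleton with a two-sided Wilcoxon rank-sum
test; genes with raw p < 0.05 and a higher cluster median are called
overexpressed, and genes appearing in exactly one contrast's list form
that contrast's exclusive set.

## Skeletonization

A voxel joins the skeleton when its mean FA is at or above
`fa_threshold` (default 0.2, in FA units) **and** it is a local maximum
along the tract-perpendicular direction of the smoothed
(σ = 1 voxel) mean FA. The perpendicular direction is taken from the
local 3×3×3 centre of gravity when that offset is informative
(> 0.1 voxel), falling back to the leading Hessian eigenvector
otherwise; on tube-like structures, where the two leading Hessian
eigenvalues are comparable and the perpendicular is a plane, the maximum
is required along both leading directions. The centre-of-gravity-first
rule matters: on a radially symmetric tract a pure Hessian rule marks
spurious tangential ring maxima near the tract boundary (the leading
curvature there runs along the ring, and the voxel is genuinely maximal
along it). A strict ridge condition (voxel value above the mean of its
two perpendicular neighbours by 10⁻⁴ of the dynamic range) rejects
plateau voxels.

Projection then assigns each skeleton voxel the maximum of the
individual FA along ± the stored perpendicular direction within
`search_radius` voxels (default 4), searching both perpendicular
directions on tube-like voxels. This absorbs residual misalignment of
individual tracts without a nonlinear warp.

## TFCE and permutation inference

TFCE integrates extent^E × height^H over thresholds `h` in steps `dh` up
to each voxel's statistic, where the extent is the 26-connected
component size at that threshold. Defaults follow the conventions of the
standard implementation: E = 1, H = 2 on skeleton data; E = 0.5, H = 2
volumetrically; `dh` = max(statistic)/100 per map. Positive and negative
lobes are enhanced separately. The implementation processes thresholds
descending with an incremental weighted union–find, so each permutation
costs O(V log V + E α) rather than O(thresholds × V).

The group test permutes labels: all distinct assignments are enumerated
exactly when their number is at most `n_perm` (e.g. 4 vs 4 → 70), else
`n_perm` distinct assignments are sampled without replacement under the
given seed. Corrected p at a voxel is the fraction of permutation maxima
(over the skeleton) at or above the observed TFCE score, with `(1 +
count)/(1 + n_perm)` in the sampled case; a relative 10⁻⁸ tolerance in
the comparison keeps the observed assignment's self-tie stable against
floating-point path differences. Constant voxels get statistic 0.
Whether the published threshold was corrected or voxelwise is not stated
in the source; corrected is the default here, which is the standard
output of the named tool.

## Registration

`affine_register` maximises a similarity metric over the 12 affine
parameters (translation mm, rotation deg applied Rz·Ry·Rx, scale,
shear), with rotation/scale/shear about the fixed volume's centre.
The default metric is normalized mutual information (32 bins), which
survives the cross-modality contrast of histology-to-MR steps; normalized
cross-correlation is the right choice for same-modality steps (FA to
template) and is what the pipeline uses. The optimizer is deterministic:
an intensity centre-of-mass translation initialisation, an optional
coarse rotation grid (default ±90° in 30° steps) at the lowest pyramid
level, then per level (downsampling factors 4, 2, 1) a rigid 6-parameter
Nelder–Mead refinement followed by the full 12 parameters, each restarted
once to rebuild the simplex. There is no unseeded randomness anywhere.
The exact metric and optimizer of the original tooling are not published;
these choices are this package's own.

Resampling is trilinear (nearest-neighbour available), excluding
missing-sentinel voxels from interpolation by renormalising the weights
over valid corners — energy values are never blended across the missing
shell. Transform chains are composed into a single matrix and applied in
one interpolation pass; sequential regridding would compound
interpolation loss, and the histogram QC (Jensen–Shannon divergence of
intensity histograms before/after, natural log, flag threshold 0.02)
guards the whole path. Note the JS score of a *noisy* map drops under
any interpolation because resampling is an averaging operation; the
≤ 0.02 expectation applies to smooth maps, which is how the acceptance
check constructs its input.

`select_most_typical` registers every volume to every candidate target
and scores a transform by the mean world displacement (mm) of the
mover's in-brain voxels (intensity above 10% of maximum); the target
minimising the mean over movers wins, ties to the lowest index. Because
this is O(n²) registrations, the default end-to-end pipeline registers
animals to the known synthetic template instead and exposes the
tournament for explicit use.

Only affine transforms are implemented. The original analysis used
nonlinear warps for the within-modality alignment steps; at phantom
scale an affine captures the planted misalignments exactly, but this is
an approximation, not an equivalence claim, for real brains.

## The synthetic cohort

The phantom lives in world mm on two grids: a diffusion grid (default
64³ at 0.125 mm, matching the acquisition scale) and an expression grid
(0.2 mm, matching the atlas scale), so every cross-resolution step is
exercised. The brain shell is an anisotropic ellipsoid (semiaxes 0.46,
0.38, 0.32 of the grid extent — elongated like a real brain, which also
makes rotations identifiable to the registration); inside it sit a thin
"callosal" sheet, a medial "peristriatal" tube and a "cerebellar" blob,
with Gaussian cross-sections (FA peak ≈ 0.6 over a 0.1 background).

The default cohort is 6/4/6/5 (male WT / male del/+ / female WT / female
del/+; 21 animals), the study's group sizes. Planted effects mirror the
qualitative endophenotype: +0.15 FA on the tube in male del/+ only,
−0.10 FA on the sheet in del/+ of both sexes, +0.05 FA on the blob in
female del/+ only. Noise is additive Gaussian FA noise (sd 0.03) inside
the brain; misalignment is a per-animal random affine at 0.15 mm /
1.5° scale. Energy maps are voxelwise log-normal (σ = 0.3) around a
baseline of 1 inside the brain and −1 (the atlas missing convention)
outside; the three male-endophenotype genes are enriched ×3 on the tube,
two genes ×3 on the sheet, one ×3 on the blob. The source states none of
the noise scales; these are simple models with controllable
signal-to-noise chosen once.

What the generator does *not* emulate: anatomically faithful geometry,
spatially correlated expression noise, partial-volume effects, or
nonlinear anatomical variability. Passing tests therefore demonstrate
the correctness of the machinery under known ground truth, not
performance on real data.

## The overexpression call and its false-positive behaviour

The cluster sample pools voxelwise energy values over all clusters of a
contrast (a per-cluster-means variant is available); the reference
sample is the entire skeleton including the cluster voxels, as
described in the source. The test is two-sided with a median-direction
filter, and the published raw p < 0.05 threshold is applied without
multiple-testing correction (Benjamini–Hochberg is available but off by
default).

A consequence worth stating plainly: with 23 unenriched genes tested at
raw α = 0.05 per contrast, each null gene has roughly a 2.5% chance of
an "overexpressed" call in any given contrast, so an *exact* recovery of
a planted exclusive set is a probabilistic event (roughly a
60–75%-per-run event under the default conditions — the partial overlap
between cluster and skeleton samples makes the test conservative, which
helps). The acceptance check runs the end-to-end recovery at a fixed
seed; across seeds, occasional single-gene false positives at p just
under 0.05 are expected behaviour of the published design, not a defect
of the implementation.

## Problem sizes and determinism

The test suite and acceptance script use: 64³ phantoms for skeleton
statistics (null calibration over 200 cohorts of 6 vs 6 at 500
permutations; planted d = 3 power), 48³ at 0.25 mm for registration
recovery (20 planted transforms at ±1.5 mm, ±15°, scale 0.91–1.10 —
within the brain's field of view), and the full 21-animal default
configuration for the end-to-end run. Every stochastic stage consumes a
seed derived from one global seed by fixed offsets, and identical
configurations reproduce results bit for bit.
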