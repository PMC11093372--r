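---
title: "Methods: from confocal stacks of bone to a canalicular connectome"
author: "lcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from confocal stacks of bone to a canalicular connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnet)
```

## The problem

Osteocytes live in micrometre-sized pores (lacunae) inside mineralized bone
and communicate through cell processes housed in sub-micrometre channels
(canaliculi). Together these pores form the lacuno-canalicular network
(LCN). Rhodamine staining fills the accessible porosity, so a confocal
stack of stained cortical bone is a 3D image of the network. `lcnet` turns
such a stack into a mathematical network -- nodes (lacunae, canalicular
junctions, free ends) connected by edges (canaliculi with a smooth 3D
curve and an arc length) -- and quantifies it with three connectomic
parameters:

* **Can.Dn**, the canalicular density: total canalicular length per unit
  bone volume (um/um^3), with lacunar and vascular volumes excluded from
  the denominator. `Can.Dn = sum(Can.Seg_i) / V_ROI`.
* **Can.Ln**, the canalicular length: the arc length of one edge.
* **DoC**, the degree of connectivity of a node: the number of edges
  meeting there. A junction needs at least three intersecting canaliculi,
  so the minimum degree is 3 and degree-3 junctions are called
  *tree-like*.

Because real stacks of this kind are not generally available, the package
ships a first-class phantom generator that produces ground-truth networks
and renders them into confocal-like stacks, so that the entire chain can
be validated against known truth.

## Pipeline overview

1. **Segmentation** (`dog_binarize`): two Difference-of-Gaussians (DoG)
   band-pass detections, one scale-matched to thin canaliculi
   (`sigma = 0.15/0.6 um`) and one to bulky lacunae (`1.5/6 um`). Each
   response is thresholded *adaptively* against a local signal-amplitude
   scale -- a wide Gaussian (8 um) of the local mean absolute deviation.
   This makes detection exactly invariant to intensity offsets and robust
   to residual depth trends; an exactly constant image yields an empty
   foreground. The working thresholds (0.6 thin, 1.2 bulky, on the
   response/scale ratio) were calibrated on noise-free phantoms to give
   high overlap (Dice > 0.9) with the true tube masks at the working
   resolution.
2. **Pore classification** (`classify_pores`): connected components of the
   bulky-pass detections are eroded to compact cores (voxels with at
   least 13 of 26 bulky neighbours), labelled, re-grown one shell over the
   foreground, and classified by volume and extent: compact blobs of at
   least 100 um^3 are lacunae (osteocyte lacunae are typically 100-250
   um^3, canalicular junctions only 1-30 um^3); components above 300 um^3
   spanning more than 20 um along an axis are vascular canals. The
   erosion step keeps the thin false-positive bridges that the bulky pass
   picks up over dense canalicular tangles from fusing separate lacunae.
3. **Region partition** (`build_region_mask`): the calcein channel carries
   two bright label surfaces (old mineralization fronts) crossing the
   cortex. Both bands are detected by thresholding, required to cover at
   least half of the transverse cross-section, reduced to a per-column
   intensity-weighted mean position, gap-filled, smoothed, and used to
   split the volume into endosteal new bone, intercortex and periosteal
   new bone. Fewer than two detectable bands is an error that names the
   missing surface.
4. **Skeletonization** (`skeletonize`): topology-preserving curve thinning.
   Simple border voxels are deleted sequentially in six directional
   sub-iterations until stable; a voxel is *simple* when its removal
   changes neither the foreground 26-connectivity nor the background
   6-connectivity in its neighbourhood, and curve end points (a single
   26-neighbour) are protected. Deleting only simple points guarantees
   that component and loop counts are preserved, which the tests verify
   on random tube phantoms.
5. **Chain graph** (`build_chain_graph`): skeleton voxels are classified
   by neighbour count (1 end, 2 chain, >= 3 branch); adjacent branch
   voxels collapse into one junction (merge radius 1 voxel -- larger radii
   were found to fuse distinct neighbouring junctions into spurious
   degree-4 nodes); skeleton voxels adjacent to a lacunar component
   terminate their chain on that lacuna's node. Chains are traced between
   terminals; pure cycles get a node at the first remaining voxel in
   array order and become a self-edge. Free-ending chains shorter than
   1 um are discarded as thinning spurs (the shortest genuine canaliculi
   reported are in the 0-1 um bin, so this is deliberately the smallest
   useful cutoff). Finally, free tips are advanced along their outgoing
   direction while they remain inside the canalicular foreground, minus a
   0.4 um cap margin: thinning retracts every tube tip by roughly one
   tube radius, and with thousands of free ends this retraction is the
   single largest length bias if left uncorrected.
6. **Spline fitting** (`fit_splines`): each chain is lightly smoothed
   (moving average over a 1 um window, end points fixed) and interpolated
   per coordinate by a natural cubic spline over the cumulative chordal
   parameter. Arc length is measured on a dense (0.1 um) resampling of
   the spline. The smoothing window suppresses the half-voxel staircase
   jitter of the raster skeleton, which would otherwise inflate arc
   length by several percent; collinear chains remain exact to 1e-6 um
   and a quarter-circle of radius 10 um is recovered within 2%.
   Lacuna-attached edges stop at the lacunar surface contact -- extending
   them to the lacunar centroid would add a spurious centroid-to-surface
   stub to every root edge and bias Can.Dn upward by construction.
   Degree-2 junctions left over from pruning are dissolved (their two
   chains merge); degrees are recomputed on the final graph.

## Sub-volume analyses

`subvolume_map` partitions the volume of interest into cubic cells
(default edge 5 um, i.e. 125 um^3 cells) and accumulates spline-sampled
length increments into the half-open cell `[lower, upper)` containing each
increment's midpoint. Increments are obtained by subdividing the stored
polyline segments rather than resampling them, so the summed cell lengths
equal the clipped network length exactly (the conservation tests require
agreement within 0.1% for every cell size from 1 to 20 um; the observed
error is at rounding level). `V_ROI` per cell counts bone voxels minus
lacunar/vascular voxels; border cells keep their actual partial `V_ROI`,
and cells with `V_ROI = 0` are dropped from all statistics.
`convergence_scan` repeats the map over a range of cell sizes; on
statistically homogeneous phantoms the per-cell density distribution is
stable between 4 and 6 um, which motivates 5 um as the working size.

Two assignment rules coexist deliberately:

* **density** clips edges across cells -- each length increment counts in
  the cell that contains it;
* **Can.Ln histograms** (`length_histogram`) assign the *whole* edge to
  the cell containing its length-weighted centre of mass, because a long
  canaliculus crossing several cells is still one canaliculus.

Histograms use 1 um bins `[k, k+1)` and are reported in percent.
Canaliculi longer than 5 um are "long"; both the count-weighted and the
length-weighted long fraction are computed, and the length-weighted one is
the default for the density regressions (the fraction of canalicular
*length* in long canaliculi is the quantity that a length-vs-density
mechanism acts on). `doc_histogram` covers junction nodes only: lacunar
nodes are morphologically different objects and free ends have degree 1
by definition, so including either would dilute the connectivity
statistic the tree-like fraction is based on.

`cortical_profile` averages cell densities over the longitudinal and
depth axes for each transcortical column, places columns on a normalized
axis from 0 (endosteal bone boundary) to 1 (periosteal boundary), and
reports the calcein surface positions on the same axis.
`density_connectivity_regression` fits ordinary least squares of %long
and %tree-like against per-cell Can.Dn (cells need at least one assigned
edge, respectively junction); no weighting is applied, matching the
descriptive use of such fits.

## The phantom generator

`generate_network` grows canalicular trees from ellipsoidal lacunae
(default semi-axes 3 x 5 x 2 um, ~126 um^3, inside the typical 100-250
um^3 range; elongated along the bone axis). Growth is a biased random
walk in 0.5 um sub-steps with direction perturbation (`tortuosity`,
default 0.12) and Poisson branching (`branch_rate`, default 0.11 per um);
a branch creates a degree-3 junction and two child tips splayed 50-75
degrees from the parent direction. Segment lengths between decision
points are drawn from a truncated normal (mean 4 um, sd 1.5 um). With
`branch_rate = 0` a process is a single segment, so fully deterministic
spot checks (three straight 10 um processes) are possible.

Design choices that required care:

* **Collision avoidance.** Tips keep a minimum centre-to-centre spacing
  (default 1.2 um) from all previously grown points, tracked in an
  occupancy grid storing the point, its edge identity and its arc
  position (points are stored at 0.25 um spacing so the enforced
  separation is tight). Without this, at realistic densities
  (~0.2 um/um^3) tubes overlap in the rendered stack, the segmentation
  merges them, and "ground truth" no longer describes the image -- every
  recovery test would then measure the phantom's self-inconsistency
  rather than the pipeline. The separation is set so that neighbouring
  canaliculi remain resolvable at the 303 nm working pixel size, which is
  precisely the regime in which confocal LCN imaging operates.
* **Branch-zone exemptions.** Within 1.6 um (arc) of a branch point the
  parent, sibling and grandparent edges are exempt from the separation
  rule -- otherwise children could never splay away from the junction.
  The exemption is tied to the edge identities and to the spawn position;
  an earlier depth-based rule allowed same-depth branches to cross and
  produced spurious high-degree tangles.
* **Root capacity.** Roots per lacuna are capped by the lacunar surface
  area divided by the squared separation; oversubscribed surfaces would
  otherwise sprout processes that die immediately as unresolvable stubs.
* **Sub-resolution stubs.** Edges that terminate (by collision) before
  reaching four tube radii (~1.2 um) are retracted entirely: a side
  branch shorter than the tube diameter cannot be represented in the
  image, so keeping it in the truth would only manufacture irrecoverable
  junctions.
* **Density control.** With `target_density` set, trees are added
  round-robin over lacunae until the accumulated length reaches
  `target * volume`; the final tree receives the remaining length as a
  growth budget, so the achieved density lands well within the 5%
  contract at any feasible target (the saturation density at the default
  spacing is ~0.25 um/um^3).
* **Gradients.** An optional linear `density_gradient` modulates lacuna
  placement and root allocation, producing monotonic transcortical
  profiles for testing the profile machinery.

`render_volume` rasterizes the edge curves as capsules of radius
`canalicular_radius` (default 0.3 um -- real canaliculi are below optical
resolution, so this is a free phantom parameter chosen just above the
voxel half-diagonal so that voxelized tubes stay connected) plus the
lacunar ellipsoids, then applies, in order: Gaussian PSF blur, depth
attenuation `(1 - a)^z`, and Poisson photon plus Gaussian read noise.
The unblurred binary mask is returned as ground truth, and with zero PSF
and no noise it equals the analytic capsule/ellipsoid membership exactly.
`generate_calcein_surfaces` renders two label surfaces (planes, sinusoids
or arbitrary functions) as thin Gaussian bands and returns the true
region partition.

### What the phantom does and does not emulate

It reproduces the statistical structure the analysis relies on:
tree-dominated branching, sub-micrometre tube calibre, tunable edge-length
distribution, spatially varying density, anisotropic voxels, PSF, photon
noise and depth attenuation. It does not emulate stitching artefacts,
woven-versus-lamellar texture in the background, bleed-through between
channels, micro-cracks, or canaliculi of varying calibre. Passing the
recovery tests therefore demonstrates the correctness of the image-to-
network chain under controlled optics, not robustness to every artefact
of real acquisitions.

## Numerical conventions

* Array axes are `[x, y, z]`; voxel `(i, j, k)` (1-based) has centre
  `origin + (c(i,j,k) - 0.5) * voxel_size`; all geometry is in physical
  micrometres and anisotropy (default 0.303 x 0.303 x 0.27 um) is carried
  through every stage.
* Sub-volume cells are half-open boxes, so every length increment lands
  in exactly one cell; ties on boundaries go to the upper cell.
* Cycle tie-break: a branch-free cycle gets its node at the first
  remaining voxel in column-major order.
* Degenerate inputs: empty networks render as flat background; constant
  images binarize to empty foreground; empty histogram scopes are
  returned flagged rather than as errors; regressions with fewer than
  three eligible cells are errors.
* Determinism: every stochastic stage consumes a seed derived from one
  root seed, and the caller's RNG state is restored afterwards.

## Problem sizes used by the test-suite

The validation suite generates all data in code: deterministic
single-tube, Y, ring and two-region phantoms; a 30 x 30 x 14 um branched
phantom at 0.12 um/um^3 shared across segmentation and extraction tests;
a 40 x 40 x 20 um phantom at 0.08 um/um^3 for the quantitative recovery
contract (total length within 10%, junction count within 15%); and one
full study-scale phantom, 50 x 50 x 30 um at 0.2 um/um^3 rendered
noise-free at the working resolution, on which the end-to-end density
recovery (within 15%) and tree-like fraction recovery (within 10
percentage points) are checked. These sizes give each statistic hundreds
of cells or junctions while keeping the phantoms comfortably inside the
regime the generator's spacing can support.

## Known limitations

* Recovered Can.Dn at the working density carries a systematic deficit of
  roughly 10%: residual tip retraction, curvature below the voxel scale,
  and canalicular length absorbed into the (slightly dilated) lacunar
  labels all shorten the extracted network. The recovery tests bound,
  rather than remove, this bias.
* Crossing canaliculi closer than the resolvable spacing are merged by
  any intensity-based segmentation; the resulting junction inflation is
  kept small by the phantom's separation rule but will be larger in real,
  denser tissue.
* The vascular-canal rule (volume > 300 um^3 and span > 20 um) is a
  geometric heuristic; stacks dominated by large canals would need a
  dedicated detector.
* `build_region_mask` assumes the transcortical axis is x and that both
  calcein surfaces cross the full cross-section; strongly oblique
  cortices would need a reparameterization.
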