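---
title: "Localizing intracranial electrodes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing intracranial electrodes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrolocate)
```

## The problem

Patients undergoing intracranial monitoring for epilepsy are implanted with
ECoG grids/strips on the cortical surface and/or SEEG depth leads. Their
positions must be recovered from a postimplant CT, where metal contacts
appear as very bright blobs (electrode artifact ≫ 1000 HU), and expressed
both in the patient's own anatomy and in a standard (MNI) space so that
recordings can be related to anatomical structures. Three complications
dominate:

1. **Thresholding is dataset-specific.** Artifact intensity varies with
   scanner, kernel and hardware, so no single Hounsfield threshold separates
   contacts from skull across datasets.
2. **Brain shift.** After surgery, surface electrodes often sit below the
   preoperative pial surface; their apparent positions must be projected
   back onto a smoothed brain envelope.
3. **Centroid jitter.** Voxelization and imperfect artifacts displace
   detected SEEG centroids by fractions of a millimetre; manufacturer
   intercontact spacing is a strong prior that can be re-imposed.

`electrolocate` implements the computational core of this workflow as a
headless library: detection, surface building, geometry correction,
gray/white classification, atlas labeling, and channel-sorted export. Image
registration and tissue segmentation are *inputs* (tissue-probability maps
and deformation fields, e.g. from SPM-style unified segmentation); the
package consumes them and never estimates them.

## Detection by threshold stability

All CT voxel intensities define a percentile scale. Candidate thresholds are
21 values evenly spaced from the 99th to the 100th percentile (linear
interpolation between order statistics). At each threshold, supra-threshold
voxels are grouped into 26-connected components; a component is an electrode
candidate if

* its intensity-weighted centroid lies inside the projection surface,
* it has strictly more than 6 voxels, and
* its volume is below that of a 2-mm-radius sphere (≈ 33.5 mm³).

The per-threshold candidate count forms a curve. *Stable segments* are
maximal runs of consecutive thresholds whose counts differ by at most 5
between neighbours; the winning segment is the one whose maximum count is
largest, and the optimal threshold is the segment's centre element. Two
readings of the stability rule were open: we define the step test pairwise
on consecutive thresholds (not on the within-segment range), and "the
segment containing the most electrodes" as the segment with the largest
per-threshold maximum, with ties broken toward the longer segment and then
the lower threshold. Both choices are asserted against a brute-force
re-implementation of the rule in the tests.

Detections closer than 1 mm are then merged — we keep the brighter
component, processing in descending mean intensity, which makes the cleanup
idempotent — and at most 250 electrodes are reported, brightest first. The
inside-the-surface test uses the component's weighted-centroid voxel rather
than all voxels, so contacts abutting the envelope are not lost.

Because thresholds are percentile-derived and all filters are geometric,
detection is invariant under positive affine rescalings of the CT — tested
explicitly.

## Surfaces

The brain mask is `gray + white > 0.95` with all but the largest
26-connected component removed. The **brain surface** is the 0.3 isosurface
of the mask smoothed with a 3-mm cuboid (uniform box) kernel; the
**projection surface** uses a 10-mm kernel, producing an inflated envelope
that bridges sulci. Kernel width is converted to an odd number of voxels per
axis. Isosurfaces are extracted by marching tetrahedra on the Kuhn (6-tet)
cell subdivision with linear interpolation along edges — the same contract
as marching cubes, with an implicit zero-padding layer so meshes always
close. Detached surface remnants (typically ventricle shells) are removed by
DBSCAN over mesh vertices, keeping the largest cluster; `eps` defaults to 3×
the median edge length and `min_pts` to 10 (both exposed — the source
recipe does not specify them), and size ties break toward the cluster
containing the smallest vertex index.

Note that a 0.3 iso-level on a box-smoothed binary mask sits *outside* the
0.5 level by about `(0.5 − 0.3) × kernel width`; on a 15-mm sphere with the
3-mm kernel the enclosed volume is that of a ≈ 15.6-mm sphere. The tests use
this closed form as the oracle rather than the nominal radius.

## Geometry correction

**Grids.** Each contact of an `r × c` grid is moved along the local grid
normal — the cross product of the mean row and column directions from its
labelled neighbours (one-sided at edges and corners) — to the nearer
ray–surface intersection of the two orientations. **Strips** (1 × n), where
no normal is defined, go to their nearest surface point. Manual projection
modes supply the vector instead: from the mid-commissural point through the
contact, along the viewing direction, or along the surface normal at the
nearest surface point; contacts can also be nudged stepwise (default step
0.4 mm, one working voxel).

**SEEG spacing correction.** Starting from the (visually trusted) deepest
contact, each contact `k` is repositioned to lie at exactly the
manufacturer gap spacing from the corrected contact `k − 1`, along the mean
of the vectors from `k − 1` to the original contacts `k` and `k + 1` (the
last contact uses its single vector). We average the raw vectors and then
normalize (rather than averaging unit vectors); with one lookahead contact
the two conventions coincide, and with two they differ negligibly for the
sub-millimetre jitters this procedure targets. The post-condition — every
corrected gap equals its nominal spacing to numerical precision — is what
the acceptance target measures: the median normalized intercontact spacing
after correction is exactly 1.00 with zero spread. The procedure
straightens small jitter but has no curvature model: a strongly bent lead
is corrected segment-by-segment and can end up displaced, a known failure
mode that is reproduced, not fixed.

**Inline rotation.** For in-plane display of a depth lead, the minimal
rotation about `lead × normal` (through the lead midpoint) brings the
first-to-last contact vector into the viewing plane; a lead parallel to the
plane normal rotates 90° about a deterministic perpendicular axis.

## Gray/white classification and atlas labels

For each contact, the voxels of a 1.3-mm sphere (the nominal contact
radius) are read from the gray and white probability maps. If both means
are below 0.1 the contact is **unknown** (outside the brain). Otherwise a
two-sided Wilcoxon rank-sum test compares the two samples; at `p < 0.001`
the tissue with the higher median wins, otherwise the default is **gray**.
We evaluate the unknown rule first so degenerate out-of-brain contacts
never reach the test; the rules are mutually exclusive in practice, so the
outcome is unchanged. The rank-sum p-value uses exact enumeration of the
permutation distribution (midranks, so ties are exact) when both samples
have ≤ 10 observations, and the normal approximation with tie and
continuity corrections otherwise.

Atlas labels come from integer label volumes in MNI space with
tab-delimited label tables. Contact-sphere voxel centres are warped to MNI
space through a deformation field — stored SPM-style as absolute target
coordinates on a definition grid, sampled trilinearly — and looked up in
the atlas by nearest neighbour (labels are categorical). The most common
label is assigned; background counts, and a background mode yields
"unlabelled" rather than the best tissue label; 50/50 ties break to the
lower label index. A probabilistic list over a 1-cm sphere stores each
label's voxel fraction (summing to 1, background included), sorted
descending; matching utilities exclude entries below 5% of the sphere.
Whole atlases are also warped into patient space (voxel-wise field lookup,
nearest-neighbour atlas read) for overlay, conventionally saved with an
`lw` prefix.

## The head phantom

Every algorithm is testable without patient data through a synthetic head:

* **Geometry.** An ellipsoidal brain (default semi-axes 22 × 26 × 20 mm — a
  desk-scale head that keeps default grids near 180³ voxels at the 0.4-mm
  working resolution) with a 6-mm gray shell over a white core; a 2-mm
  skull shell at 1500 HU offset 3 mm from the brain; air at −1000 HU.
* **Tissue maps** ramp smoothly over 1 mm at boundaries, with
  `gm + wm = 0.98` inside the brain (so the 0.95 mask threshold behaves as
  on real segmentations) and `gm + wm ≤ 1` everywhere.
* **Electrodes** are isotropic Gaussian blobs peaking at 3000 HU with
  FWHM = 2 × the 1.3-mm contact radius, placed along lead/grid geometries;
  3.5-mm lead spacing and 10-mm grid pitch mirror common clinical hardware.
  The blob peak is above the CT's 99th percentile by construction, so the
  threshold search brackets it. Optional additive Gaussian noise (tests use
  σ = 50 HU) exercises robustness. Metal streak artifacts and cortical
  folding are deliberately not modelled — the phantom exercises the
  thresholding, centroid, geometry and labeling logic, so passing tests
  demonstrate algorithmic correctness, not clinical-grade performance on
  streaky CTs.
* **Spaces.** The synthetic "MNI" space is the patient grid under a known
  affine (6° rotation, 5% scale, small translation), so field application
  has a closed-form oracle; both deformation fields are exact. The toy
  atlas labels the warped brain by coordinate octant, giving planar label
  boundaries with analytically known membership.
* **Determinism.** All randomness flows through one seed; the same seed
  reproduces the phantom bit-for-bit. `random_phantom_spec()` draws
  randomized implants (2–7 leads, 6–8 contacts) on an azimuthal fan with a
  slight inward tilt, which guarantees by construction that contacts stay
  ≥ 2 mm apart and inside the brain.

## Problem sizes and numerical choices

Tests and the acceptance script run phantoms at 0.8–1.2 mm voxel pitch
(grids of ~50–90³ voxels) — small enough for a laptop-class single core,
while the package defaults remain at the 0.4-mm working resolution. Other
fixed choices:

* Coordinates are world RAS millimetres; affines map 0-based voxel indices
  to mm; all electrode math happens in world space.
* Image interpolation is tricubic Catmull–Rom convolution (the standard
  "cubic" of image-resize tools; exact for linear fields), trilinear for
  deformation fields, nearest-neighbour for label volumes. Reslicing fills
  out-of-field voxels with the input minimum so padding can never imitate
  electrode signal.
* The ACPC frame (conventions unspecified in common usage) is fixed as:
  origin at AC, PC on the −y axis (anterior positive), midsagittal point in
  the x = 0 plane with positive z, right-handed.
* Mesh queries are exhaustive over triangles (no BVH); at phantom mesh
  sizes (10⁴–10⁵ faces) this is fast enough and trivially correct, and the
  tests compare against independent brute-force oracles.
* Degenerate inputs fail loudly: collinear ACPC landmarks, empty masks,
  open meshes, leads with coincident contacts, out-of-domain warp points
  and incomplete grid topologies all raise errors naming the offender.

## A worked phantom run

```{r, eval = FALSE}
ph <- make_head_phantom(phantom_spec(voxel_mm = 0.8))
surf <- build_surfaces(ph$gm, ph$wm)
det <- auto_detect(ph$ct, surf$projection)
det
#> <eloc_detection> 24 electrodes at threshold 1722.9 HU
#>   curve: 21 thresholds in [1500.0, 2986.3] HU

es <- classify_electrodes(det$electrodes, ph$gm, ph$wm)
es <- label_electrodes(es, ph$atlas, ph$field_to_mni, ph$gm)
es <- assign_channels(es, data.frame(label = sprintf("E%02d", 1:24),
                                     channel = 1:24))
export_channel_map(es, "session/")
```

## Known limitations

* No energy-minimizing projection that preserves intercontact distances:
  grid projection slightly expands spacing (the tests bound the normalized
  spacing in [0.9, 1.2]).
* Bent SEEG leads defeat the straight-line spacing correction.
* The phantom's Gaussian blobs underestimate the difficulty of real metal
  artifacts (streaks, blooming, overlapping contacts at sub-3-mm pitch).
* Microwire (hybrid macro/micro) contacts are out of scope; they are
  usually too small to detect on clinical CT.
* DICOM ingestion, CT–MR registration and tissue segmentation are out of
  scope; inputs are NIfTI volumes, probability maps and deformation fields
  produced by standard neuroimaging tools.
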