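---
title: "Airway route planning: models, parameters, and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway route planning: models, parameters, and validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchonav)
```

## The problem

Bronchoscopic biopsy of a peripheral pulmonary lesion requires choosing, at
every airway bifurcation from the trachea down, which daughter bronchus to
enter. `bronchonav` computes that route from a chest CT volume and renders it
as a short list of operator-readable commands — "go left", "go up-right" —
one per bifurcation, so the plan can be followed without a navigation system
in the room.

The pipeline is: segment the air-filled lumen, reduce it to a centerline
skeleton, encode the skeleton as a rooted tree, find the tree path from the
trachea to the airway point closest to the lesion, and classify each
off-path/on-path daughter pair by where it falls in a virtual endoluminal
camera image at the bifurcation.

## Coordinate conventions

All world geometry is in the DICOM patient frame (LPS: +x left, +y
posterior, +z superior), in mm. NIfTI input, whose native world frame is
RAS, is flipped on load. Voxel indices are 0-based and an integer index
addresses the voxel center; DICOM slices are ordered by their position
projected on the slice normal, never by `InstanceNumber`, which makes
loading robust to renumbered series.

## Lumen segmentation

Airways are dark tubes (air, about −1000 HU) inside brighter wall and
parenchyma. The detector is the Hessian of the Gaussian-smoothed volume at
scale $\sigma$: with eigenvalues $\lambda_1 \le \lambda_2 \le \lambda_3$ of
$\sigma^2 H_\sigma$ (the $\gamma = 2$ normalization that makes responses
comparable across scales), the per-voxel response is

$$ R_\sigma = \begin{cases}
\max(\lambda_2 \lambda_3 - \lambda_1^2,\, 0) & \lambda_2 > 0,\
\lambda_3 > 0\\ 0 & \text{otherwise}
\end{cases} $$

A dark tube has two large positive cross-sectional curvatures and a near-zero
axial one, so $\lambda_2\lambda_3$ is large while the $\lambda_1^2$ term
suppresses blobs and edges; the positivity gate enforces polarity (a *bright*
tube scores exactly zero on its axis). Derivatives are computed in mm with
per-axis kernel scales, so anisotropic voxels need no resampling.

Because main bronchi and distal bronchioles differ in calibre by an order of
magnitude, responses are taken at scales $\{0.5, 1, 2, 4, 8\}$ mm and
combined by a voxelwise maximum (the argmax scale is kept as a calibre
estimate). The default threshold is Otsu's threshold of the nonzero response
histogram, recomputed per volume and overridable.

Thresholded tubularity alone under-segments the trachea — a 16 mm-wide tube
is locally more wall than tube at these scales — so the mask is united with
a seeded region growing over HU < −950 from the trachea seed. The seed
itself is found as the centroid of the largest near-circular dark (< −900
HU) component with area 20–2000 mm² in the most superior 10% of axial
slices. Growing proceeds in breadth-first waves and aborts any wave whose
voxel gain exceeds 4× the running median of previous waves: the classic
guard against flooding the parenchyma through a segmentation leak. The final
mask is the single 26-connected component containing the seed, which makes
threshold monotonicity exact: raising the threshold can only shrink it.

## Skeleton and tree encoding

The mask is thinned to a one-voxel-wide medial curve by topology-preserving
thinning: a border voxel is deleted only if it is a *simple point* — exactly
one 26-connected object component in its 3×3×3 neighborhood and exactly one
6-connected background component touching its faces — and not a curve
endpoint. Deletion runs in six directional subiterations (up/down/
north/south/east/west borders) so material is removed symmetrically and the
curve stays medial.

Skeleton voxels partition exactly into branching clusters (26-connected
groups of voxels with ≥ 3 skeleton neighbors), endpoints, and degree-2
chains; clusters and endpoints become graph nodes, chains become edges
carrying their ordered voxel polyline in world mm. Terminal edges shorter
than 3 mm are pruned (thinning artifacts near the wall; real bronchial
branches at CT resolution are longer), and pass-through nodes left behind
are merged. The graph is then rooted at the node nearest the trachea seed
(ties to the most superior) and directed away from it by depth-first search
with children visited in descending edge length, a deterministic order;
edges that would close a cycle are discarded and recorded. Node levels count
edges from the root (trachea = level 0); nodes with more than two children
are kept and flagged non-binary rather than force-split, because
near-coincident bifurcations are exactly the case the instruction encoder
must handle explicitly (below).

The tree is stored as the pair used throughout the package: a binary
node-adjacency matrix plus a matrix of 3D centerline segments, one polyline
per adjacent node pair. `encode_adjacency()` / `decode_adjacency()`
round-trip this representation exactly.

## Path planning

The lesion is a world point. Its anchor is the global minimizer of the
Euclidean distance over *all* sampled polyline points of all edges —
point-to-sampled-polyline rather than point-to-continuous-segment, which
bounds the extra error by half a voxel diagonal and matches the discrete
skeleton encoding. Ties break on the lowest edge id, then the lowest point
index, so results are reproducible. The navigation path is the unique tree
path from the root to the anchor's edge, with the final polyline truncated
at the anchor (lesions rarely align with the most distal reached point; the
residual `gap_mm` is reported). Each segment's first point is the
bifurcation it leaves, so junction points are owned by the distal segment
and concatenated paths count each junction once.

## Virtual camera and quadrant instructions

At the distal end of each path segment (a bifurcation), a camera is placed
`setback_mm = 5` mm proximal along the centerline — emulating a bronchoscope
approaching the carina — looking at the bifurcation point. Image "up" is the
patient-superior axis orthogonalized against the view direction; when the
view is near-vertical (|view · superior| > 0.99, e.g. in the trachea) the
patient-anterior axis substitutes. This fixes a reproducible scope roll; a
real bronchoscope's roll is arbitrary, which is a known limitation, not a
bug. Projection is pinhole with a wide 120° cone; quadrant decisions use
normalized coordinates, so they are invariant to any positive rescaling and
insensitive to the exact field of view.

Each daughter's centerline points are projected; the image is split into
quadrants I (up-right), II (up-left), III (down-left), IV (down-right)
about the projected bifurcation point, half-open so boundary points go
right/up. A daughter is assigned the quadrant holding most of its points;
ties go to the quadrant of its most distal projected point, the direction
the operator would actually steer toward. The two daughters' two-word labels
are then simplified by dropping the word they share: quadrants in different
vertical halves give "go up"/"go down", otherwise different horizontal
halves give "go right"/"go left". Two deliberate conventions close the gaps
this rule leaves open: diagonal pairs (I vs III, II vs IV) use the vertical
rule, and same-quadrant pairs are ordered by mean angle within the quadrant
and split along the axis of larger separation of their mean points.

When the next bifurcation on the path lies within `close_mm = 6` mm of the
current one, both carinae fall in one camera view and the operator sees
three lumens; the instruction is flagged `close_levels`. With `merge_close =
TRUE` the two steps collapse into a single instruction aimed at the on-path
grandchild's projected quadrant; merging is off by default since it is a
remedial convention rather than the primary encoding.

## The phantom generator

All quantitative validation runs on synthetic phantoms with exact ground
truth. A phantom is a recursive binary tree of straight capsules: trachea
40 mm long, 8 mm radius, child length × 0.75 and radius × 0.79 per
generation, ±35° branching in a plane that alternates per generation, plus
Gaussian angular jitter (default sd 3°) so seeds give distinct anatomies.
These defaults are anatomically plausible at the default 128³ grid of 1 mm
voxels, and keep the deepest branch of a 5-level phantom at 3.1 mm radius —
at least two voxels, the regime the segmentation targets. Rasterization
assigns lumen −1000 HU, a 2 mm wall at −100 HU, background −850 HU,
optional additive Gaussian noise seeded from the spec. Two special options
exist: `plane_mode = "camera"` alternates branching planes between the
*camera frame's* right and up axes (so instruction families alternate
left/right, up/down exactly — the geometry the wording tests need), and
`close_bifurcation` shortens one branch to place two bifurcations within a
chosen distance, reproducing the three-lumen condition.

What the phantoms do **not** emulate: curved and tapering branches, breathing
motion, stenosis, mucus plugging, scanner point-spread and streak artifacts,
and real parenchymal texture. Passing phantom tests therefore demonstrates
the geometric and combinatorial correctness of the pipeline, not clinical
segmentation performance on patient CT, which would require benchmark data.

## Numerical choices and degenerate inputs

* Gaussian kernels are truncated at 4σ and discretely renormalized (order 0
  sums to 1; orders 1 and 2 differentiate a ramp and a parabola exactly),
  with reflective boundaries. Scales below half the smallest voxel spacing
  are rejected as undersampled.
* Hessian eigenvalues use the closed-form trigonometric method for symmetric
  3×3 matrices.
* Surface export (`extract_surface()`) runs marching tetrahedra at iso-level
  0.5 after a light half-voxel Gaussian pre-smoothing that de-aliases the
  binary staircase (areas then land within a few percent of analytic values);
  when smoothing would erase the surface entirely — a single-voxel mask —
  the raw grid is used instead.
* A flat response histogram (e.g. a constant volume) makes Otsu's threshold
  undefined; segmentation then relies on region growing alone.
* An anchor exactly at a bifurcation yields a one-point final segment; an
  anchor inside the trachea yields a path with no bifurcations and an empty
  roadmap, which `export_roadmap()` refuses unless explicitly allowed.
* All randomness (phantom jitter, noise, lesion placement) is locally seeded
  and restores the caller's RNG state, so identical configurations produce
  byte-identical JSON artifacts.

## Problem sizes used in validation

The test suite recovers topology on twenty 128³ phantoms (levels 2–5, five
seeds each), scores Dice on noiseless and 20 HU-noise phantoms, checks
quadrant voting against brute-force counting on 1000 random clouds, checks
instruction alternation on 10 random root-leaf paths of a 5-level phantom,
and verifies anchor optimality against exhaustive scans on 1000 random
lesions. `scripts/acceptance.R` re-runs the same measurements at slightly
reduced repetition counts and reports the numbers as JSON.

One realism limit matters for interpreting topology scores: with angular
jitter, deep phantoms occasionally place two sibling distal branches close
enough that their rasterized lumens fuse. The segmentation and skeleton then
honestly report a fused airway (a cycle, broken and recorded during
rooting), which no longer matches the analytic ground-truth tree. This is a
property of the generated anatomy, not an extraction error, and is why
topology recovery is asserted at a 95% rate rather than universally.

## Known limitations

* Levels are graph depth; no anatomical naming (RUL, LLL, ...) is attempted.
* The camera roll convention is a modeling choice; instructions assume the
  operator holds the scope with "up" toward the patient's head (or anterior
  in the trachea).
* Segmentation quality on real CT depends on acquisition parameters the
  phantoms do not model; the Otsu default for `tau` should be reviewed per
  cohort.
* Lesions are points; lesion extent and instrument reachability constraints
  are out of scope.
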