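---
title: "Methods: scripted 3D neuron segmentation and its validation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scripted 3D neuron segmentation and its validation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mansegkit)
```

# The problem

Manual expert segmentation remains the gold standard for isolating single
neurons from confocal or two-photon z-stacks, both as a product in itself and
as the yardstick against which automatic reconstruction algorithms are
judged. A manual tool, however, is only as trustworthy as the quantitative
checks around it: morphometry of the extracted object, a reference-free
goodness-of-segmentation index, branch-structure profiles, agreement between
raters, and — where a gold-standard tracing exists — a point-matching score
against it.

`mansegkit` implements that whole loop headlessly. The interactive front end
of a segmentation tool (mouse capture, sliders, 3D viewer) is replaced by
**replayable action scripts**, so that every editing behavior is
deterministic, scriptable and testable; everything downstream of the editing
core — isosurface area/volume, gray-level uniformity, skeleton Sholl
analysis, SWC nearest-point matching, Friedman tests — is ordinary package
code.

# Coordinate conventions

All modules share one convention: 0-based indices, a voxel address is
`(x = column, y = row, z = slice)`, and voxel centers sit at integer
coordinates. Continuous coordinates (freehand vertices, SWC nodes) are
subpixel; only rasterization discretizes, and all rounding is half-up so
results cannot depend on banker's rounding. Physical distances are voxel
addresses scaled by the voxel geometry `(dx, dy, dz)` in micrometers; the
default relative geometry is `(1, 1, 2)`, matching the common confocal
practice of a z-step twice the in-plane pitch (the targeted acquisitions use
0.62 um/pixel in-plane on 512 x 512 frames).

# The session model

A session (the "datamatrix") stores, per segmented object, a boolean volume
the size of the stack, the active editing time in seconds, and optionally a
cached surface mesh. Edits address one slice of the active object and are
only legal while the timer runs — the headless equivalent of "editing only
while the indicator is green".

- **draw** rasterizes a freehand polygon (auto-closed: the last point
  connects back to the first) and ORs it into the slice; drawing can only
  add.
- **undo** removes the 8-connected 2D component under the click on the
  current slice. The 2D (not 3D) scope is a deliberate choice: clicking
  operates on the slice being viewed, and a 3D removal could silently
  destroy work on distant slices. Clicking background is a warning no-op.
- **split** erases mask pixels along the 4-connected *supercover* of a drawn
  polyline. Because consecutive erased pixels always share an edge, the two
  sides are genuinely separated under 8-connectivity — an 8-connected line
  would leave diagonal leaks. Both halves remain in the same object; the
  user decides what to remove afterwards.

**Polygon fill** marks a pixel when its center is strictly inside the closed
polygon under the even-odd rule *or* when it lies on the 8-connected
rasterized boundary of any edge, so the user's stroke is always part of the
mask and a degenerate (collinear) polygon still yields its trace.

**Overlay.** To follow structures across planes, slice *i* can be blended
with the binary mask of slice *i +/- 1*: at mask pixels the overlay channel
shows `(1 - alpha) * g + alpha * 255`, elsewhere the original intensity
shows through unchanged (12/16-bit intensities are first rescaled to 8
bits). Restricting the blend to mask pixels is what makes an empty mask an
exact identity, which we treat as the defining property of the display.

**Timing.** In headless replay the timer derives from script timestamps, not
wall clock. An object accrues time from its creation, selection or a resume
until the next pause, switch-away or the final timestamp; times are kept at
millisecond resolution. Replays are therefore bit-reproducible, including
the time accounting.

**Persistence** uses an uncompressed POSIX tar container written by R's
internal tar: `manifest.json` (dims, geometry, object table with elapsed
milliseconds, format version), one multi-page 8-bit 0/255 TIFF per object
mask, one ASCII PLY per cached mesh. Plain tar needs no external archiver
and every member is itself a standard format. Stack geometry travels in a
JSON sidecar next to the TIFF (`<stack>.tif.geometry.json`), since
ImageDescription round-tripping is not available through the TIFF bindings
used.

# Isosurface morphometry

Surface area and enclosed volume are computed from a triangle mesh of the
binary mask. Contouring the raw 0/1 field at level 0.5 places every vertex
at an edge midpoint and *systematically overestimates the area of a
digitized sphere by ~9%* — the classic staircase artifact — although its
volume is nearly unbiased. We therefore contour a **band-limited indicator**
instead:

1. pad the mask by background on all sides (so boundary-touching masks mesh
   closed);
2. smooth with an isotropic Gaussian of sigma 0.8 voxel;
3. floor the field at 0.49 on foreground voxel centers (the *coverage
   floor*: every selected voxel, down to a single one, still produces a
   surface);
4. contour at level 0.48 with marching tetrahedra (Kuhn 6-tetrahedron
   subdivision — table-free and guaranteed watertight, since every shared
   cell face carries the same diagonal), then scale vertices by
   `(dx, dy, dz)`.

Sigma and level were calibrated once against analytic spheres of radius
10-25 voxels *before* the test suite was written: sigma removes the
staircase bias, and the slightly sub-half level compensates the inward
curvature shift that Gaussian smoothing induces. With these constants the
suite verifies errors below 2% (volume) and 3% (area) for every
r in {10, 15, 20, 25}, with the overall error at r = 25 below that at
r = 10; the acceptance script reports the measured values. We do not claim
strict monotonicity of the error in r: digitization error oscillates, and
the suite deliberately tests bounds plus endpoint convergence rather than
monotone decrease. Volume is reported from the mesh; the voxel-count volume
`n * dx * dy * dz` is reported alongside as a consistency check. Meshes
export to ASCII PLY and STL.

# Gray-level uniformity (GU)

The reference-free goodness index is variance-based and range-normalized:
with foreground/background regions \(R_j\), population variances
\(\sigma_j^2\), weights \(w_j = |R_j|/|\Omega|\) and
\(\sigma^2_{norm} = ((f_{max}-f_{min})/2)^2\) over the whole stack,

\[ GU = 1 - \sum_j w_j \sigma_j^2 / \sigma^2_{norm}. \]

This form is self-contained, bounded in [0, 1], equal to 1 for any perfectly
homogeneous partition, and invariant under affine intensity rescaling.
Because the literature admits several monotone-equivalent variants, and it
is not knowable which exact variant any given study used, the package also
emits the foreground-only variant \(1 - \sigma_1^2/\sigma^2_{norm}\);
either preserves the downstream rank-based (Friedman) workflow.

# Skeleton and Sholl analysis

Skeletonization is sequential topology-preserving thinning: a voxel is
deleted only if it is a *simple point* (exactly one 26-connected foreground
component among its 26 neighbors and exactly one 6-connected background
component in its 18-neighborhood touching a face neighbor) and not a curve
endpoint (at most one foreground neighbor). Deletion proceeds in six
directional subiterations with sequential re-checking until stable. Simple
point deletion provably preserves topology, so the skeleton has exactly the
source mask's 26-component count; endpoint preservation keeps branch tips in
place (tube phantoms retain their ends to within ~3 voxels).

The **soma center** defaults to the foreground voxel maximizing the
anisotropic Euclidean distance to background (Felzenszwalb-Huttenlocher
separable transform; the volume border counts as background), i.e. the
thickest point, which is the soma for any realistic neuron mask; an
explicit center can be supplied instead, mirroring the user-picked center of
interactive Sholl tools. Ties break to the smallest (z, y, x).

A **Sholl intersection** at radius r is an edge (u, v) of the 26-adjacency
skeleton graph with \(d(u) < r \le d(v)\), distances in micrometers from
the center to voxel centers. The edge-crossing rule is parameter-free,
counts each crossing of the sphere exactly once, assigns the boundary tie to
the outer side, and admits an exact brute-force oracle (walk every edge,
test interval containment), which the suite exercises on random skeletons.
Default radii step by twice the in-plane pitch from the pitch up to the
skeleton's maximal extent and can be overridden.

The **log-log fit** regresses \(\log_{10}(N(r) / \frac{4}{3}\pi r^3)\) —
crossing density per sphere volume — on \(\log_{10} r\) by ordinary least
squares over radii with nonzero counts (the log of zero being undefined,
such radii are excluded). A constant-count profile fits slope exactly -3
with \(r^2 = 1\), which the suite asserts at machine precision.

# SWC matching

Gold-standard reconstructions arrive as standard 7-column SWC. Points of
interest are roots, bifurcations (two or more children) and end-points (no
children), deduplicated by node id; a mode using every node is also
provided, since published descriptions of reference sets are often
ambiguous on this point. For each reference point the candidate point
(foreground voxel of the segmentation, or optionally its skeleton voxels)
minimizing the full 3D Euclidean distance is selected, ties broken to the
smallest (z, y, x); the pair's in-plane distance \(d_{xy}\) and axial
distance \(d_z\) are then checked against separate thresholds — defaults
4.76 pixels (XY) and 17 slices (Z) — reflecting the very different in-plane
and axial resolutions of laser-scanning microscopy. Distances are computed
in raw pixel/slice units because the thresholds are stated in pixels;
coordinates can be pre-scaled for physical-unit matching. Percentages of
matched points are reported rounded half-up to two decimals.

# Inter-rater statistics

The Friedman rank test compares k raters over n blocks (neurons, or radii
within one neuron's Sholl profile): mid-ranks within blocks, the usual
\(\chi^2_F\) statistic divided by the tie-correction factor
\(1 - \sum(t^3 - t)/(n(k^3 - k))\), and the upper chi-square tail with
k - 1 degrees of freedom. A fully tied table returns statistic 0 and p = 1.
The chi-square p-value is asymptotic; at the tiny n typical of this
workflow (4 neurons, a handful of radii) it is a coarse approximation to the
exact permutation p — discrepancies of up to roughly 0.1 are expected and
documented, which is why the test suite validates the *statistic* (and its
full exact permutation distribution) against an independent reference
implementation, and treats p-value proximity only as a sanity band. For
Sholl comparisons blocks are radii and treatments are raters, per neuron;
radii missing from any rater's profile are dropped listwise.

# The synthetic phantom

The phantom generator is the test substrate for everything above: a seeded
random binary tree — soma ball at the volume center, a primary trunk, then
bifurcation events that terminate a random tip and spawn two children with
directions perturbed on the unit sphere — rasterized as a union of capsules
(cylinders with spherical caps, per-node radii linearly interpolated) by an
exact voxel-center distance test, then rendered as two intensity levels,
convolved with an anisotropic Gaussian PSF, plus Gaussian noise, quantized
to the bit depth. Tree coordinates are stored in pixel/slice units so SWC,
ground-truth mask and rendered stack are mutually consistent by
construction. The trunk guarantees the root is never itself a bifurcation,
so a tree with B bifurcation events has exactly B two-child nodes and B + 1
leaves — a census the tests rely on.

Defaults encode the targeted acquisition: 512 x 512 in-plane at
0.62 um/pixel, z-step 1.24 um, 8-bit levels 30/200, PSF sigmas
(0.2, 0.2, 0.6) um (realistic for a 40x confocal objective), noise sigma 10.
Tests and the acceptance script shrink the frame to 96 x 96 x 48 voxels
with segment lengths 10-20 um, tube radii 1-2 um and soma radius 6 um so
the whole suite runs in about a minute; the shrunken frame is the package's
declared fixture condition, not a hidden change of regime.

What the phantom does *not* emulate: Poisson photon statistics,
depth-dependent attenuation, spectral bleed-through, and realistic
cell-type-specific arbor geometry. Tests passing on phantoms therefore
demonstrate correctness of the measurement pipeline — rasterization,
editing, morphometry, matching — not segmentation difficulty on real
tissue.

# Numerical choices and degenerate inputs

- Rounding is half-up everywhere a coordinate becomes a pixel.
- The supercover line traversal resolves exact corner crossings by stepping
  x before y, inserting the intermediate cell (the chain stays
  4-connected).
- Meshing an empty mask, skeletonizing an empty mask, fitting fewer than
  two nonzero Sholl radii, matching against empty point sets, and Friedman
  tables below 2 x 2 are errors, not silent results.
- An open mesh (any edge not shared by exactly two faces) refuses to report
  a volume and names the defect.
- 12-bit stacks live in 16-bit TIFF containers with their declared depth
  validated (values above 4095 are rejected) and recorded in the sidecar.
- The phantom's noise stream is seeded with `seed + 1` so tree topology and
  noise are independent but both fully determined by the spec.

# Worked example

```{r example, eval = FALSE}
spec <- phantomSpec(seed = 11L, dims = c(96L, 96L, 48L), somaRadius = 6,
                    segmentLengthRange = c(10, 20), tubeRadiusRange = c(1, 2))
ph <- phantomNeuron(spec)

sess <- newSession(ph$stack)
sess <- addObject(sess, "neuron")
sess@timerRunning <- TRUE
# ... drawRegion()/undoClick()/splitLine() per slice, or replayScript() ...

metricsTable(sess, ph$stack)
sk <- skeletonize3d(objectMask(sess, 1), geometry(sess))
pr <- shollFit(shollProfile(sk, somaCenter(objectMask(sess, 1), geometry(sess))))
matchPoints(pointsOfInterest(ph$tree), maskPoints(objectMask(sess, 1)))
```

# Known limitations

- The session engine stores dense logical volumes; very large stacks
  (2048^2 x hundreds of slices) will be memory-hungry. Masks are byte
  arrays, one per object.
- Mesh extraction smooths in voxel units, not physical units; with strongly
  anisotropic geometry the effective physical smoothing differs per axis.
  This matches how the mask itself is anisotropic, but implies the area of
  very thin structures is resolution-dependent.
- The nearest-point matching score is geometric only; it does not check
  topology (connection paths), and so is a simplified stand-in for
  topology-aware reconstruction metrics.
- `friedmanSholl` aligns profiles on the intersection of radius grids;
  raters measured on disjoint grids cannot be compared.
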