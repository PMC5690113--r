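---
title: "From beam-modifier design to printable mesh, and back: methods and QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From beam-modifier design to printable mesh, and back: methods and QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtprint)
```

# The problem

Patient-specific electron boluses and proton range compensators are designed
in a treatment planning system but must be fabricated before they can be
used. When the fabrication route is a 3D printer, two software problems
appear between the plan and the part:

1. **Conversion.** The bolus design lives in a DICOM RT Structure Set as
   closed planar contours on CT slices; the compensator design lives in a
   DICOM RT Ion Plan as a row-by-column thickness matrix. A printer wants a
   single watertight triangle surface in STL. Someone has to interpolate,
   triangulate and close these point clouds into a printable solid.
2. **Verification.** Once printed, the part must be checked: does its
   surface conform to the design (CT scan of the part vs. design contours),
   is the printed material internally uniform (Hounsfield statistics away
   from the air interface), what is its density, and what is its proton
   stopping power relative to water (pull-back of the Bragg peak when the
   part intercepts a beam)?

`rtprint` implements both halves plus a synthetic-data module that can
generate every input — parametric designs, DICOM fixture files, simulated
CT scans of "printed" objects with noise and partial-volume blur, and
analytic depth-dose curves — so the full pipeline can be exercised and
tested without a scanner, a printer, or patient data.

# Conversion: contour stacks and thickness grids to watertight meshes

## Resampling and slice interpolation

Design contours are stored as closed polygons without a duplicated closing
vertex, in mm, in the DICOM LPS patient frame. Before meshing,
`resample_contour()` subdivides every polygon edge of length $L$ into
$\lceil L / s \rceil$ equal parts (default target $s = 1$ mm), so output
spacing is strictly at or below the target; original vertices are never
moved, so the polygon as a curve — and its perimeter — are unchanged.

Bolus designs are drawn on planning CT slices typically 2–3 mm apart;
`interpolate_stack()` subdivides each z-gap $\Delta z$ into
$\lceil \Delta z / s \rceil$ equal sub-gaps and inserts vertex-wise linear
blends of the bounding contours. Blending two polygons requires a vertex
correspondence, which the source data does not provide. The package uses
the standard shape-blending choice: orient all contours counter-clockwise,
resample each to the common maximum point count uniformly in arc length,
then cyclically align each contour to its predecessor by minimising the
sum of squared inter-vertex distances over cyclic shifts. Two consequences
are documented rather than hidden:

* if no gap needs subdividing, the stack is returned untouched
  (interpolation at or above the existing spacing is the identity);
* when interpolation does run, the contours at the original z positions
  are the correspondence-resampled versions of the originals — every output
  point lies exactly on the original polygon, but exact vertex lists are
  not preserved (preserving them is incompatible with a common point
  count). The corner rounding this introduces is bounded by half the
  resampling spacing and is included in the measured conformity numbers
  below.

## Triangulation

A literal 3-D Delaunay triangulation of the full design point cloud yields
a convex tetrahedralisation, not the object surface, so Delaunay
triangulation is used where it is well-posed and correspondence strips
where they are the natural structure:

* **Lateral walls** (`stack_to_mesh()`): corresponding vertices of adjacent
  slices are joined by triangle strips (two triangles per quad).
* **End caps**: the top and bottom contours are closed by a triangulation
  of the polygon interior (`triangulate_polygon()`): Bowyer–Watson
  Delaunay of the cap vertices, recovery of any missing boundary edge by
  cavity retriangulation (a constrained Delaunay triangulation), and
  culling of exterior triangles by a point-in-polygon test at centroids.
  The empty-circumcircle property therefore holds for the caps in the
  constrained sense (no vertex visible past the boundary constraints lies
  inside a triangle's circumcircle), and the test suite audits this
  against a brute-force check.
* **Compensators** (`grid_to_mesh()`): the thickness matrix is a height
  field on grid nodes, extruded along $-z$ from a flat base. The four
  corners of every rectangular cell are cocircular, so the Delaunay
  diagonal is ambiguous; the tie is broken deterministically (node
  $(r, c)$ to $(r{+}1, c{+}1)$). For any such triangulation the enclosed
  volume equals the prismatoid integral of the linearly-interpolated
  thickness field, which the tests verify exactly.

Every produced mesh must pass `validate_mesh()`: each undirected edge
shared by exactly two facets traversed in opposite directions, Euler
characteristic $V - E + F = 2$ per component, no degenerate facets, and
positive signed volume (outward normals). `mesh_to_printable()` refuses to
write an STL that fails these checks unless forced. Cocircular-point
tie-breaking inside the incremental Delaunay is by insertion order, which
is fixed by the input polygon; repeated runs are bit-identical.

## STL

Binary STL is the default (80-byte header recording the mm unit, uint32
facet count, 50 bytes per facet, attribute bytes zero); ASCII is
available. ASCII vertex values are printed from float32-rounded doubles
with nine significant digits, so ASCII and binary files of the same mesh
re-read bit-identically. The reader merges bit-identical vertex positions
to rebuild indexed topology from the triangle soup.

# Verification

## Geometric conformity

`extract_slice_profile()` pulls a sub-pixel surface profile from a CT
slice by marching squares with linear interpolation (base R's
`contourLines`) at a threshold defaulting to the midpoint between the
background and material intensity classes — the level at which the
partial-volume ramp crosses half-maximum, making the extracted iso-line an
unbiased estimate of the physical surface.

`slice_conformity()` scores one slice as the **largest Euclidean
distance** between the design and measured profiles. Two details the
source data leaves open are fixed as package policy and recorded in every
report: the metric is the *symmetric* largest nearest-point distance
(Hausdorff distance on the sampled point sets — the conservative choice;
a directed metric can hide protrusions of the part), and comparison is by
point-to-point distance after both contours are resampled to at most
0.5 mm spacing, which bounds the discretisation error at 0.25 mm.
`conformity_report()` aggregates over all measured slices inside the
design's z-range (the design is blended to each measured z), reporting
mean and *population* (N) standard deviation. Rigid in-plane
pre-registration (centroid shift plus 2-D iterative closest point) is off
by default — a part scanned in a jig shares the design frame — and is
recorded in the report when enabled.

## HU uniformity, density, heights

`hu_stats()` erodes the object mask by a ball of radius 1.25 mm (the
protocol's margin; converted to per-axis voxel radii, rounded up) before
computing mean and sd, so partial-volume voxels at the air interface do
not drag the mean toward air. The tests construct cubes with known
interior statistics and interface ramps and verify both the recovery
(mean within 0.5 HU, sd within 15% at $\ge 10^4$ voxels) and the fact
that the un-eroded mean is biased. `estimate_density()` is mass divided
by design mesh volume. `height_check()` interpolates the design height
bilinearly at probe positions and flags deviations beyond a 1 mm default
tolerance, mirroring a height-gauge bench check. `hu_to_red()` converts
HU to relative electron density only through a user-supplied
piecewise-linear calibration: that mapping belongs to the scanner, not to
this package, so no default table is shipped.

## Stopping power from Bragg-peak pull-back

The depth-dose model (`bragg_curve()`) is the Gaussian range-straggling
convolution of the power-law stopping curve
$D_0(z) \propto (R_0 - z)^{1/p - 1}$, $p = 1.77$, with
$\sigma = 0.012\,R^{0.935}$ cm by default — a standard analytic Bragg-peak
parameterisation used here as a stand-in for measured or Monte Carlo
curves. $R_0$ is calibrated internally so the distal 80% depth (d80)
equals the requested range; the singular integrand is cell-averaged
exactly before discrete convolution; the default grid is 0.1 mm and a
grid coarser than $\sigma/2$ is refused.

`apply_slab()` shifts a curve upstream by the slab's water-equivalent
thickness $\mathrm{WET} = t \cdot \mathrm{RSP}$, preserving shape — a
first-order model that neglects straggling growth inside the sample,
acceptable because the estimator uses only the shift, in which that
growth largely cancels. The estimator is
$\widehat{\mathrm{RSP}} = (d80_\mathrm{ref} - d80_\mathrm{sample})/t$,
with the range level configurable (0.8 default; 0.9 available — the
measurement convention, not physics, dictates the level). A 1-D slab has
no orientation, consistent with the empirical finding that print
orientation does not shift the depth-dose curve. The published values for
printed PLA (1.10) and polyamide (0.98) are *measurements of physical
prints*; the package uses them only as constructed truths in recovery
tests — a composition calculation cannot reproduce a printed part's
effective density, so no attempt is made to predict them.

# What the synthetic module emulates — and what it does not

`make_scalp_bolus()` generates a crescent-shaped shell with slice-varying
ellipse axes and a smooth seeded perturbation: the geometric regime of a
scalp bolus (tens of mm, curved, non-convex) without anatomical realism.
`make_compensator()` generates a concave bowl plus band-limited noise at
1 mm grid resolution, the regime of a prostate compensator. Thickness is
quantised to 0.01 mm at generation, matching the decimal-string precision
with which grids are written to the plan file, so DICOM round trips are
exact. `voxelize_ct()` classifies voxel centres by vertical ray parity
(the grid is jittered by a fraction of a voxel so rays never graze mesh
edges), adds partial-volume fractions by $3^3$ supersampling, Gaussian
PSF blur, and seeded Gaussian HU noise at 0.5 × 0.5 × 0.625 mm default
spacing. Material defaults follow the measured regimes of printed PLA
(130.1 ± 10.1 HU) and polyamide (−72.1 ± 5.3 HU).

What passing tests on these fixtures *show*: the conversion is watertight
and volumetrically correct, the QA estimators recover known truths at the
voxel scale, formats round-trip, and the whole chain is deterministic
under a seed. What they *do not show*: printer-process artefacts (layer
lines, underfill, warping), scanner artefacts (beam hardening, streaks),
or anatomy. The conformity of a real printed part against its design
(reported at 0.84 ± 0.45 mm for an FDM bolus and 0.40 ± 0.42 mm for an
SLS compensator in the motivating study) can only be measured on physical
prints; the synthetic round trip bounds the *software's* contribution to
that error at roughly one voxel diagonal (the measured mean is ≈ 0.36 mm
at 0.5 × 0.5 × 0.625 mm voxels with 10 HU noise).

# Numerical choices and problem sizes

* Ceiling-based subdivision counts keep output spacing strictly at or
  below targets.
* Scaling (`scale_mesh()`) is about the bounding-box minimum corner by
  default so a part's base stays put; configurable.
* The DICOM layer writes explicit-VR little-endian only, with defined
  sequence lengths; decimal strings carry nine significant digits within
  the 16-byte limit. It is scoped to the RT objects this pipeline touches
  and is not a general DICOM implementation.
* CT HU is raw × slope + intercept from the file's own rescale tags; CT
  fixture pixels are stored as signed 16-bit integers (whole HU), as
  scanner exports are.
* Degenerate inputs error early and specifically: contours with fewer
  than 3 points, self-intersecting design contours, single-slice stacks,
  non-watertight meshes (open edges are listed), beams without
  compensators, mixed CT series, non-uniform slice spacing.
* Test and acceptance problem sizes are chosen to exercise the estimators
  at full fidelity while staying desk-sized: bolus fixtures of ~11 design
  slices and ~60 mm extent voxelised at 0.5 mm (≈ 1M voxels), cubes of
  30–40 mm with $3^3$ supersampling, 100-seed Monte Carlo for the noisy
  RSP study, 1000 random contour pairs for the metric-vs-oracle audit.

# Known limitations

* Single-component, genus-0 designs only: one contour per slice, no
  branching, no tunnels.
* The slab model ignores straggling growth and lateral scatter in the
  sample; it is adequate for range pull-back, not for full curve
  prediction.
* The bolus is closed as an independent solid; a clinical system might
  instead cap it against the skin surface.
* Eclipse-specific compensator dialects (tray orientation, milling-tool
  offsets) are out of scope; the standard ion range compensator
  attributes are assumed.
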