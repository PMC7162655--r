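---
title: "Methods: quantifying retinal vasculature in undistorted 3D"
author: "retinalsfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retinal vasculature in undistorted 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Light-sheet fluorescence microscopy (LSFM) images the mouse retina in its
natural curved conformation, whereas confocal imaging requires flat-mounting,
which compresses the tissue along the optical axis. This package implements,
as reproducible code, the measurements that this experimental contrast calls
for: plexus-plane-referenced vessel diameters (to quantify the flat-mount
distortion), morphometrics and voxel topology of pathological neovascular
tufts in the oxygen-induced retinopathy (OIR) model, filopodium and
actin-bundle kinematics from time-lapse track tables, outer nuclear layer
(ONL) density and thickness, and nucleus-Golgi polarity. Every measurement
can be validated against a synthetic-volume generator with complete ground
truth.

# The reference frame: the plexus plane

In a flat-mounted confocal stack, "width" is the vessel diameter in XY and
"depth" the diameter along Z. In an LSFM stack the tissue sits at an
arbitrary orientation, so the package reconstructs the local orientation of
the superficial vascular plexus instead: all skeleton points within
`fit_radius` (default 30 µm) of the measurement site are collected, and the
plane through their centroid whose normal is the direction of least variance
(the smallest principal component) becomes the *plexus plane*. On a sphere
of mouse-eye scale (radius 1700 µm) a 30-50 µm neighbourhood deviates from
its tangent plane by well under a micrometre, so the planar model is
adequate at capillary scale; the RMS residual of the fit is reported so
users can catch sites where it is not.

Depth is then the chord of the vessel mask through the site along the plane
normal; width is the chord along the in-plane direction perpendicular to the
local vessel axis (`normal x axis`), which is the unique in-plane direction
transverse to the vessel and the direct analogue of the confocal XY
measurement. A `max_inplane` variant measures the maximal in-plane chord
instead, since the flat-mounted analyses did not record which convention was
used; the perpendicular chord is the default because it is well defined for
curved segments. Chords are found by bidirectional ray casting with
trilinear interpolation of the binary mask and linear localisation of the
0.5 crossing, giving sub-voxel precision (diameter errors below one voxel
diagonal in the validation study). Sites whose vessel axis lies within 15°
of the plane normal are rejected: there the width direction is ill defined.

Group comparison (`compare_distortion`) reports per-modality means of width,
depth and aspect ratio and unpaired two-sample t-tests on depth and aspect.
Student's (pooled-variance) test is the default variant and Welch's is
always reported alongside, since the original comparisons state only
"unpaired t-test" and pooled variance is the common default in the field's
statistics software. Degenerate inputs (both groups constant and equal)
report t = 0, p = 1 with a flag rather than erroring.

# Tuft morphometrics

A tuft is a 26-connected component of vessel voxels whose signed height
above the plexus reference exceeds `min_height_um` (default 10 µm; the
source analyses give no numeric cutoff for "above the superficial plexus",
and 10 µm clears the superficial vessels' own diameter while cutting well
below any tuft body). Volume is voxel integration; depth is the maximum
signed height of tuft voxels above the plexus mid-surface, realising "tuft
length perpendicular to the plexus plane". Size classes follow the nuclear
count: fewer than 4 nuclei is small, 4-20 medium, over 20 large, with the
boundary nuclei resolved as 20 → medium and 21 → large.

Connections to the plexus are counted on the skeleton: adjacent
skeleton-voxel pairs straddling the iso-height surface at `min_height_um`,
restricted to those whose upper voxel connects to the tuft's component, and
clustered at 5 µm so a single stalk counts once. The count is stable to ±2
µm perturbations of the crossing height on the validation phantoms. Whether
real "connections" required a lumen is unknowable from the text; any
skeleton bridge counts here.

## Topology

"Holes going through" a tuft are formalised as the first Betti number of the
binary tuft mask. The mask is treated as a union of closed unit cubes, whose
Euler characteristic is computed exactly as V − E + F − C over distinct
vertices, edges, faces and cubes. This realisation makes the foreground
26-connected and the background 6-connected — the convention is stated
because Betti numbers depend on it. With b0 the number of foreground
components and b2 the number of enclosed cavities (background components not
reaching the volume border), b1 = b0 + b2 − χ. Masks touching the border are
rejected ("pad required") so cavity detection is well defined. The
implementation (occupancy arrays in C++) is tested against an independent
set-enumeration oracle in R on balls, tori, double tori and random blobs.

## Nuclei and curvature

Nuclei are detected in the ERG-like nuclear channel by Otsu thresholding,
26-connected labelling, and a marker-based watershed that splits touching
blobs. The watershed floods from the brightest plateaus of the rendered
intensity and accepts a split only when the interface between two candidate
parts is a genuine valley (below 0.8 of the dimmer peak). Intensity, not the
interior distance transform, is the default height function: at nuclear
scale (capsules of ~1.7 µm radius) chamfer quantisation is as large as the
neck contrast between touching nuclei, whereas the blurred intensity valley
between neighbours is well resolved. The distance transform is the fallback
for binary inputs.

Each nucleus is reduced to a principal curve by 3D medial-axis thinning; the
longest geodesic path through the skeleton is resampled at 1 µm and lightly
smoothed. A nucleus is *curved* when arc/chord exceeds 1.2 or the total
tangent direction change (angle between the mean tangents of the first and
last thirds of the curve) exceeds 60°. Both thresholds are this package's
operationalisation — the original classification was visual. The two-sided
criterion is deliberate: thinning erodes the ends of strongly bent nuclei,
deflating arc/chord, while the direction-change metric is insensitive to end
erosion; conversely a straight but tilted capsule acquires staircase noise
that the smoothing and averaged tangents suppress. Sub-resolution skeletons
(under ~2 voxels of arc) are flagged degenerate and classified flat. The
documented pitfall that two parallel nuclei can masquerade as one curved
nucleus is covered by an explicit phantom test.

# Track kinematics

Tracks arrive as CSV (native `track_id, frame, x_um, y_um, z_um`, or the
ImageJ Manual Tracking dialect with pixel coordinates converted via the
supplied pixel size). A filopodium's length at each frame is the distance
from its tip to the base point — by default the first recorded tip position,
because manual tracks record only the tip. Appearance is the first frame
with length above ε (default 0.5 µm, about one pixel of manual clicking
noise); disappearance is the first later frame at or below ε; lifetime
spans the half-open alive interval, so the disappearance frame is excluded.
Tracks that never return to baseline are right-censored, with lifetime up to
the last frame. Extension and retraction speeds are means of the positive
and negative per-frame length rates (maximum rates are not used; the means
are the convention here). Bundle statistics are path length (summed step
lengths), duration, and their ratio as average speed. All of these are
closed-form functions of the track, and the scripted generator computes the
same quantities independently from its scripts, so agreement is exact.

# Nuclear layers

ONL density follows the freehand-ROI particle-analysis procedure: threshold
the nuclear channel inside a polygon, count particles above a minimum size,
divide by the polygon area, and average across sampled slices (the source
procedure sampled every 50 slices at roughly eight areas per condition). One
departure is documented: by default the channel is max-projected across z
inside the ROI before particle analysis, because a single optical section
intersects only the nuclei within about one nucleus radius of its plane and
would underestimate the layer's areal density several-fold on the synthetic
phantoms, where the ground truth is the full count over the ROI area.
`projection = FALSE` restores strict single-slice analysis. Thickness is the
mean of three line measurements per sampled slice (sub-voxel extent of the
layer mask along z), averaged across slices.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the measurements are validated under.

* **Geometry.** A spherical cap of radius 1700 µm (mouse-eye scale) or a
  plane carries tubular vessels with circular cross-sections; default voxel
  spacing is isotropic 1 µm (anisotropy, e.g. (2, 0.5, 0.5) µm, is exercised
  in tests). Vessels thinner than twice the largest voxel pitch are rejected
  as unresolvable.
* **Imaging model.** Binary masks are blurred with a separable Gaussian
  (PSF-like, default σ 0.8 µm), placed on a constant background (0.05) and
  corrupted with additive Gaussian noise (σ 0.02), then clipped to [0, 1] —
  the simplest model that makes thresholding non-trivial. Optical realism
  (light-sheet PSF anisotropy, scattering, photobleaching) is explicitly out
  of scope, so passing tests demonstrate correctness of the measurement
  geometry, not robustness to every real-world artefact.
* **Flat-mounting.** The distortion operator optionally maps the curved
  surface to a plane and compresses all distances to the surface along z by
  a factor k (0.4 in the validation pair, chosen to match the strong
  flattening seen in correlative imaging). Ground-truth widths are invariant
  and depths scale exactly by k; compression 1 without unbending is the
  voxel-identical identity.
* **Tufts.** Bodies realise the requested first Betti number: balls (0
  tunnels), solid tori (1), and two tangent tori fusing in one contractible
  junction (2). A 0-tunnel tuft whose ball would not fit the height budget
  becomes a "cup" — a ring sealed by a top plate, still b1 = 0 and close to
  morphologies seen in drug-treated retinas. Exactly `n_connections` stalk
  tubes join the body to the surface, and exactly `n_nuclei` capsules stand
  inside the body along the outward normal (cells growing into the
  vitreous), spaced ≥ 6 µm so rendered blobs stay separable; curved nuclei
  are longer (12 µm) arcs bent 200° radially outward, so neighbours never
  collide. Nuclei counts, connection counts, tunnel counts and realized
  voxel volumes are recorded per tuft.
* **Time lapse.** Filopodia are scripted as base + direction + per-frame
  lengths, bundles as per-frame positions; the exact track table and the
  closed-form kinematics are emitted with the rendered 4D stack. The
  population helpers reproduce the study conditions: 40 one-minute frames,
  filopodium populations whose mean maximum length targets 14.84 µm
  (developing, P5) or 4.3 µm (OIR), and bundles walking at 2.56 µm/min on
  average — these constants are the observed values of the conditions being
  emulated, and the pipeline re-measures them from the emitted tracks rather
  than echoing them.
* **Layers.** Nuclei are placed by a uniform point process at the requested
  areal density inside a slab of the requested thickness; a warning flags
  densities high enough that rendered blobs merge.
* **Determinism.** Every generator draws all randomness from the single
  integer seed of its specification; identical specs produce bit-identical
  volumes and byte-identical track files.

# Validation studies and problem sizes

`run_distortion_study()` generates 50 tubes with radii uniform in [3, 15]
µm on the spherical cap (each in a 56×96×96 scene with a surrounding
capillary web for the plane fit), measures width and depth natively and
after 0.4 compression, and reports recovery errors, the compressed
depth/width ratio, and the depth t-test. `run_tuft_recovery_study()`
generates 30 tufts cycling through the three classes (up to four per
184×184×72 scene) and matches measured morphometrics to ground truth by
anchor. These sizes keep a full validation run to a few minutes on a single
CPU while spanning the full radius range and all tuft classes; both studies
and the per-module tests run from `tests/testthat`, and
`scripts/acceptance.R` recomputes the same quantities from scratch.

# Known limitations

* Tuft bodies are idealised handlebodies; real tufts are knotted irregular
  vessels. Topology counts are validated, knot *type* identification is out
  of scope.
* The watershed split rule is tuned for ERG-scale nuclei (1.5-2 µm radius);
  heavily overlapping nuclei beyond the generator's packing margin would
  under-split.
* The ONL procedures reproduce the measurement recipe; the original study's
  absolute densities came from n = 1 retina with unstated thresholds and are
  not reproducible quantities.
* Deposited source-data spreadsheets can be re-analysed with
  `read_source_table()`/`cmd_benchmark()` once their column layout is
  mapped; the mapping is configurable because the deposited headers are not
  standardised.
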