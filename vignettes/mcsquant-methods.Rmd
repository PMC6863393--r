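---
title: "Models and methods behind mcsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mcsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsquant)
```

mcsquant quantifies the architecture of ER–plasma-membrane contact sites
from tomographic annotations, and scores genetic interactions from colony
plates. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Surface reconstruction and intermembrane distances

A contact site is annotated as two point clouds clicked along the
cytosolic leaflets of the PM and the ER (nm coordinates). The PM surface
model is built in three steps.

**Plane fit.** A total-least-squares plane: the normal is the direction of
least variance about the centroid (smallest eigenvector of the point
covariance). The normal is oriented with nonnegative z (ties broken by y,
then x), which matches the tomogram convention of an upright PM with the
cytosol above it. Collinear clouds are rejected with the offending site
named.

**Rotation.** The minimal (Rodrigues) rotation taking the fitted normal to
+z, applied about the centroid. The inverse rotation restores the input
to machine precision.

**Biharmonic spline.** Heights above the plane are interpolated with the
biharmonic radial basis $g(r) = r^2(\ln r - 1)$, $g(0) = 0$, the kernel
classically used for smooth surface recovery from scattered tomographic
clicks. We augment the radial expansion with a linear polynomial under
the standard side conditions. The augmentation matters: without it the
interpolant passes through the data but does *not* reproduce a constant
or planar height field between points, so a flat membrane would acquire
spurious undulations between clicks. With it, constants and planes are
reproduced exactly everywhere, and exact interpolation at the clicks is
retained. A ridge term $\lambda = 10^{-8}$ on the radial block keeps the
dense system well conditioned; duplicate click locations are merged by
averaging their heights. The surface is evaluated on a regular
20 × 20 grid spanning the rotated cloud's bounding box.

**Distances.** The grid is triangulated (two triangles per cell, diagonal
from low to high corner) and each ER point contributes its minimum
point-to-triangle distance. We report mean, SD ($n-1$ denominator; a
single-point site reports 0 rather than an undefined value), minimum and
maximum per site. A point whose nearest triangle touches the grid border
lies at or beyond the interpolation domain; it is counted but flagged, so
extrapolation-dominated sites are visible. Complex sites should be split
by the annotator into separate site ids before measurement; the package
does not split automatically.

Two numerical details are deliberate. First, the in-plane orientation of
the grid is canonicalized to the projected cloud's principal axis, with
the 180° ambiguity fixed by the sign of the third moment. This makes the
statistics invariant (to ~1e−13 nm) under rigid motions that keep the
patch upright; without it the axis-aligned bounding box, and hence the
mesh, would depend on the world frame. For laterally isotropic patches
the principal axis is ill-defined and invariance degrades to the mesh
discretization error — flat patches are unaffected because distances to a
planar mesh are exact regardless of triangulation. Second, the
mesh-vs-spline discretization error is below 0.01 nm for smoothly curved
membranes, but click jitter is interpolated exactly, so a 1 nm jitter
produces a wiggly surface that the 20 × 20 mesh smooths unevenly; on
jittered sites the per-point distances can deviate from a dense-grid
evaluation by a few tenths of a nm. The distance-recovery checks therefore
compare *site means*, which stay well within 0.5 nm of the truth.

## Bridging-particle tilt geometry

Each bridging density is picked with four points: A at the ER base, B at
the PM end, C and D auxiliary points roughly 10 nm away along the ER and
PM respectively. Clicks need not be coplanar; we project all four onto
their best (total-least-squares) plane, which is the identity for
coplanar picks. The particle axis is $u = B - A$ and the PM tangent
$t = D - B$; the deviation from perpendicular to the PM is
$\alpha = |90^\circ - \angle(u, t)|$, clipped to $[0^\circ, 90^\circ]$.
Only the PM tangent enters α — the figure quantity is deviation *relative
to the PM* — while C is retained for quality control and box orientation;
averaging both tangents would change α whenever the membranes are not
parallel. The signed in-plane rotation of $u$ against the tangent normal
is retained as the alignment prior. Histograms use 5° half-open bins over
[0°, 90°].

## Collapse-to-2D averaging

Membrane paths clicked in slices (8 nm nominal z spacing) are fitted with
per-coordinate cubic smoothing splines against cumulative chord length,
relaxing the penalty until the maximum residual at the clicks is ≤ 1 nm
(interpolation is the fallback), then reparameterized by arc length.
Boxes are extracted at fixed arc-length steps by trilinear interpolation
on a grid rotated so the membrane normal is the image x axis; the applied
rotation is stored as the item's orientation prior. Particle boxes are
centred at the A–B midpoint with a side of `round(444 Å / pixel)` pixels.
Out-of-bounds boxes are dropped with a log message. Collapse is a plain
sum projection over the full box depth (total intensity is conserved);
the box depth equals the box side unless overridden.

Alignment and classification use constrained multi-reference
cross-correlation with hard assignment — a deterministic, seedable
classifier adequate for the separable class structure of synthetic data,
in place of a regularized-likelihood classifier whose tuning parameters
are not reproducible from published information. References start from a
seeded random partition. Each iteration scores every image against every
reference over rotations within ±15° of its prior (1° steps) and integer
shifts (default ±3 px), by normalized cross-correlation after Gaussian
band-limiting (FWHM 2 nm by default; the original filter values are not
published, and this choice resolves leaflets at 0.74 nm pixels). Scoring
uses a central crop so shifted windows never leave the data. Search grids
are ordered by transform magnitude and a candidate must beat the
incumbent by more than 1e−9 — ties, which arise systematically for images
invariant along the membrane direction, resolve to the smallest
transform. Iteration stops when fewer than 1% of assignments change; an
emptied class is reseeded from the worst-scoring image. With $k = 1$ the
procedure is constrained global averaging.

**Measurements.** Coat thickness: the class average is averaged along the
membrane direction; the two strongest profile peaks are the PM bilayer
(leaflets 4 nm apart); background and noise are estimated from the far
cytosolic tail; the extra layer is the region beyond the first dip after
the cytosolic leaflet exceeding background + 3 SD, and its thickness is
the full width at half maximum above background with linear-interpolated
crossings. If nothing exceeds the threshold the result is "no layer".
Rod length: the profile along the particle axis, averaged over 15 pixels,
is searched for substantial local maxima; the widest inter-peak gap is
the intermembrane span and the length is the distance between its two
flanking peaks, refined to sub-pixel precision by parabolic
interpolation. Both measures are invariant under intensity scaling.

## Coat coverage and SGA scoring

Coverage is arithmetic on voxel masks: volumes are voxel counts times
voxel volume, and the ratio layer/cER is invariant under common voxel
rescaling and additive over disjoint subregions. Masks are inputs;
segmentation is interactive upstream work. A helper thresholds synthetic
volumes at half the slab amplitude for testing.

Colony sizes are normalized multiplicatively: divide by the plate median,
then each row by its row median, then each column by its column median —
one pass, rows before columns, medians over nonzero non-missing wells.
The published description fixes only "per plate, row and column"; the
multiplicative order chosen here is scale-invariant and removes exactly
the effects the generator plants. Median polish (additive in log space)
would be equally defensible; results on multiplicative effect structures
are identical. A plate with under 50% growth among its occupied wells is
flagged and excluded. Scores are log₂ ratios of mean normalized sizes
(replicates averaged after normalization); a query mean of zero is a
lethal sentinel (−∞) and always a hit. The hit cutoff is *strictly*
below −1.00, following the published wording — a score of exactly −1.00
is not a hit. Note that sparse plates distort column medians (a column
with two occupied wells has a fragile median); screens are run on full
384-spot plates, and simulated plates should fill whole rows.

## Cortex profiles

The contour is traversed clockwise from its start vertex in 1 px
arc-length steps; each channel is sampled as the maximum
bilinear-interpolated intensity over a ±2 px band along the inward
normal, capturing thin cortical signals lying slightly inside the drawn
contour. Band width and the max statistic are package choices — the
published straightening procedure does not specify them — validated on
synthetic rings where plateau boundaries land within ~1 step of the
generating angles. Channel comparison is Pearson correlation, which is
offset- and scale-invariant per channel.

## Synthetic-data generators

The generators define the validation conditions:

* **Membrane sites** — click rasters at 10 nm in-plane and 5.5 nm slice
  spacing, flat/tubular/buckled ER geometries, Gaussian click jitter
  along the normal (default studies use SD 1 nm). Distance-recovery runs
  use 29 flat sites of 200 × 200 nm, matching the site count of the
  reference distance dataset.
* **Volumes** — membranes as two Gaussian leaflets (σ 1 nm, 4 nm centre
  spacing, density positive-up), chosen to match bilayer appearance at
  ~2 nm resolution with unambiguous leaflet peaks; rods as 2.5 nm-radius
  cylinders spanning leaflet to leaflet at stated tilts; the coat as a
  uniform slab at half membrane amplitude starting 3 nm above the
  cytosolic leaflet centre (the offset does not enter the FWHM); additive
  Gaussian noise. Default voxel 0.37 nm (the nominal 3.7 Å pixel);
  recovery pipelines run at the 2×-binned 0.74 nm. Membrane thickness and
  rod radius are plausible defaults, not measured values.
* **Picks** — exact rod endpoints plus isotropic Gaussian click jitter;
  with 1 nm jitter and 1000 picks the mean tilt is recovered within 1°.
* **Plates** — multiplicative plate/row/column effects, per-gene fitness
  factors, lognormal noise (multiplicative, keeping sizes positive, as
  colony-size noise behaves in practice).
* **Cortex rings** — Gaussian radial cross-section (σ 2 px) with angular
  intensity domains per channel.

What the generators do **not** emulate: the missing wedge and anisotropic
resolution of real tomograms, CTF effects, membrane undulations at scales
below the click spacing, segmentation errors in masks, plate edge
effects beyond multiplicative row/column structure, and optical blur or
bleaching in fluorescence images. Passing recovery tests therefore
demonstrates correctness of the computations under idealized imaging, not
robustness to every artefact of real acquisitions.

## Problem sizes and determinism

Validation runs are sized for a single CPU: 29 sites × ~780 clicked
points for distance recovery; 111 boxes of 48² px for the coat pipeline;
50 particles in 60² px boxes for the rod pipeline; 100 seeds × 4
replicate plate pairs for the SGA power and false-positive checks. All
generators are deterministic given their seed, and the acceptance script
derives every seed from its `--seed` argument.

## Known limitations

* Point-to-surface distance is defined against the triangulated 20 × 20
  mesh, not the continuous spline; whether the original analysis measured
  to grid vertices or a continuous surface is unknown, and agreement is
  validated against our own dense-grid oracle only.
* The classifier is not a likelihood method; on real, low-SNR cryo-ET
  data a regularized-likelihood classifier would be preferable.
* 3D subtomogram alignment, CTF handling and missing-wedge compensation
  are out of scope.
* The cortical profile extraction does not reproduce any specific
  interactive straightening tool; only qualitative agreement on synthetic
  rings is claimed.
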