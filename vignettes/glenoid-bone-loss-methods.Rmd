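---
title: "Measuring glenoid bone loss and bony stability from CT segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glenoid bone loss and bony stability from CT segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenoidbl)
```

## The measurement problem

Anterior shoulder instability erodes the anterior rim of the glenoid — the
shallow socket of the scapula — and the size of that bony defect drives the
choice between soft-tissue repair and bony reconstruction (Latarjet, J-bone
graft). Three families of CT measurements are in clinical use:

* **Linear (1D)**: a best-fit circle (BFC) is placed on the *inferior*
  glenoid rim, which anterior defects spare; bone loss is the defect
  diameter over the BFC diameter.
* **Area (2D)**: the defect area over the BFC area (the surface/PICO
  method).
* **Concavity-based (3D)**: the *bony shoulder stability ratio* (BSSR), a
  biomechanical index derived from the depth and width of the articular
  concavity, reflecting the concavity-compression mechanism. Deeper sockets
  resist larger tangential forces for the same compressive load.

Manual versions of these measurements require a rater to orient an en-face
view, place the circle, and read off distances — and interrater reliability
degrades as the measurement gets more complex. This package implements the
semiautomated pipeline: from a scapula/humerus label map (the output of any
segmentation tool) it derives all three measurement families
deterministically, with programmatic override hooks standing in for the
interactive review a clinical workstation would offer. It also implements the
statistical machinery used to validate such pipelines (two-way random
absolute-agreement ICC with F-based confidence intervals, Landis–Koch
interpretation, distribution-gated paired comparisons), and a synthetic
phantom generator whose ground truth is available in closed form, so every
stage is testable without patient data.

## Pipeline

`measure_glenoid()` chains the stages; every stage is exported and usable on
its own.

1. **Surface extraction** (`extract_surface`). The binary mask for a role is
   anti-aliased with a Gaussian (sigma one voxel by default) and the
   iso-0.5 surface is extracted by marching tetrahedra. Anti-aliasing is
   load-bearing: the isosurface of a *raw* binary mask is a staircase whose
   area overshoots a sphere's by ~8%, far outside morphometric tolerance,
   while the anti-aliased surface recovers the area and volume of a 10 mm
   sphere voxelized at 0.625 mm to better than 1.5% (the package's own
   convergence tests cover 1.0/0.625/0.4 mm). Marching tetrahedra (six
   tetrahedra per cell sharing the main diagonal) is used because its output
   is watertight by construction for any field. A separate `iso_smoothing`
   flag adds one Laplacian pass on the mesh; it is off by default because
   smoothing biases measurements and the prototype behaviour it would mimic
   is unknown.

2. **Articular region isolation** (`isolate_glenoid_region`). The primary
   heuristic selects scapular vertices within `max_distance` of the humeral
   head surface and keeps the largest connected component. The default is
   6 mm, sized for real joints where cartilage (not segmented in bone label
   maps) and incongruence separate the subchondral plates. For highly
   congruent geometry — the phantom's proxy head touches the socket — the
   threshold must shrink with the joint space; the phantom tests use 0.3 mm
   (noise-free) and 1.0 mm (with 0.2 mm surface jitter, i.e. several sigmas
   of the noise). When no humerus is available, a seed point grows
   geodesically, bounded by dihedral-angle creases (`crease_deg`, default
   12°); this works on sharp articular margins but can leak across smoothly
   blended margins, where the crease is crossed mid-triangle in small
   angular steps — the humerus-distance path is the robust default. An
   explicit `vertex_mask` bypasses both heuristics and models manual outline
   refinement.

3. **Anatomical frame** (`compute_frame`). Principal components of the
   region vertices, ordered by decreasing eigenvalue: long (superoinferior),
   short (anteroposterior), normal (mediolateral). Eigenvectors carry no
   sign, so the caller provides superior/anterior direction hints (from the
   image axes); the normal completes a right-handed triad. Because a
   right-handed frame with the normal pointing at the humeral head cannot
   hold for both shoulder sides simultaneously, `measure_glenoid()` mirrors
   right-side inputs into left-shoulder convention first; all reported
   metrics are mirror-invariant. Near-equal eigenvalues (a circular region)
   trigger an "ambiguous axes" warning; the in-plane orientation is then
   arbitrary but deterministic, which is harmless for rotationally symmetric
   quantities.

4. **Best-fit circle** (`select_posteroinferior_rim`, `fit_best_circle`).
   Border vertices with strictly negative long- and short-axis coordinates —
   the posteroinferior quadrant spared by anterior defects — are fitted with
   a circle in their own least-squares plane: an algebraic (Kasa) fit
   initialises a damped Gauss–Newton refinement of the geometric residual
   (max 50 iterations, tolerance 1e-10; step halving keeps the RMS residual
   non-increasing). The geometric refinement matters because algebraic fits
   are biased on partial arcs, and rim data are quarter-arcs. Vertices lying
   exactly on a quadrant axis are excluded (strict inequalities; a
   deterministic, measure-zero rule). An override circle is returned
   verbatim and flagged in the report, modelling manual refinement. The
   circle is fitted in the rim points' own plane rather than the PCA
   long–short plane; the rim plane is observable directly and is exact when
   the rim is coplanar.

5. **1D/2D bone loss** (`project_contour`, `linear_bone_loss`,
   `area_bone_loss`). The region border is projected orthogonally onto the
   circle plane. The defect diameter is the maximum distance from
   circle-boundary samples (2048 by default) lying outside the projected
   contour to the contour — on a straight chord defect this reduces exactly
   to the classical perpendicular rim-to-circle distance. The defect area is
   the circle area minus the clipped circle-contour intersection, with the
   circle as a regular 1024-gon (relative area error 6e-6) and
   Sutherland–Hodgman clipping (the circle polygon is convex). Discretization
   counts were chosen so their error is far below the 0.1 mm / 0.1% scale of
   reported values; both are configurable. By default any missing arc counts
   as defect; `anterior_only = TRUE` restricts the search to the anterior
   half-plane for strict emulation of the manual technique.

6. **Concavity and BSSR** (`cross_section`, `supporting_line_depth`,
   `concavity_profile`, `compute_bssr`). The articular region is cut by
   planes normal to the long axis through the BFC centre — 10 cuts evenly
   spaced within ±20% of the BFC radius (both configurable; the span keeps
   cuts near the deepest part of the socket). Each cut's intersection
   segments are chained into the longest polyline, expressed in
   (short, normal) coordinates. The supporting line is the line parallel to
   the short axis touching the profile from the lateral side (w = max w);
   depth is the distance from that line to the deepest point, and the chord
   is the span between the contact points (touch tolerance 1e-6 mm). On
   discrete or noisy profiles usually only one point touches the line; the
   per-cut chord then falls back to the BFC diameter, and the fallback is
   flagged in the report. Cuts that miss the region or produce a polyline
   under 5 mm are skipped with a warning; more than half must succeed —
   mesh-irregularity robustness is the stated reason the measurement is
   averaged over cuts at all.

   The BSSR model: the cross-section is treated as a circular arc with depth
   d and half-chord c, giving radius of curvature r = (d² + c²)/(2d), rim
   angle α = asin(c/r), and BSSR = 100·tan(α). This tangent-of-rim-angle
   form is this package's reconstruction of the concavity-compression
   stability ratio (the clinical literature defers to a reference we do not
   reproduce); it is clearly labelled in every report
   (`"circular-arc tan(alpha)"`), and `compute_bssr(ratio_fn =)` accepts a
   substitute depth/chord → ratio function. Plausibility anchor: depths of
   1–2 mm with 25 mm chords give BSSR in the 15–35% band reported for
   patient cohorts. The model requires d ≤ c (a minor arc); deeper profiles
   are rejected, and BSSR grows without bound as d → c.

## The phantom and what it does (and does not) test

`generate_phantom()` builds a glenoid-like solid with closed-form ground
truth: a spherical-cap articular concavity of chord radius R and central
sagitta d (cap sphere radius R_s = (d² + R²)/(2d)) sunk into a bone slab; an
optional superior trapezoidal extension making the outline pear-shaped, so
that fitting the *inferior* circle is genuinely exercised; and an optional
anterior chord defect at offset a — the canonical bony Bankart geometry —
with the cut face re-capped by a vertical wall. The whole top face lies on
the articular sphere: real glenoid articular surfaces are pear-shaped, and a
circular articular face would make the principal axes ill-defined (the
package warns about "ambiguous axes" in exactly that situation). The
inferior rim circle sits exactly in a plane; outside the outline the solid
drops as a vertical wall to the slab bottom. The humeral proxy is a sphere
of radius R_s at the cap's centre of curvature. The polar surface grid
places vertices exactly on the rim circle and the defect chord, so the
tessellation itself introduces no spurious bone loss. Ground truth is a pure
function of the spec: linear ratio 100·(R−a)/(2R), area ratio from the
circular-segment formula, depth profile d(y) = R_s − sqrt((R_s−d)² + y²),
and the circular-arc BSSR of the central cut (depth d, chord 2R).

Defaults are R = 12.5 mm (BFC diameter 25 mm, matching automated
measurements on instability cohorts), d = 2 mm, 0.5 mm mesh edge, 0.625 mm
voxel spacing (a standard CT slice thickness), superior extension on, no
defect and no jitter. Jitter, when requested, is seeded i.i.d. Gaussian
displacement along the cap-sphere normal of articular vertices only — a
deliberately harsh model of segmentation surface noise (real segmentation
error is spatially correlated and smoother). Two numerical footnotes:
the recorded depth profile formula measures the cap's sagitta radially from
the rim ring rather than within the cut plane; the two differ by under 0.3%
over the configured cut span at these geometries, far inside the 5%
validation band. And the phantom's proxy head is perfectly congruent with
the socket, which is why phantom tests tighten `max_distance` as described
above.

What passing phantom tests shows: the geometry engine recovers known
quantities through the whole chain — isolation, frame, circle fit,
projection, clipping, cutting — at sub-percent accuracy, and degrades
gracefully under surface noise and CT-resolution voxelization. What it does
not show: performance on real anatomy (muscle-attachment ridges, osteophytes,
cartilage-space variation, segmentation failure modes), or agreement with
human raters.

## Known limitations found by the phantom

Two are worth stating prominently.

* **Frame tilt on defected glenoids.** The anatomical frame is the PCA of
  the articular vertices, and its normal axis tilts whenever the region is
  asymmetric. Tilt in the long/normal plane is harmless for concavity depth:
  the long-axis coordinate is constant on each cut plane, so the shift it
  induces in the supporting-line coordinate cancels within a cut (the
  phantom grid confirms this — superiorly extended intact caps tilt the
  normal by up to 9° with depth still recovered to ~1%). Tilt in the
  *short*/normal plane does not cancel: removing an anterior segment makes
  the short/normal covariance non-zero, the normal leans anteriorly by a few
  degrees, and the supporting-line depth shifts by up to sin(tilt)·R —
  roughly 30% of d at a 25% linear defect, shrinking as the defect shrinks.
  The 1D/2D metrics are immune (they live in the rim circle's own plane,
  fitted from the coplanar posteroinferior rim). This is a property of the
  method, not of the implementation: the tests verify that depth is
  recovered to 5% with an untilted frame and that the PCA-frame deviation
  stays within the mechanistic sin(tilt)·R bound. Concavity validation
  against closed forms therefore uses the intact cap, where PCA is
  unbiased. On patient data the same mechanism makes concavity depth
  sensitive to how the articular region is outlined — consistent with
  concavity measures being the least reliable manual measurement.

* **Voxel-resolution rim erosion.** Measuring from a 0.625 mm label map
  rather than the source mesh rounds the rim crease (mask quantization plus
  anti-aliasing), pulling the apparent rim inward by roughly a voxel; the
  BFC radius drops by ~0.5–0.9 mm and the ratios shift by a few points. The
  volume-path tests bound these against voxel-sized tolerances (2 voxels on
  the radius, 5 percentage points on ratios). Real CT pipelines inherit this
  scale of bias from the segmentation resolution.

## Reliability statistics

`icc_absolute_agreement()` implements ICC(A,1) — two-way random effects,
absolute agreement, single measures — from the ANOVA mean squares:
ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)), with the
F-distribution confidence interval (Satterthwaite degrees of freedom for the
rater term). The variant is recorded in every output because reliability
studies often omit it; single-decimal published ICCs cannot disambiguate the
variant after the fact, so the standard interrater choice for interchangeable
raters is made explicit here. Calibration: with true ICC 0.90 (case SD 3,
rater error SD 1, n = 100, k = 2), 1000 replicates recover the mean estimate
within 0.02 and 95% CI coverage within 3 points — the acceptance suite reruns
this. Landis–Koch banding rounds to two decimals first so boundary values
behave as printed tables imply; negative coefficients map to "slight".
Missing ratings are a hard error: silently dropping cases changes the ICC.

`compare_paired()` reproduces the distribution-gated protocol: paired
differences are tested for normality with the Lilliefors-corrected
Kolmogorov–Smirnov test (parameters are estimated from the data, so the
plain KS null is wrong); normal-looking differences get the paired t-test,
others the Wilcoxon signed-rank test (exact for n ≤ 25, normal approximation
with continuity correction above). All-zero differences return p = 1 with a
warning. The gate holds its nominal 5% type-I error within 2 points over
1000 null simulations.

For an in-silico two-observer study, a "rater" is one pipeline run with its
own segmentation-noise seed (or its own override file); `reliability_table()`
then mirrors a reliability analysis over any set of parameters. Because the
shared anatomy dominates the noise, pipeline raters agree almost perfectly —
the in-silico analogue of software raters outperforming manual ones on
complex measurements.

## Problem sizes and determinism

The validation suite uses 0.5 mm phantom meshes (~46k triangles) for
accuracy checks, 0.8 mm meshes for the multi-phantom reliability simulation,
1000 replicates for the statistical calibrations, and 1e6 points for the
Monte-Carlo area oracle; these sizes put every oracle's own noise well below
the tolerance it guards. All randomness is seeded: the phantom jitter seed
lives in the spec, and `measure_glenoid()` itself is deterministic — two
runs on the same inputs produce byte-identical reports except the timestamp.

## Input conventions

Volumes: NIfTI (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) integer label maps;
world coordinates are LPS millimetres with 0-based voxel indices (NIfTI's
RAS affine is converted on the boundary). Meshes: PLY or STL, assumed mm.
DICOM series, resampling and automatic segmentation are out of scope: the
pipeline starts at the label map precisely because everything downstream is
independent of how the segmentation was produced.
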