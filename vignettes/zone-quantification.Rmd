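---
title: "Quantifying zone in ROP from ultra-widefield OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zone in ROP from ultra-widefield OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ropzone)
```

## Overview

Zone in retinopathy of prematurity (ROP) describes how far retinal
vascularization extends from the optic nerve. This package measures it
quantitatively from segmented ultra-widefield OCT volumes: it extracts the
retinal pigment epithelium (RPE) surface from a retina/choroid label
volume, connects manually annotated landmarks, measures retinal arclengths
(RAL) as geodesic distances along the RPE from the optic-disc centroid to
the vascular–avascular border, and summarizes them into per-eye
biomarkers — mean-RAL, min-RAL, foveal distance (FD), the min-RAL:FD
ratio, the assessed angle of the border, a spherical-cap estimate of the
area of vascularized retina (AVR), and a mathematical zone label.

This vignette records the model, the parameters that matter, and the
design decisions taken where the procedure was genuinely open.

## Scan geometry

A swept-source UWF-OCT scanner acquires A-scans as rays through a common
pivot. We model the scan-to-space transform as a **single-pivot
equiangular fan**: voxel `(fast, slow, depth)` (0-based, fractional
allowed) maps to

```
alpha = (fast/(nFast-1) - 1/2) * fovFastDeg
beta  = (slow/(nSlow-1) - 1/2) * fovSlowDeg
point = Rx(beta) %*% Ry(alpha) %*% c(0,0,1) * (pivotOffsetMm + depth * depthStepMm)
```

with the pivot at the origin and the central axis along +z. The rotation
order (fast-angle about the slow axis first, then slow-angle about the
fast axis) is fixed and tested against an explicit rotation-matrix
product. Real devices need a calibrated transform; every constant here
(`fov_*_deg`, `depth_step_mm`, `pivot_offset_mm`) lives in a JSON/YAML
sidecar so an alternative calibration can be swapped in without code
changes. The default field of view is 140°, matching current
investigational widefield scanners.

Axial length is calibrated from the radial distance of the foveal RPE:
`AL = al_scale * r_fovea + al_offset_mm`. Whether a device's axial
distance includes an anterior-segment offset is device-specific, so the
offset is an explicit calibration parameter rather than a guess; a
measured AL supplied with the eye always takes precedence. The phantom
profile places the pivot at the globe center, so `al_scale = 2`,
`al_offset_mm = 0` makes AL exactly the globe diameter.

## Surface extraction

The segmentation provides three labels per voxel (background, retina,
choroid) and no explicit RPE class. We define the **RPE as the half-voxel
interface between the last retina voxel and the first choroid voxel**
along each A-scan — the retina/choroid boundary is anatomically the RPE,
and its height is robust to disease severity (unlike the inner retinal
surface, which thickens with ridge formation). Columns lacking either
label are invalid. Noisy columns where stray retina voxels appear after
the first choroid voxel resolve to the last retina-to-choroid transition
and are counted in a QC slot; a column whose choroid lies entirely above
its retina violates the acquisition geometry and is an error.

Retinal thickness is counted **along the ray** (retina voxels ×
depth step), matching per-A-scan depth maps; this overestimates
perpendicular thickness by a factor `1/cos(incidence angle)`, negligible
near normal incidence and documented as an approximation. Display
normalization of thickness maps is configurable (`zlim` in
`writeEnfaceMap`) since no canonical scaling exists.

## Landmarks, border chains and resampling

Annotations are sparse clicks: ≥3 disc-edge points, the foveal center,
and ≥2 border points, all as 0-based `(fast, slow)` coordinates in a JSON
document. Consecutive points are connected by **integer Bresenham
rasterization** (nearest-cell selection), giving an 8-connected chain that
visits every click. The classic driving-axis formulation is used; its
half-integer ties resolve round-half-down in the driving direction, which
the tests pin down with a frozen hand trace.

The **disc centroid** lifts the closed disc-edge chain to 3D using the RPE
depth at the optic-nerve margin (the disc interior itself has no RPE;
edge cells on invalid columns interpolate from the nearest valid columns
within a 5-cell radius, with a QC count) and averages the 3D chain points.
Averaging the edge chain rather than the filled disc region was chosen
because the annotation is an edge contour; the filled-region centroid is
available as an option (`filled = TRUE`) and differs negligibly for
near-circular discs.

Border **resampling** is defined in bearing about the disc's en face
center, reference direction disc→fovea. "Evenly spaced per clock hour" is
implemented as even in *bearing* (3° steps at the default density of 10
per clock hour), not in chain arclength, because the clock hour is an
angular unit about the disc. The temporal hemisphere is the half-plane
containing the fovea (bearings within ±90°); the covered bearing interval
is sampled half-open at its end, so a border covering exactly 60° yields
20 samples. Borders with gaps are handled per contiguous chain, with
coverage the union of the per-chain intervals. Two caveats are deliberate:

- Bearings are measured in the en face index chart, where the fan-beam
  projection distorts angles; a border constructed at ±35° of
  tangent-space bearing on a spherical phantom appears as roughly ±33° en
  face. The assessed angle is therefore an *en face* quantity, as it
  would be when a grader sweeps the projection image.
- The half-open endpoint convention and the bearing-vs-arclength choice
  are config-visible (density, and the chain structure is exposed), not
  silently hard-coded.

## Geodesic arclengths

RAL is the geodesic distance along the RPE surface. We compute it as a
shortest path over the graph whose nodes are the valid surface columns at
their physical 3D positions and whose edges join each column to its
**16-neighborhood** (8 adjacent cells plus 8 knight moves) with Euclidean
3D chord weights (Dijkstra, via `igraph`). Endpoints are spliced into the
graph at their exact 3D positions, connected to the valid columns near
their en face projections, so the disc centroid (which sits slightly
beneath the surface) and interpolated border points are handled uniformly.
The result can never undercut the straight-line 3D distance.

Numerical properties worth knowing:

- The 16-neighbor metrication **overestimate** on a smooth surface is at
  most ~2.8% of the true geodesic, direction-dependent, and does *not*
  vanish with grid refinement; the chord edges meanwhile *undercut* the
  curved surface by O(h²). The package-wide accuracy target is therefore
  3% for lengths (5% for the nonlinearly amplified AVR). An
  8-neighborhood (~8% worst case) is available via `neighborhood = 8`.
- Mesh convergence is assessed on the full-pipeline foveal-distance error,
  where the h-scaled components (annotation rounding, half-voxel surface
  quantization, splice hops) dominate; that error falls monotonically
  across 100², 200², 400² grids in the acceptance suite.
- Degenerate inputs: identical endpoints return 0 exactly; endpoints in
  disconnected surface components raise a categorized measurement error;
  unreachable border samples are dropped with a warning and counted.

FD is measured **geodesically**, consistent with RAL (the 3D chord is
retained in the output as `fdChordMm` for comparison); on a sphere the
two differ by the chord-vs-arc factor `2 sin(θ/2)/θ`, about 1% at typical
disc-fovea angles.

## Biomarkers

The area of vascularized retina uses the spherical-cap formula **exactly
as printed in the clinical literature**,

\[ \mathrm{AVR} = \frac{\pi\,AL^2}{2}\Bigl(1 - \cos\frac{\overline{RAL}}{AL}\Bigr), \]

in which AL plays the role of a radius inside the cosine but of a
diameter in the prefactor. We implement the verbatim form and apply no
geometric correction, because published group-mean AVR values arise from
exactly this parameterization (the acceptance suite reproduces them
within 2% from the group means of AL and mean-RAL). The geometrically
exact cap area on a sphere of radius r, `trueCapArea(r, s) =
2πr²(1 − cos(s/r))`, is provided separately and serves as the phantom
reference. The formula's domain ends at `mean-RAL = π·AL` (the full
sphere in the printed parameterization); beyond it is an error.

The mathematical zone label uses **strict inequalities**: zone I iff
`min-RAL < 2·FD` (a border exactly on the zone I circle is not inside
it), posterior zone II up to two further disc diameters. No consensus
infant disc diameter exists, so it is a required parameter with default
1.1 mm, exposed in configuration. The continuous counterpart
`min-RAL / FD` is always reported alongside.

## The eye phantom

The phantom is the testing ground for every measurement stage: a
spherical globe of radius R (axial length 2R; default 7.7 mm, spanning
7.6–8.0 mm in the acceptance grid to match infant axial lengths of
15.2–16.0 mm), a uniform retinal shell ending at the RPE sphere (0.2 mm),
a choroid shell beyond it (0.2 mm), a disc of 3° angular radius at 28.3°
colatitude, the fovea 28.3° from the disc (so FD = R·0.494 ≈ 3.8 mm, a
typical infant disc-fovea distance), and a border at configurable angular
radius θ_b about the disc — constant, or notched (a rectangular dip in
θ_b over a bearing window) to emulate the posterior notch that drives
zone I classification. A ridge thickening band at the border exercises
thickness-map realism. With the scan pivot at the globe center, every
ground truth is closed-form: FD = R·θ_f, RAL(bearing) = R·θ_b(bearing).

Deliberate simplifications — what passing phantom tests does *not*
establish about clinical data:

- The globe is perfectly spherical; real infant eyes are aspheric and the
  RPE has foveal and peripapillary relief.
- Segmentation noise is modeled only as boundary-interface label flips
  (`noise` = per-voxel flip probability within one voxel of an
  interface), not as the spatially correlated failures of a real U-Net.
- No speckle, motion, vignetting or off-axis pivot misalignment.
- Landmarks are exact grid projections of the configured anatomy;
  clinical annotation error is not simulated.
- Border bearings whose points leave the 140° field of view are clipped
  at generation (wide borders on posterior discs can exceed the scan),
  and truth is computed over the emitted bearing range.

The cohort simulator produces eye-level metric rows directly (volumes for
85-eye cohorts would be needlessly slow): per patient, a latent severity
thresholded into zones I/PII/II; demographics and biometrics from
per-zone normals with defaults representative of published infant ROP
cohorts (gestational age 24.1/24.2/27.8 weeks; birthweight
557.9/605.0/964.6 g; mean-RAL 10.3/11.9/14.8 mm; axial length
15.4/15.2/16.0 mm); two eyes per patient sharing a patient random effect
with inter-eye correlation 0.8 (a stated assumption — the true magnitude
is not established — exposed as `interEyeCor`); min-RAL = mean-RAL minus
a gamma-distributed positive offset; treatment Bernoulli with log-odds
`12.84 − 1.2·mean-RAL`, chosen so that treatment probability is ~62% at
the zone I mean arclength and near zero at the zone II mean.

## Cohort statistics

- **AUROC** by midranks — algebraically the Mann–Whitney pair count with
  ties worth ½, identical to trapezoidal ROC integration with tie
  handling. Single-class input is an explicit error (and an `NA`, i.e. a
  redraw, inside bootstrap replicates).
- **Cluster bootstrap**: whole patients are resampled with replacement
  (2000 replicates in the reference analysis; tests use 250–500),
  because eyes within a patient are strongly correlated and eye-level
  resampling would understate variance. Confidence intervals are
  percentile (2.5/97.5); BCa is not implemented. All cluster draws for a
  run come from one seeded stream laid out replicate-by-replicate, so
  results are bit-reproducible and independent of evaluation order;
  replicates with an undefined statistic are redrawn (counted, and >50%
  undefined is an error). With one eye per patient the procedure reduces
  exactly to the ordinary iid bootstrap, which the tests verify
  draw-for-draw.
- **Predictor comparison**: the paired AUROC difference on the same
  resampled eyes, significant when the percentile CI excludes zero — our
  reading of "mean difference between each predictor pair", since no
  reference distribution is canonical.
- **Calibration**: the acceptance suite simulates 500 cohorts of 150
  patients (two correlated eyes each) from a clustered binormal model
  whose population AUROC is analytic, and checks 95% CI coverage within
  ±3 points at 500 replicates per interval. Percentile intervals for
  U-statistics are mildly anticonservative at realistic cohort sizes
  (coverage ≈ 0.94 here); that behavior is inherent to the percentile
  method, not to the clustering.
- ANOVA and GEE modeling are deliberately delegated to standard
  statistical tooling (`aov`, `geepack`/`glmmTMB` and friends); the
  package's job is to export the tidy eye-level table they consume.

## Problem sizes and tolerances used by the tests

Unit tests run phantoms at 80–200² en face grids; the acceptance grid
(three radii × four border angles, with and without a 12° notch) runs at
400² with 0.02 mm depth sampling, where the full pipeline recovers FD,
mean-RAL and min-RAL within 3% and AVR within 5% of closed-form truth,
and zone labels match whenever the phantom sits ≥5% from a classification
threshold. The notch-flip check brackets the closed-form critical depth
`θ_b − 2θ_f` at ±3°.

## Known limitations

- Geodesics carry a ~1% systematic overestimate (metrication minus chord
  shortcut) that refinement does not remove; an exact polyhedral or
  fast-marching solver behind the same interface would be the upgrade
  path.
- Thickness along the ray, en face bearings, and the en face assessed
  angle are all chart-dependent quantities; they match how graders read
  projection images but are not intrinsic surface measures.
- The nasal border is excluded by construction (only the temporal
  hemisphere is sampled), mirroring current clinical annotation practice.
- The AVR formula is reproduced verbatim with its internal geometric
  inconsistency; `trueCapArea` should be preferred when the globe radius
  is actually known.
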