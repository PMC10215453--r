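---
title: "Quantifying Eustachian tube balloon dilation on CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Eustachian tube balloon dilation on CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etdilate)
```

## The measurement problem

Balloon dilation of the Eustachian tube (BDET) widens the cartilaginous
portion of a thin, obliquely oriented, normally collapsed canal. On axial
CT the ET crosses slices at an angle, so single native slices neither show
the whole lumen nor allow a like-for-like pre/post comparison. The
protocol implemented here solves this with three ideas:

1. an anatomically anchored oblique reslicing plane (medial pterygoid
   plate, hamulus of the opposite medial pterygoid plate, sphenoid spine)
   that can be re-found in both the pre- and post-dilation volume, so the
   two stacks are geometrically matched;
2. balloon-guided ROIs, using the radiopaque marker beads of the inflated
   balloon as fixed, visible anchors for the measurement box;
3. a density (gray-value) criterion for "air", calibrated per scan from
   reference regions, so the outcome — the increase in air-classified
   pixels — does not depend on absolute scanner calibration.

The headline statistic per ear and ROI is

$$\Delta_{\%} \;=\; 100\,\frac{a_{\mathrm{post}} - a_{\mathrm{pre}}}{a_{\mathrm{pre}}},$$

where $a$ is the air-pixel count summed over the 25-image stack.

## Pipeline model and assumptions

**Reslicing.** The plane is fit through the three landmarks (converted to
mm via the voxel spacing); the frame origin is their centroid. The
in-plane vertical is the projected torus-tip→balloon-tip axis when those
points are annotated, otherwise the longest triangle edge — the original
protocol rotated images manually until the lumen was vertical and did not
state a rule, so the balloon-axis convention is this package's choice and
is recorded with the results. The stack is the center image plus 12
images per side at the native 0.625 mm slice spacing (matching the
acquisition protocol), trilinear-interpolated, with an isotropic in-plane
pixel spacing equal to the smaller native row/column spacing so width
measurements carry no direction bias. Values stay continuous internally
and are quantized half-up to integers only where gray-level semantics
require it (histograms, classification, export) — this avoids a second,
uncontrolled quantization of the kind the original viewer-export workflow
could not rule out.

Assumptions: single-frame axial acquisitions without gantry tilt;
landmarks given in 0-based voxel `(slice, row, col)` coordinates (the
slice index grows cranial→caudal; every annotation file must declare this
convention explicitly and is refused otherwise).

**ROI rules.** The small box's rows cross the two marker beads; its
columns span the markers' mean column ± `ceiling(3.5 mm / pixel
spacing)` px. The 3.5 mm half-width is half the balloon's 7 mm maximum
diameter: the reference protocol states only that the small box includes
the inflated cylindrical segment, so the balloon radius is the natural,
scanner-independent default; it is a package convention, exposed as a
parameter. The longest box extends both ends by the same pixel distance
`d`, capped by the torus tip row, the balloon tip row, and strict
exclusion of bone and of the nasopharyngeal air column (any overlap
between the candidate rows and the exclusion mask stops the extension).
The long box is the longest box minus exactly 5 px per end. On real
images the exclusion masks come from density classification (bone range;
nasopharyngeal air as the air-classified connected component touching the
image top); on phantoms the same code path is used. Pixels resliced from
outside the volume are tracked as invalid and are never classified as
air — zero-padding is not anatomy.

**Densitometry.** Ranges are the `[min, max]` of each reference sample
after discarding gray-value bins holding under 0.1 % of the sample
(min/max alone is fragile to single stray pixels; the trim leaves clean
samples untouched). Two air ranges are always computed and reported side
by side: the strict range observed in pure air regions, and a
partial-volume range sharing the air minimum but extending to a
configurable ceiling (default 31), because boundary voxels averaging air
and tissue within one voxel brighten intraluminal air. The reference
study used both (0–16 and 0–31) without stating which produced its
per-ear table, so this package treats the partial range as the headline
mode and labels every count with its mode. All bounds are inclusive, as
the reference ranges are stated as closed intervals.

**Morphometry.** Widths at the nasopharyngeal opening, mid-cartilaginous
level and isthmus are measured on the rotated center image as the maximal
run of air-classified (partial range) pixels along the level row that
contains the seed column, taken from the longest-ROI center — the
reproducible analogue of a manual caliper guided by a constant locator
box; a closed lumen measures 0. Lengths are straight-line pixel distances
between annotated points (torus tip, widest balloon level, balloon tip).
The total length is an independent measurement, *not* the sum of the two
parts — in the reference per-ear table the parts do not sum to the total
(the three points need not be collinear) — so the package only asserts
the triangle inequality, not additivity. Pixel→mm conversion always uses
an explicit spacing argument: the reference study's implied factor
(16.8 mm / 45.26 px ≈ 0.371 mm/px) differs from its header-derived
spacing (160 mm field of view / 512 ≈ 0.3125 mm/px), so no factor is ever
hard-coded.

**Summary statistics.** Column summaries use the arithmetic mean and the
sample standard deviation (n−1): that convention reproduces every printed
SD of the reference tables from their per-ear entries, and population SD
does not. Per-ear air-increase percentages are rounded half-up to
integers at report time; column means are computed on the rounded values
and rounded to the printed precision (the reference table's integer means
are reproduced by this path).

## The synthetic phantom

The cadaver scans behind the reference protocol are not deposited, so the
package generates a parametric stand-in with known ground truth
(`phantom_spec()`, `generate_phantom()`): a soft-tissue background
containing a spherical nasopharyngeal air pocket at the torus, an
obliquely oriented lumen rendered as a tube with elliptical cross-section
whose diameter tapers piecewise-linearly through three knots
(nasopharyngeal opening, mid-cartilaginous level at the end of the
cartilaginous fraction, isthmus), a petrous-bone sleeve around the bony
portion (with a soft-tissue cuff between lumen and bone, as mucosa
separates them anatomically), and — in the during state — an inflated
balloon (16 mm cylinder, 7 mm diameter, conical tip to 3 mm) with two
radiopaque marker beads at the cylinder ends. Dilation multiplies the
three knot widths by per-level factors, concentrated at the mid level as
observed in the reference study.

Defaults are the study conditions: 0.625 mm slices, 0.3125 mm in-plane
spacing (160 mm FOV / 512 matrix, cropped to a 144×144 region around the
ET so a volume stays tractable), a 28 mm lumen (the reference total
length, 75.42 px × 0.371 mm/px) with cartilaginous fraction 0.6 (the
reference part-length ratio 45.26/75.42), pre-dilation knot widths
2.0/1.6/1.0 mm (a plausibly patent cadaver lumen tapering toward the
isthmus; the reference study reports no absolute widths), per-level
dilation factors 1.08/1.72/1.38 (the reference mean width increases per
level), intensities air 6 / tissue 65 / bone 235 / balloon 120 / marker
245 — inside the calibrated density ranges — noise SD 5 gray levels, and
3× supersampling.

Partial volume is simulated physically: each state is rendered on a 3×
supersampled grid and block-averaged, so boundary voxels take
intermediate values and reproduce the 17–31 partial-volume tail; zero-mean
Gaussian noise is added per voxel afterwards, then values are rounded
half-up and clamped to [0, 255]. Rendering is deterministic given the
spec: each state derives its own noise stream from the mandatory seed, so
rendering any subset of states gives identical volumes.

Ground-truth lumen masks mark voxels whose supersampled air fraction is
at least 0.5 (with supersampling off this is exactly the rendered-air
set). One consequence, documented rather than hidden: partial-mode
counting classifies a resliced pixel as air when its air fraction is
roughly ≥ 0.58 at the phantom's air/tissue contrast (the ceiling 31 sits
below the air–tissue midpoint), so raw counts undercount the resliced
ground-truth mask by a stable ≈ 9 % shell of boundary voxels. The percent
*increase* — the method's outcome — is unaffected, because the shell
bias cancels between states; the tests assert both facts.

What the phantom does **not** emulate: full head anatomy, curved lumen
centerlines, mucosal folds, tissue elasticity or recoil, beam hardening,
metal artifacts, or scanner-specific noise spectra. Passing tests
therefore demonstrate the correctness and stability of the *measurement
chain* under controlled geometry and noise, not clinical performance on
patient scans.

## Numerical choices

- Rounding is half-up (`floor(x + 0.5)`) everywhere a gray value or a
  table entry is quantized, so behavior at `.5` is deterministic and
  matches the integer entries of the reference tables.
- Landmark triangles with area ≤ 1 mm² are rejected as degenerate:
  sub-millimeter triangles at CT resolution are annotation errors, and
  the plane normal would be numerically unstable.
- Trilinear (volume) and bilinear (rotation) interpolation; interpolation
  at exact grid points is exact, which the tests exploit (an axis-aligned
  frame reproduces native slices bit-for-bit).
- Out-of-volume samples are zero-valued and flagged invalid; validity is
  propagated through rotation (a rotated pixel is valid only if fully
  interpolated from valid pixels).
- The during-state phantom seed, width quantization, and all ROI
  arithmetic are integer-exact; the only stochastic component anywhere is
  the phantom noise.

## Problem sizes used by the test-suite

Unit tests run on reduced phantoms (17×120×120 voxels, 18 mm lumen with a
scaled 8 mm balloon) chosen so every structure still fits the smaller
volume; the end-to-end recovery checks use the full study conditions
(25×144×144, 28 mm lumen, noise SD 5, 3× supersampling) across ten seeded
runs whose configured dilation spans relative air increases of roughly
20–100 %. At ~5 px pre-dilation mid-width, a single run's width ratio is
quantized in one-pixel (≈ 20 %) steps, so the width-recovery check is
evaluated on the mean ratio across the seeded runs; air-count recovery is
checked per run (±10 percentage points against the ground truth resliced
into the same ROI).

## Known limitations

- Landmarks and balloon-derived points are inputs (manual annotation or
  phantom ground truth); no automatic landmark detection is attempted on
  real scans.
- The DICOM support is deliberately minimal: uncompressed single-frame CT
  series in explicit-VR little-endian form, one series per directory.
  Enhanced multi-frame objects, compressed transfer syntaxes and
  non-axial acquisitions are refused, and a raw-volume + JSON sidecar
  format is provided as the fully controlled interchange path.
- Widths are 1 px-quantized; at the study resolution this dominates the
  error budget of width ratios (see above).
- The air-range ceiling (31) is a calibration constant of the reference
  series; other scanners/windows require recalibration via
  `calibrate_ranges()`.
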