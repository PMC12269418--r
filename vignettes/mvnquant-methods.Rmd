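---
title: "Quantifying cancer intravasation into microvascular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cancer intravasation into microvascular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvnquant)
```

# The measurement problem

In microphysiological models of tumor metastasis, cancer spheroids are
embedded next to self-assembled microvascular networks (MVNs) in a
microfluidic chip. Intravasation — a tumor cell breaching the vessel wall
and entering the lumen — is read out from multi-channel fluorescence
microscopy: a GFP-labelled endothelial channel showing the vessels, a
red-labelled cancer channel, and a phase-contrast channel. The quantity of
interest is the number of cancer particles co-localizing with the vessel
area near each spheroid, reported as intravasation events per spheroid and
compared between experimental conditions (for example, control medium
versus an EMT-inducing cocktail).

`mvnquant` implements this quantification as a reusable, tested pipeline,
together with the supporting measurements used in such studies: vascular
network architecture (junctions and tubule length), microvascular
permeability from dye-efflux time-lapse windows, and the standard 2D assay
metrics (cell circularity, corrected total cell fluorescence, scratch gap
area, spheroid invasion ratio, cytokine-array log2 fold changes).

Because the original microscopy images behind such studies are rarely
deposited, the package ships a synthetic-scene generator with
machine-readable ground truth. All validation in the test suite runs
against that generator; what this does and does not demonstrate is
discussed at the end.

# The intravasation pipeline

The pipeline mirrors the established Fiji/ImageJ workflow, stage by stage:

1. **GFP pre-threshold.** The GFP channel is binarized with the IsoData
   ("default") intermeans threshold. This map is informative where GFP
   expression is strong, but endothelial GFP decays during culture, so it
   is not sufficient on its own.
2. **Feature bank.** A Weka-style per-pixel feature bank is computed on the
   phase-contrast channel and the binarized GFP map jointly: Gaussian
   blur, Sobel gradient magnitude, Hessian eigenvalues, differences of
   Gaussians, and membrane projections. Scales form the powers-of-two
   ladder from `sigma_min = 1` px to `sigma_max = 16` px; membrane kernels
   are 19 x 19 px with line thickness 1, rotated in 30 steps of 6 degrees
   and reduced across rotations by sum, mean, SD, median, max and min.
3. **Random-forest pixel classification.** A 200-tree random forest
   (fitted with `ranger`) labels each pixel vessel versus
   spheroid-plus-background from sparse scribble annotations. A recorded
   seed makes training and prediction reproducible; prediction matches
   feature planes by name, so plane order is irrelevant. A class-probability
   tie (exactly 0.5) is resolved to background: conservative vessel calls
   avoid false intravasation events.
4. **Spheroid windows (tROI).** Spheroids are located in the cancer
   channel (IsoData threshold, components above a minimum area), an
   ellipse is fitted to each by second image moments, and an axis-aligned
   square window with side 115% of the fitted major axis is drawn around
   the center. The window restricts analysis to each spheroid's immediate
   proximity.
5. **Vessel ROI (vROI) and counting.** The classifier runs inside each
   tROI; the cleaned vessel mask (one erosion, one dilation, 3 x 3 cross
   element) becomes the vROI. Cancer signal outside the vROI is excluded,
   the remaining in-window intensities are Otsu-thresholded, 8-connected
   components are labeled, and components with area >= 50 um^2 and
   circularity in [0.5, 1.0] are counted as intravasation events.
6. **Summaries.** Per-spheroid counts are aggregated per condition as
   n, mean, SD and median, and exported in long format for external
   statistical software. The package deliberately reports descriptive
   statistics only; inferential tests belong to dedicated tools.

## Tunable parameters

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| `pixel_size_um` | 1 | um/px | Must be supplied; source images carry no deposited calibration, so every absolute area and length flows from this value. |
| `sigma_min`, `sigma_max` | 1, 16 | px | Feature-scale bounds; the ladder is 1, 2, 4, 8, 16. |
| `membrane_patch_size`, `membrane_thickness` | 19, 1 | px | Membrane-projection kernel geometry. |
| `n_trees` | 200 | — | Forest size. The historical "batch size of 100" of the original tool is a prediction-batching detail and is recorded as provenance only. |
| `troi_scale` | 1.15 | — | Window side over spheroid major axis. |
| `min_area_um2` | 50 | um^2 | Particle size filter. |
| `circ_min`, `circ_max` | 0.5, 1.0 | — | Particle circularity window. |
| `d_max_um` | 50 | um | Permeability diameter selection bound. |

# Shape measurement

Circularity is `4 * pi * area / perimeter^2`, 1.0 for a perfect circle,
approaching 0 for elongated shapes, clipped at 1.0 because digital circles
can nominally exceed 1 under discrete perimeter estimates.

The perimeter estimator matters more than it may appear. Perimeters are
measured by Moore boundary tracing of the outer contour with
corner-corrected step weights: 0.948 per axial and 1.340 per diagonal
step. Naive weights (1 and sqrt(2)) overestimate a digital circle's
circumference by about 5%, which would push ideal-disk circularity down to
roughly 0.90 and silently shift the meaning of the printed [0.5, 1.0]
filter. With the corrected weights, rasterized disks of radius 50–400 px
measure 1.00 within 0.02, and a 1 x 200 px line measures below 0.02. One
consequence of tracing through pixel centers is that small rasterized
squares also measure near 1.0 (their traced contour is nearly the
inscribed octagon); the estimator is tuned for smooth blob-like particles,
which is what the filter is applied to.

Ellipse fitting uses second image moments with the 1/12 pixel-variance
term; generated ellipses with major axis >= 50 px are recovered within
0.2%, comfortably inside the 3% the tROI construction needs.

## Thresholds

Both automatic thresholds are implemented over integer-resolution
histograms (256 bins for non-integer data) with foreground strictly above
the threshold:

- **IsoData (intermeans):** iterate `t <- (mean(below) + mean(above)) / 2`
  from the global mean until stable. The iterative fixed point is tested
  against exhaustive search over all candidate thresholds.
- **Otsu:** exhaustive maximization of between-class variance. When the
  optimum is a plateau — typical when a histogram gap separates the modes —
  the middle of the plateau is returned, matching common reference
  implementations and keeping the threshold centered between classes. The
  returned `effectiveness` (between-class over total variance) is exposed
  for QC.

# Network metrics

Binarized network images are thinned to a 1-px skeleton (Zhang–Suen).
A junction is a skeleton point with at least 3 neighbors; operationally,
the package requires at least 3 *emanating branches* (0-to-1 transition
runs around the 8-neighborhood), which is the same thing for true
branchings but excludes corner pixels of a bent tubule that have 3
neighbors and a single branch. Thinning splits an X-crossing into two
nearby 3-branch pixels, so junction pixels within 2 px merge into one
junction node. Tubule segments are traced between junction/endpoint nodes
with geodesic step lengths (1 px axial, sqrt(2) px diagonal), and reported
per field of view as junction count and total tubule length. On bar, Y,
cross and lattice phantoms the counts are exact and lengths agree with the
constructed geometry within 1%. An optional minimum-spur prune (default
off) drops short junction-to-endpoint segments.

# Permeability

The permeability coefficient of a window spanning a vessel lumen plus
perivascular gel is

P = 1/(I_i − I_b) × (I_f − I_i)/Δt × d/4,

with `I_i`/`I_f` the window means at the initial and final frames, `I_b`
the background level, `Δt` the elapsed time and `d` the mean vessel
diameter, converted from um to cm exactly once inside the formula. The
default series geometry is the standard 15-s interval over 15 min
(61 frames, Δt = 900 s). Windows with `d >= 50 um` are refused (the
cylindrical cross-section assumption), unless explicitly overridden, in
which case the result carries a `diameter_ok = FALSE` flag. Negative P
(final dimmer than initial, e.g. photobleaching-dominated) is reported
with a QC flag rather than clipped.

The vessel diameter is measured as twice the mean Euclidean distance from
the skeleton centerline to the vessel boundary, minus one pixel — the
center-to-center distance overshoots each wall by half a pixel. An
odd-pixel-width strip is therefore recovered exactly, and the synthetic
generator renders vessel strips at odd pixel widths so the rendered
diameter is well defined on the grid.

`I_i` and `I_f` are means over the whole window (lumen plus gel); `I_b`
comes from a user-designated vessel-free region or a supplied scalar.
There is a mild tension between assuming constant intravascular intensity
and measuring the change of the whole-window mean; the printed form of the
estimator is implemented as stated, and the forward model in the generator
keeps the lumen constant while the gel accumulates dye, so the two views
coincide exactly there. An optional regression estimator (slope over all
frames) is provided as a robustness variant and labelled as such; the
endpoint difference remains the reference path.

# The synthetic-scene generator

`scene_spec()` defines the reference conditions used by the validation
suite; they are chosen once to emulate the imaging setting the analysis
assumes:

- 224 x 224 px fields at 1 um/px; five vessel branches as random-walk
  tubes steered through the spheroid's proximity, widths uniform in
  10–40 um (one branch drawn from the upper part of the range so the
  spheroid-proximal region always contains a mature vessel), heading noise
  SD 0.12 rad per step. A `wide_vessels` switch draws 50–80 um widths to
  exercise the permeability selection rule from above.
- GFP: vessel pixels at mean 180, background 20, Gaussian read noise
  SD 10, and *dropout patches* — random blobs inside vessels whose GFP
  falls to background level — covering a configurable fraction of vessel
  pixels (default 0.3; the segmentation stress test uses 0.5). Dropout
  emulates decayed endothelial GFP expression, the reason the
  classification uses the phase channel at all.
- Phase contrast: stylized, not optical simulation — background 100 with a
  random illumination gradient (±10), vessels as a blurred +40 offset with
  an edge-enhancement term, spheroid +80, noise SD 8.
- Cancer channel: background 40 (noise SD 8), spheroid ellipse
  (100 x 70 um default) at 200, particles at 300.
- Particles with exact pixel-count control: filter-passing intravascular
  disks (areas uniform in 60–150 um^2), extravascular disks (outside
  vessels, testing the masking step), undersized disks (49 um^2, just
  under the filter), and elongated 3 x 24 px bars (circularity ≈ 0.39,
  failing the filter). Planted shapes keep >= 2 px clearance from the
  vessel wall (3 px for bars) so that boundary jitter of a *predicted*
  vessel mask cannot clip them into shapes with different filter outcomes,
  and whole shapes stay inside the placement window. Ground truth records
  every particle's pixels, area, nominal circularity, `inside_vessel` and
  `passes_filters` flags, derived from the generating parameters.
- Per-spheroid event counts in condition batches are Poisson draws — the
  simplest count model consistent with a reported per-spheroid mean.
- Dye-efflux series invert the permeability estimator as their forward
  model: constant lumen intensity, gel rising so the window mean grows at
  `(I_i − I_b) · 4P/d` per second, plus per-pixel multiplicative read
  noise (interpreted as sensor noise; window-mean estimation averages it
  down, which is exactly why the method uses window means).

Generation is a pure function of the spec (including its seed). A dense
particle plan can be infeasible for an unlucky vessel layout; the
generator retries with derived sub-seeds (up to 10 layouts,
deterministically) before raising a generation error. Under the default
conditions no failures were observed across 1000+ scenes.

## Problem sizes in the validation suite

The test suite uses 100 scenes for counting recovery, 100 scenes per
condition with five seeded repetitions for the condition-mean study
(classifier trained once on three scenes and shared across repetitions,
matching the one-classifier-many-images workflow), 10 scenes for the
dropout-0.5 segmentation stress test, and 50 seeds for noisy permeability
recovery. The condition-mean study runs with a reduced feature bank
(Gaussian blur, Sobel, difference of Gaussians; sigma 1–8) — the
separation of synthetic phase/GFP textures does not require membrane
projections, and the full bank is exercised separately by the segmentation
stress test.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the pipeline relies
on: bimodal channel histograms, vessels with decayed GFP recoverable from
phase texture, particles on both sides of the size and circularity
filters, and linear dye accumulation. It does not simulate optics (no PSF,
no shot-noise calibration), cell motility, 3D lumen geometry, or touching
particles. Ground-truth recovery on these scenes therefore validates the
pipeline's logic and numerics — masking order, filter semantics,
calibration handling, estimator inverses — not its performance on any
particular real microscope's images. On real data, classifier quality
depends on the user's scribbles, and counting fidelity on staining
contrast; the QC outputs (overlap tables, effectiveness, OOB accuracy,
diameter flags) are there to catch exactly those failure modes.

# Design decisions in brief

- "Default threshold" is implemented as IsoData intermeans, the Fiji
  default; foreground strictly above threshold.
- "Fast random forest" is a standard 200-tree random forest with a
  recorded seed; `ranger` provides the fitting behind the package's
  training/prediction surface.
- The binarized GFP mask enters the classifier as a {0, 1} channel
  alongside phase contrast, with one joint feature bank over both.
- tROI squares are axis-aligned (windows "drawn around" a region suggest
  bounding boxes, and axis-aligned windows make exclusion semantics
  unambiguous).
- Particles touching the window border are kept; particles straddling the
  vessel boundary contribute only their in-vROI portion, because masking
  precedes thresholding in the counting order; no additional
  overlap-fraction criterion is imposed.
- Overlapping tROIs are processed independently; counts are per-spheroid
  statistics.
- Connectivity is 8-connected throughout (Analyze-Particles convention).
- All convolutions use reflect padding, avoiding dark-border artifacts
  that would bias vessel probability at chip edges.
- Cytokine spot handling averages duplicate spots; background subtraction
  is available but off by default, since the reference procedure measured
  raw mean spot intensities.
- Scratch gap masks can be detected automatically from local intensity
  variance (cell-free regions are smooth), but manually traced masks
  remain the reference path; the detector is a convenience.

# Known limitations

- The classifier is validated on synthetic ground truth only; the original
  study's training images are not public.
- The perimeter estimator targets smooth particles; strongly non-convex or
  holed regions are outside its design envelope.
- Junction counting follows the printed pixel-level definition with the
  branch-run refinement; it does not reproduce the full output of
  interactive angiogenesis-analysis tools (meshes, master junctions).
- The permeability model is the single-compartment endpoint estimator; no
  radial-diffusion PDE fitting is attempted.
- Time-lapse particle tracking, 3D lumen verification and
  adherent-versus-lumenized discrimination are out of scope; the automated
  proxy counts co-localized particles, as the source workflow does.
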