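---
title: "Simulated cortical prosthetic vision for indoor mobility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated cortical prosthetic vision for indoor mobility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvsim)
```

## What this package models

A cortical visual prosthesis stimulates visual cortex through an electrode
array; each electrode elicits a *phosphene*, a localized flash of light.
Simulated prosthetic vision (SPV) studies present sighted participants with a
rendered approximation of that percept to ask design questions before
implants exist: how many electrodes are needed for a task, and how should
camera input be reduced to the few features a phosphene display can carry?

`spvsim` re-creates, as a fully synthetic and testable stack, an indoor
obstacle-avoidance paradigm built around *contour-based scene
simplification*: a camera frame is reduced to a binary contour mask, the mask
drives a grid of binary phosphenes, and mobility performance under different
phosphene resolutions and image-processing strategies is compared with
nonparametric paired statistics. Every stage is driven by synthetic inputs —
a ray-cast corridor world and a generative model of behavioral endpoints —
so the full pipeline runs and is verifiable without human data or network
weights.

## The corridor world

The scene generator models a 3 m wide, 22 m long corridor (2.5 m ceiling)
containing thirteen cardboard boxes: seven small (0.30 × 0.50 × 0.90 m,
depth × width × height) and six large (0.30 × 0.75 × 1.80 m). A *route
layout* is one arrangement of the boxes on a slot grid: thirteen
longitudinal slots (defaults: first slot at 2 m, 1.4 m spacing), each
offering a left-flush, centered or right-flush lateral position. The exact
slot coordinates of the physical course are not recoverable, so they are
configuration with documented defaults.

Route difficulty is the length of the shortest collision-free path from the
entrance midline to the far goal line. The walking agent is approximated by
a square of half-width 0.30 m (a shoulder half-width; the agent radius is a
free parameter), obstacle footprints are inflated accordingly
(axis-aligned Minkowski sum), and the shortest path is computed exactly on a
visibility graph over the inflated corners with Dijkstra search; the final
leg meets the goal line perpendicularly, as taut-path optimality requires.
An independent checker (`grid_path_length()`) recomputes the length on a
5 cm lattice whose move set contains all coprime offsets up to four cells,
bounding the lattice metric's overestimate below about 1%; the two agree to
within 1% on random layouts, which is the main correctness evidence for the
planner.

`generate_route_layouts()` samples random slot assignments, keeps `n_routes`
passable layouts whose path lengths all lie within a tolerance (default 2%)
of their median, and appends each layout's mirror image. Among all windows
of candidates that satisfy the tolerance, the one whose median difficulty is
closest to the candidate-pool median is kept: picking the tightest cluster
instead tends to collapse onto trivially straight routes, which would make
"difficulty-matched" vacuous.

### Rendering and ground truth

`render_view()` ray-casts a pinhole camera (default field of view 35°, the
visual angle of the phosphene display, so rendered and displayed fields
coincide; the physical headset's fisheye optics are deliberately not
modeled). Each ray returns planar depth, the hit surface's unit normal, and
a surface identity. The *plain* condition uses one flat reflectance per
surface — dark floor, light ceiling, distinct mid-gray walls, and box faces
that cycle a four-value shade palette (emulating per-face directional
lighting plus slight per-box material variation). The palette exists for an
honest reason: if every cardboard face had identical reflectance, the
boundary between two overlapping boxes would carry no luminance step and no
contrast-based edge detector could see it, in the simulation or in reality.
The *complex* condition multiplies procedural stripe textures (period 0.5 m,
contrast 0.35, per-surface phase) into the floor, walls and box faces —
never the geometry — emulating the wallpaper-and-tape manipulation that adds
within-surface gradients.

The ground-truth surface-boundary mask marks depth or orientation
discontinuities: a centered second-difference depth test per image axis
(`|d(p-1) + d(p+1) - 2 d(p)| > 0.05 d(p)`) plus a pairwise normal-angle test
(threshold 20°). The second-difference form matters: a pairwise relative
depth-jump rule fires spuriously on smooth floor pixels near the horizon,
where grazing perspective makes neighboring depths differ by more than 5%
within a single plane. Because the mask depends only on geometry, it is
pixel-identical between plain and complex renders of the same pose — the
defining property of an idealized surface-boundary predictor, and the reason
it can stand in for a learned boundary network. An adapter
(`boundary_prediction()` + `extract_contours(..., "boundary_external")`)
accepts any external predictor producing a 0–255 boundary-probability map
and a normal map; no network or weights ship with the package.

## Contour extraction

The edge-detection path is a from-scratch Canny implementation: Gaussian
smoothing (default sigma 3.0 px, reflective borders), 3 × 3 Sobel gradients
with L2 magnitude (the isotropic choice; the gradient norm is configuration
since reference implementations differ), non-maximum suppression over four
quantized gradient directions, and dual-threshold hysteresis (defaults 25
and 50 on the 8-bit scale): a pixel survives if its gradient exceeds the
upper threshold, or exceeds the lower one and is 8-connected through
above-lower pixels to a pixel above the upper threshold. Hysteresis is
implemented as connected components (via igraph) and is tested against an
explicit flood-fill oracle on small random fields. Grayscale conversion uses
ITU-R 601 luma weights.

The surface-boundary path thresholds the boundary-probability map at 94 (of
255) and ORs in Canny contours of the surface-normal map (Canny per normal
component, union of masks; sigma 1.0, thresholds 25/50). How the original
pipeline computed normal-map contours is unstated, so the per-component
union — the simplest rule that reduces to the scalar case — is the
documented choice.

On plain-scene renders the Canny mask and the geometric boundary mask agree
closely (F1 above 0.8 under a 2-pixel matching tolerance, computed by
`mask_f1()`); this is the package's embodiment of the claim that
plain-environment edge detection approximates ideal surface-boundary
detection, and it is checked end-to-end in the test suite.

## Phosphene simulation

`phosphene_grid_spec()` describes an n × n grid (study values 10–50) on a
480 × 480 display spanning ~35° of visual arc. Phosphenes are white Gaussian
blobs of sigma 2.0 px — an angular size of 2 × 2.0 × 35/480 ≈ 0.29°,
consistent with punctate phosphenes reported around 0.3° — truncated at four
sigma, additively accumulated and clipped at 1. Grid locations receive
uniform jitter (default up to 15% of the grid pitch per axis) and each
phosphene a temporally constant brightness gain (normal, mean 1, SD 0.1,
clipped to [0.5, 1.5]); both are frozen by the spec's seed, so a frame
stream sees a constant map. The jitter and gain magnitudes emulate
"biological irregularity" qualitatively; no quantitative values exist to
calibrate against, and they are flagged as assumptions.

Phosphenes are binary (on/off), reflecting the current lack of graded
brightness control in cortical stimulation. The mask-to-activation rule is
not published; the default here is max-pooling over each phosphene's
pitch-sized receptive window: contour masks are one pixel thin, so mean
pooling would extinguish nearly all phosphenes at low resolutions.
Mean-pooling with a threshold is retained as configuration for sensitivity
analysis. Even-n grids place no phosphene at the exact display center; this
cell-center convention is accepted.

```{r phosphene-demo}
co <- corridor_spec()
layout <- generate_route_layouts(n_routes = 2, seed = 7)[[1]]
pose <- walkthrough(layout, co, speed_mps = 1, frame_rate_hz = 0.5)[[1]]
view <- render_view(co, layout, pose)
percept <- simulate_view(view, phosphene_grid_spec(26, seed = 1))
percept
```

## Experiment design

Each participant completes two sessions of 18 trials: two camera-vision
controls first (one per scene complexity, order randomized), then 16 SPV
trials — edge detection at six resolutions times two complexities, plus
surface-boundary SPV at 26 × 26 and 42 × 42 times two complexities — in
uniformly random order. Totals over both sessions: 4 camera, 24 CED-SPV and
8 boundary-SPV trials. Layout assignment enforces two matching constraints:
the plain and complex trials of one condition share a base layout in
mirrored orientations, and each surface-boundary condition reuses the layout
of its CED counterpart in the same session. The two sessions draw layouts
independently (how repeated conditions were matched across sessions is not
specified; independent draws are the weakest assumption). Whether the
complexity order within a pair was itself randomized is also unstated; it is
randomized here. `verify_schedule()` re-checks every constraint and names
offending slots, and is itself exercised with deliberately corrupted
schedules in the tests.

## Synthetic behavioral model

The generator is a *structural stand-in* for unpublished human data — its
purpose is calibration and power analysis of the statistics pipeline, not
reproduction of the study's numbers. Per trial:

* duration = condition mean + participant effect (normal, SD 7.748 s, the
  reported between-participant dispersion) + a −3.468 s shift on session-2
  SPV trials (the reported learning effect, implemented as a session shift
  rather than a per-trial slope; the reported trial-number correlation
  r ≈ −0.15 is treated as an emergent qualitative check, not a calibration
  target) + normal residual (SD 6 s, a free parameter), floored at 5 s;
* collisions ~ Poisson(condition rate × lognormal participant frailty), the
  frailty scaled so the between-participant SD of mean collisions
  approximates the reported 0.251; camera-vision collisions are forced to
  zero, as reported for the control condition;
* rating = condition mean + participant effect (SD 0.783) + residual,
  rounded and clipped to the 1–10 scale.

Only two condition-level anchors are published (camera mean duration
16.74 s; overall mean 31.02 s). All other condition means are free
parameters with qualitative defaults: monotone improvement with resolution,
a complexity penalty at low resolutions that vanishes and slightly reverses
at 50 × 50, and boundary-SPV trailing CED in the plain scene. Figure-read
values are never hard-coded as truth. Setting
`default_condition_means(complexity_penalty_scale = 0)` yields a null
generator with no complexity effect, used for type-I calibration.

What the generator deliberately does **not** model: locomotion dynamics,
gaze, perceptual decision processes, or any coupling between the rendered
scenes and the behavioral endpoints. Passing calibration tests therefore
demonstrates correctness of the *analysis pipeline* under the assumed
endpoint model, not validity of conclusions about real human mobility.

## Statistical pipeline

All endpoints are z-scored within participant over all analyzed trials,
controls included (the standardization scope is a documented choice; only
"within participants" is specified). The pairing unit for planned
comparisons is the per-participant mean of a condition's trials across both
sessions. Two families of two-sided Wilcoxon signed-rank tests are run per
endpoint: scene complexity at each of six CED resolutions (Bonferroni
threshold 0.05/6, displayed as 0.0083) and surface-boundary vs CED in each
of four measured subconditions (0.05/4 = 0.0125).

The signed-rank test drops zero differences (Wilcoxon's original rule) and
mid-ranks ties. With at most 15 informative pairs the two-sided p-value
comes from exact enumeration of the 2^n sign patterns of the observed ranks
(computed by convolution, valid under ties); beyond that a normal
approximation with tie and continuity correction is used. Whether the
original analysis used exact or asymptotic p-values is unknown; both paths
exist and the switch point is configuration. The implementation is verified
against brute-force enumeration and against `stats::wilcox.test()` on
tie-free data. Shapiro–Wilk screening (via `stats::shapiro.test`) is
advisory only — the pipeline always proceeds with rank tests. The
restoration percentage expresses a condition's performance linearly between
a floor (worst SPV condition: 10 × 10, complex) and a ceiling (camera
vision), unclamped. A least-squares slope of collisions on duration per
condition screens for a speed–accuracy trade-off.

Calibration, checked in the test suite at n = 20 participants: family-wise
type-I error of the six-test complexity family stays at or below 0.05
(within binomial tolerance over 500 null replicates), and the injected
low-resolution complexity effect is detected in at least 80% of replicates.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script are chosen to keep
a full run in the low tens of minutes on one CPU: oracle comparisons use
small rasters (up to 32 × 32 for hysteresis, 64–200 px renders for
geometry), full-resolution (480 px) renders appear only in the end-to-end
checks, the grid-Dijkstra comparison uses 20–50 layouts, and calibration
uses 500 null plus 200 effect replicates. Degenerate inputs fail loudly:
zero within-participant spread, all-zero paired differences, blocked
corridors and invalid poses raise typed errors rather than silent values.
All randomness flows through explicit integer seeds; identical seeds
reproduce layouts, maps, schedules and datasets bit-for-bit.

## Known limitations

* The renderer is a flat-shaded pinhole model: no fisheye distortion, global
  illumination, shadows or motion blur. Its plain-condition contrasts are a
  design choice that makes all surface boundaries in principle visible to an
  edge detector; real low-contrast scenes will be harder for CED than this
  simulation suggests.
* The ideal-boundary oracle has none of the failure modes of a learned
  predictor (frame-to-frame inconsistency, motion-blur sensitivity,
  generalization gaps), so comparisons against it bound what boundary-based
  simplification could achieve, not what any current network does achieve.
* Cortical magnification, eccentricity-dependent phosphene size, fading and
  electrode interactions are out of scope, as in the simulated paradigm this
  package models.
* The behavioral generator's condition means are assumptions; analyses of
  synthetic data characterize the pipeline, not human performance.
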