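# spvsim

Simulated cortical prosthetic vision (SPV) for indoor mobility research.

A cortical visual prosthesis elicits a pattern of *phosphenes* — localized
flashes of light — via electrode arrays in visual cortex. Because the
percept carries orders of magnitude less information than normal vision,
camera input must be reduced to the few features worth transmitting; a
leading strategy is **contour-based scene simplification**, either edge
detection on the raw frame (Canny, CED) or stricter **surface-boundary
detection** that discards within-surface gradients and background texture.
`spvsim` implements a complete, testable simulation stack for studying that
trade-off in an indoor obstacle-course paradigm:

* **Scene generator** — ray-cast renders of a 3 m x 22 m corridor with 13
  box obstacles (plain or textured "complex" variants), with ground-truth
  depth, surface normals, and surface-boundary masks; route layouts
  difficulty-matched by shortest collision-free path length (visibility
  graph + Dijkstra, validated against a 5-cm grid oracle) plus mirrored
  counterparts.
* **Contour extraction** — a from-scratch Canny implementation (Gaussian
  sigma 3.0, hysteresis thresholds 25/50 of 255) and a surface-boundary
  combiner (probability threshold 94 of 255 OR'd with normal-map contours),
  with an adapter contract for plugging in any external boundary predictor.
* **Phosphene simulator** — binary phosphenes on an n x n jittered grid
  (n = 10..50) rendered as Gaussian blobs (sigma 2 px ≈ 0.29 degrees of
  visual arc on a 480 px / 35 degree display) with temporally constant
  per-phosphene gains.
* **Experiment design** — the randomized two-session trial schedule
  (4 camera + 24 CED + 8 boundary trials per participant) with mirror- and
  method-matching constraints, plus a verifier.
* **Synthetic behavioral data** — condition-level means with participant
  random effects (SD 7.748 s duration, 0.251 collisions, 0.783 rating), a
  −3.468 s session-2 learning shift, Poisson collisions, bounded ratings.
* **Statistics** — within-participant z-scoring, exact/approximate Wilcoxon
  signed-rank tests (zero-drop, mid-ranks), Bonferroni-adjusted planned
  comparison families (6 complexity tests, threshold 0.0083; 4 method tests,
  threshold 0.0125), Shapiro–Wilk screening, learning-effect and
  restoration-percentage summaries.

The methods vignette (`vignettes/spv-methods.Rmd`) documents the models,
parameter choices and limitations.

## Worked example

```r
library(spvsim)

co <- corridor_spec()                                  # 3 x 22 x 2.5 m, plain
layouts <- generate_route_layouts(n_routes = 7, seed = 1)
round(attr(layouts, "lengths"), 3)
#> [1] 22.051 22.066 22.069 22.078 22.088 22.091 22.097

pose <- walkthrough(layouts[[1]], co, speed_mps = 1, frame_rate_hz = 0.5)[[1]]
view <- render_view(co, layouts[[1]], pose)
view
#> <rendered_view> 480x480 px, plain corridor, depth 2.86-21.90 m

percept <- simulate_view(view, phosphene_grid_spec(26, seed = 1))
percept
#> <phosphene_frame> 133/676 phosphenes on, 480 px display

mask_f1(extract_contours(view, "ced"),
        extract_contours(view, "boundary_oracle"), tol_px = 2)$f1
#> [1] 0.879
```

The seven routes differ in shortest-path length by well under the 2%
difficulty tolerance; the 26 x 26 percept switches on the 133 phosphenes
whose receptive windows contain contour pixels; and on a plain (texture-free)
scene the Canny mask agrees with the geometry-derived ideal boundary mask at
F1 = 0.88 under a 2-pixel tolerance — edge detection in a plain environment
approximates ideal surface-boundary detection.

Synthetic behavioral analysis:

```r
sch <- build_experiment_schedule(20, seed = 1)
trials <- sample_trials(sch, behavioral_model_params(), seed = 2)
rep <- run_planned_comparisons(trials, endpoints = "duration_s")
head(as.data.frame(rep)[, c("resolution", "W", "p", "significant")], 3)
#>   resolution   W            p significant
#> 1         10 210 9.569173e-05        TRUE
#> 2         18 199 4.819289e-04        TRUE
#> 3         26 204 2.357454e-04        TRUE
```

With default effect sizes, the injected complexity penalty is detected at
the low phosphene resolutions (p < 0.0083 after Bonferroni) and absent at
the high ones — the qualitative signature the paradigm is designed to
resolve.

## Command line

A thin CLI over the package functions ships in `inst/cli/spv.R`:

```sh
Rscript inst/cli/spv.R schedule --participants 20 --seed 1 --out schedule.csv
Rscript inst/cli/spv.R synth    --schedule schedule.csv --seed 1 --out trials.csv
Rscript inst/cli/spv.R analyze  --trials trials.csv --out report.json
Rscript inst/cli/spv.R simulate --n-phosphenes 26 --complexity plain --out spv.png
```
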