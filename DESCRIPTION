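Package: spvsim
Title: Simulated Cortical Prosthetic Vision for Indoor Mobility Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simulation toolkit for studying contour-based scene
    simplification in simulated cortical prosthetic vision (SPV). Provides a
    ray-cast generator of indoor obstacle-course scenes with ground-truth
    depth, surface normals and surface-boundary masks; Canny edge detection
    and surface-boundary contour extraction; a binary phosphene simulator
    (jittered grids of Gaussian blobs at configurable resolutions); a
    randomized two-session trial-schedule builder with route mirroring and
    matching constraints; a synthetic behavioral data generator with
    participant random effects and a session learning effect; and a
    nonparametric analysis pipeline (within-participant standardization,
    exact and approximate Wilcoxon signed-rank tests, Bonferroni-adjusted
    planned comparisons, normality screening, learning-effect and
    performance-restoration summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
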