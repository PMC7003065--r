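Package: sptmix
Title: Single-Molecule Tracking Simulation and Apparent-Diffusion Mixture
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mobility of DNA-repair proteins from
    sparse single-molecule localization (PALM) data in bacteria. Provides a
    seeded simulator of multi-state Brownian motion inside rod-shaped
    (spherocylindrical) cells with photobleaching-limited track lengths and
    localization noise; conservative nearest-neighbour track linking;
    per-track apparent diffusion coefficients D* = MSD/(4 dt) from a fixed
    number of steps; maximum-likelihood fitting of a multi-species gamma
    mixture to the D* distribution (with an optional fixed-mobility,
    occupancy-only variant); and replicate-level immobile-fraction summaries
    with unpaired two-sample comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
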