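# sptmix

Quantitative mobility analysis for single-molecule tracking (PALM) of
DNA-repair proteins in bacteria.

When a repair protein such as UvrB engages DNA it stops diffusing, so the
fraction of *immobile* molecules is a direct, live-cell readout of repair
activity. `sptmix` implements the full computational chain behind that
readout:

1. **Simulation** of sparse photoactivated emitters diffusing inside
   rod-shaped (spherocylindrical) cells, with multi-state Brownian motion,
   reflecting boundaries, Gaussian localization noise, and
   photobleaching-limited track lengths (geometric, mean 2.5 frames at the
   default survival probability 0.6).
2. **Track linking** by conservative mutual-nearest-neighbour assignment
   between frames, with a hard displacement gate.
3. **Per-track apparent diffusion coefficients.** For each track with at
   least *n* = 4 steps,

   D\* = MSD / (4 Δt),  MSD = (1/n) Σᵢ |rᵢ₊₁ − rᵢ|²,

   using exactly the first n single-frame steps (Δt = 15 ms by default).
4. **Mixture decomposition.** For one diffusive species with mobility *D*,
   D\* follows a gamma law with shape *n* and scale *D*/*n*:

   f(x) = (n/D)ⁿ xⁿ⁻¹ e^(−n x / D) / (n−1)!

   A population is modelled as a *k*-species mixture
   p(x) = Σᵢ fᵢ · f(x; Dᵢ, n), fitted by multi-start
   expectation–maximization on the raw D\* values (no histogram binning).
   Mobilities can optionally be held fixed so that only occupancies are
   fitted (the constrained fit used to compare a perturbed condition against
   reference mobilities).
5. **Replicate statistics.** The immobile fraction (occupancy of the
   lowest-mobility species, or threshold counting at D\* < 0.2 µm²/s) is
   summarized per biological replicate and compared between conditions with
   the unpaired two-tailed pooled-variance t-test.

The package is written for the regime typical of bacterial PALM: three
diffusive species near 0.11 (immobile), 0.41 (slow) and 1.24 µm²/s (fast),
10,000-frame movies at 15 ms intervals, and track populations of 10³–10⁵.

## Worked example

Recover species mobilities and the immobile fraction from a synthetic
population of 20,000 four-step tracks in which 35 % of molecules are
immobile:

```r
library(sptmix)

species <- species_set(d = c(0.11, 0.41, 1.24),
                       occupancy = c(0.35, 0.325, 0.325))
tracks  <- simulate_tracks(20000, species, n_steps = 4,
                           frame_interval = 0.015, seed = 1)
dstars  <- compute_dstars(tracks, frame_interval = 0.015, n_steps = 4)
fit     <- fit_dstar_mixture(dstars, k = 3, seed = 1)
fit
#> Gamma mixture of 3 diffusive species (free mobilities)
#>   20000 tracks, 4 steps per D*, log-likelihood -7075.085
#>   species 1: D = 0.1120 um^2/s, occupancy 0.353
#>   species 2: D = 0.4153 um^2/s, occupancy 0.328
#>   species 3: D = 1.2359 um^2/s, occupancy 0.319
immobile_fraction(fit)
#> [1] 35.28725
```

The three mobilities come back within a few percent of the ground truth and
the immobile occupancy within half a percentage point.
`plot_dstar_distribution(dstars, fit)` overlays the fitted component
densities on the normalized D\* histogram.

The same analysis can start from a full simulated movie — localizations,
linking and the 4-step filter included — and compare two conditions across
biological replicates (independently simulated movies):

```r
cfg <- pipeline_config(
  acquisition = acquisition_config(n_frames = 5000),
  geometry    = cell_geometry(n_cells = 500),
  seed        = 42
)
conditions <- list(
  control = species_set(c(0.11, 0.41, 1.24), c(0.16, 0.42, 0.42)),
  darT    = species_set(c(0.11, 0.41, 1.24), c(0.35, 0.325, 0.325))
)
report <- run_pipeline(cfg, conditions, n_replicates = 4)
report
#> Single-molecule mobility report
#> control: immobile 18.2% +/- 2.5 (n = 4 replicates)
#> darT: immobile 33.9% +/- 3.0 (n = 4 replicates)
#> control (18.2%) vs darT (33.9%): t = -8.043, df = 6.00, p = 0.0001974
#>   unpaired two-tailed t-test (pooled variance)
```

Movie-level estimates sit 1–2 points off the simulated occupancies because
localization noise (35 nm by default) raises every apparent mobility by
about σ²/Δt ≈ 0.08 µm²/s and blurs the immobile/slow boundary; the methods
vignette (`vignettes/mobility-analysis.Rmd`) discusses this and every other
modelling choice.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "spt.R", package = "sptmix")` with subcommands
`simulate`, `link`, `fit`, `report` and `run`; an example YAML configuration
is in `inst/extdata/example_config.yaml`.

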