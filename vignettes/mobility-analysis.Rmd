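---
title: "Models and methods behind the sptmix mobility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the sptmix mobility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptmix)
```

# The measurement

Photoactivated localization microscopy (PALM) follows individual
fluorescently tagged molecules in live bacteria: a handful of emitters are
stochastically activated per frame, localized to a few tens of nanometres,
and bleached within a few frames. Linking the per-frame localizations gives
short tracks; each track's apparent diffusion coefficient

$$D^* = \frac{\mathrm{MSD}}{4\,\Delta t}, \qquad
  \mathrm{MSD} = \frac{1}{n}\sum_{i=1}^{n} \lVert r_{i+1}-r_i\rVert^2,$$

summarizes its mobility from exactly the first $n$ single-frame steps
($n = 4$, $\Delta t = 15$ ms by default). For a DNA-repair enzyme such as
UvrB, molecules engaged on DNA are immobile while searching molecules
diffuse, so the occupancy of the lowest-mobility species reports repair
activity. `sptmix` provides the simulator, the linker, the $D^*$
computation, the mixture decomposition, and the replicate-level statistics
as one seeded, testable pipeline.

# Statistical model of $D^*$

For 2-D Brownian motion with coefficient $D$ observed without noise, each
squared step displacement divided by $4\Delta t$ is exponential with mean
$D$ (the two squared Gaussian components form a $\chi^2_2$). The mean of
$n$ such estimates is therefore gamma with shape $n$ and scale $D/n$:

$$f(x \mid D, n) = \frac{(n/D)^n\, x^{\,n-1}\, e^{-n x / D}}{(n-1)!},$$

with mean $D$ and variance $D^2/n$ (`dstar_density()`). A population of $k$
species with occupancies $f_i$ yields the mixture
$p(x) = \sum_i f_i\, f(x \mid D_i, n)$.

Two points follow from this model and shape the whole package:

* **Fixed step count.** Using the *first four steps of every qualifying
  track* — not all steps, not a lag-time fit — keeps the shape parameter
  identical across tracks. Mixing shapes would invalidate the closed form.
* **Apparent mobilities.** Localization error $\sigma$ inflates each
  displacement independently of motion, adding roughly $\sigma^2/\Delta t$
  to every apparent mobility ($\approx 0.082\ \mu m^2/s$ at
  $\sigma = 35$ nm, $\Delta t = 15$ ms). The reference immobile species at
  $0.11\ \mu m^2/s$ is consistent with essentially bound molecules seen
  through this noise floor, and the `test-mixture-fit` suite verifies the
  floor directly. For this reason the fitted $D_i$ are reported as apparent
  mobilities and no $\sigma^2/\Delta t$ subtraction is applied; the
  correction is trivial for a caller to apply but keeps the fitted and
  literature values on the same scale when omitted.

## Fitting

`fit_dstar_mixture()` maximizes the mixture log-likelihood on the raw $D^*$
values by EM. Both M-step updates are closed-form: occupancies are mean
responsibilities, and each mobility is the responsibility-weighted mean of
the data (the MLE of a gamma scale at fixed shape). Numerical choices:

* **Multi-start.** Quantile-spaced mobilities with equal occupancies, plus
  nine restarts with log-uniform mobilities on $[0.01, 5]\ \mu m^2/s$ and
  Dirichlet-uniform occupancies; best final likelihood wins, ties to the
  first found. On the three-species reference problem all seeds land on the
  same optimum to $\sim 10^{-4}$.
* **Convergence.** Stop when the log-likelihood improves by less than
  $10^{-8}(1 + |\ell|)$ for three consecutive iterations, or flag
  `converged = FALSE` after 1,000 iterations — never silently.
* **Degenerate inputs.** Exact zeros (perfectly stationary tracks) are
  nudged to machine epsilon so the shape-$n$ density stays finite;
  component weights are floored at $10^{-300}$ inside the M step to avoid
  0/0; fits require at least $10k$ observations.
* **Label switching.** Species are always returned sorted by mobility. With
  very few tracks two components may coalesce onto one mobility; the fit is
  still returned (occupancies then split arbitrarily between the twins).
* **Constrained ("fixed mobility") fit.** `fixed_d` holds the $D_i$ at
  caller-supplied values — typically the free fit of a reference
  condition — and fits occupancies only. This is the natural way to ask
  "did occupancies shift?" without letting mobilities drift between
  conditions. Note that the fixed values must be on the same apparent scale
  as the data: fixing movie-derived data at noise-free mobilities
  misassigns mass.

`immobile_fraction()` defaults to $100 f_1$ (mixture occupancy of the
slowest species). The alternative `method = "threshold"` counts tracks with
$D^* < 0.2\ \mu m^2/s$, reproducing per-track mobility-map coloring; it is
biased wherever species densities straddle the cut-off (the shape-4 gamma
at $D = 0.41$ puts $\sim 18\%$ of its mass below 0.2), so the mixture
estimator is the default. Classification boundaries belong to the *slow*
class because both published cut-offs are strict inequalities.

# The synthetic-data generator

No tracking dataset accompanies the reference analysis, so the simulator is
a first-class module and defines the study conditions used everywhere in
the tests:

| parameter | default | why |
|---|---|---|
| frame interval | 15 ms | acquisition setting of the reference experiment |
| movie length | 10,000 frames | same |
| species mobilities | 0.11 / 0.41 / 1.24 µm²/s | reference three-species fit |
| immobile occupancy | 16 % control, 35 % perturbed | reference conditions |
| survival probability | 0.6 / frame | geometric track lengths, mean $1/(1-0.6)=2.5$ frames |
| localization σ | 35 nm | typical PAmCherry precision; gives the 0.08 µm²/s noise floor consistent with the immobile species |
| cell geometry | spherocylinder, cylinder 2.0 µm, radius 0.45 µm | typical *E. coli*; 2-D because analysis uses projected positions |
| activation density | 0.01 emitters/cell/frame | keeps ≲ 0.03 simultaneously active emitters per cell, so linking is nearly unambiguous |

Slow and fast occupancies are not printed for the perturbed condition in
the reference work, so the generator splits the non-immobile mass evenly —
a choice, recorded here, that matters only for the slow/fast balance, not
for the immobile readout.

Mechanics: each emitter draws a species, a cell, a uniform activation
frame and a geometric lifetime; its true position starts uniformly inside
the spherocylinder and takes per-axis Gaussian steps of standard deviation
$\sqrt{2 D \Delta t}$, mirror-reflected at the boundary (flat wall in the
cylindrical section, radial reflection about the cap centre at the poles,
iterated until inside); reported positions add isotropic Gaussian noise.
`simulate_tracks()` is the desk-scale shortcut: exact-length tracks,
optionally unconfined and noise-free, for which the gamma law is exact —
this is the generator used for mixture-calibration tests and for the
acceptance computations, with species mobilities interpreted as apparent
mobilities.

What the generator deliberately does **not** emulate: photoblinking
(dark-state gaps), motion blur within the exposure, localization-precision
heterogeneity, cell-to-cell expression variability, cell growth or
movement, and 3-D effects beyond projection. Passing tests therefore show
that the *analysis chain* is correct and well-calibrated under its own
model; they cannot certify performance on real movies where those effects
are present.

## Confinement

Inside a 0.45 µm-radius cell the fast species ($\sqrt{4D\Delta t} \approx
0.27$ µm per frame) feels the boundary: mean squared steps shrink below
$4D\Delta t$, so movie-derived fast mobilities are biased down while noise
biases all mobilities up. The tests assert the direction of the
confinement bias (a property of the reflecting geometry), and the
calibration tests that need the exact gamma law use the unconfined
generator.

# Linking

Frame-to-frame **mutual nearest neighbour** assignment with a hard gate
(0.9 µm per frame of separation, about $3\sqrt{4 D_{fast} \Delta t}$):
a pair is linked only if each is the other's closest candidate within the
gate, candidates being same-cell by default. There is no gap closing by
default because the emulated photophysics has no dark state. Ties are
broken towards the lower input row, making linking deterministic. On
sparse two-frame instances the procedure provably coincides with the
exhaustive maximum-cardinality, minimum-cost assignment, and the suite
checks this against a brute-force enumerator.

One failure mode is inherent to the *data* rather than the algorithm: if
one emitter bleaches and another activates within the gate one frame
later, the handover is indistinguishable from a continuation, and any
frame-to-frame linker will chain the two tracks. At the default activation
density this affects roughly 1.5 % of tracks (activation rate × gate area,
counting both track ends); at 5× sparser activation it is negligible and
track recovery exceeds 99 %.

# Replicate statistics

A biological replicate is an independently simulated movie (cells and
emitters resampled). Per-replicate immobile percentages are summarized as
mean ± sample SD, and conditions are compared with the classic
pooled-variance unpaired two-tailed t-test (`compare_groups()`), the
default reading of an "unpaired t test"; a Welch option exists behind
`welch = TRUE`. The degenerate zero-variance cases are defined explicitly
(equal means → $t = 0, p = 1$) rather than erroring. Reproducibility comes
from one master seed: `run_pipeline()` draws all per-replicate child seeds
once, up front, from the master seed.

# Problem sizes used in the checks

The package's calibration checks run at the sizes the analysis is designed
for: 20,000 four-step tracks for mixture recovery (mobilities within
±15 %, occupancies within ±0.03, immobile fraction within ±3 points of
16 % and 35 %), $10^5$ draws for the track-length law and the
Kolmogorov–Smirnov comparison against the gamma form (distance < 0.01),
and 100 seeded 4-vs-4 replicate contrasts at 1,500 tracks per replicate
(with 2 EM starts, ample for this well-separated problem) for the power of
the control-vs-perturbed comparison. The movie-level pipeline demonstration
in the README uses 500 cells × 5,000 frames per replicate,
about 3,200 qualifying tracks.

# Known limitations

* The gamma mixture assumes discrete, non-interconverting species over a
  track's (short) lifetime; state changes within a track are not modelled,
  and no hidden-Markov segmentation is attempted.
* Apparent mobilities conflate diffusion, localization noise and
  confinement; comparisons are meaningful within a consistent acquisition,
  and the fixed-mobility fit should only fix values measured on the same
  apparent scale.
* The threshold estimator of the immobile fraction is systematically
  biased by species overlap (documented above) and is provided for
  comparability with per-track mobility maps, not as the primary readout.
* The geometric track-length model reproduces the observed mean duration
  (2.5 frames) exactly but puts 12.96 % of tracks at ≥ 5 frames where
  roughly 10 % is observed — a documented approximation of the memoryless
  bleaching model.
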