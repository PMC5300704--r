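---
title: "The injection-diffusion model of flagellar growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The injection-diffusion model of flagellar growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A bacterial flagellum grows at its distal tip.  Every flagellin monomer
that extends the filament must first be unfolded and injected at the base
by the type III secretion system, then travel the full length of the
filament through a channel so narrow (~2 nm) that monomers can neither
fold nor pass one another.  For *Vibrio alginolyticus* polar flagella the
measured growth rate is strongly length-dependent: roughly constant near
50 nm/min for filaments shorter than about 1500 nm, then decaying sharply
to ~9 nm/min by 7500 nm.  `flagrowth` implements a stochastic transport
model that reproduces this behaviour and the analysis pipeline used to
confront it with growth-rate measurements.

## The model

The channel is a one-dimensional segment `[0, L]` that elongates as the
filament grows.  Each unfolded monomer is a rod of length `ell = 56 nm`
(estimated from residue count: 74 nm x 379/494 = 56.77 nm, truncated to
the canonical 56 nm).  The model has three parameters:

* `S_load` (attempts/s): the loading rate at the base, fixed at 1.7 Hz —
  the frequency needed to sustain the observed maximal growth rate, since
  each crystallized monomer adds `dL = 5.2/11 = 0.47 nm` (one helical turn
  of 11 subunits rises 5.2 nm) and `1.7 x 0.47 x 60 = 47.9 nm/min`.
* `LS` (dimensionless integer): the loading strength — how many resident
  monomers the secretion apparatus can push forward to clear the first
  56 nm for a new entry.
* `D` (nm^2/s): the apparent diffusion coefficient of a monomer in the
  channel.

Dynamics per time step `dt`:

1. **Loading.**  Attempts occur on a fixed clock every `1/S_load` seconds
   (the first at `t = 1/S_load`); a failed attempt does not delay the
   next.  With a new monomer occupying `[0, ell]`, resident k (counting
   from the base) must sit at `x >= k*ell`; residents short of that are
   pushed to exactly `k*ell` (minimal displacement, order preserved).
   Entry succeeds iff at most `LS` residents need pushing and no pushed
   front edge would pass the tip; otherwise the arriving monomer diffuses
   away and the state is untouched.  With `LS = 0` this reduces exactly
   to "the first 56 nm are empty".
2. **Diffusion.**  Monomers carry no external force in the channel; in
   the overdamped limit each position evolves as a pure Wiener process,
   simulated as `x(t+dt) = x(t) + sqrt(2 D dt) Z`, `Z ~ N(0,1)`.  Each
   monomer is visited once per step in a fresh uniformly random
   permutation, and its move is clipped at contact: it can neither
   overlap either neighbour's current position nor cross the base at
   `x = 0` (monomers never re-enter the cytoplasm).
3. **Crystallization.**  Immediately after its move, a monomer whose
   front edge reaches the tip (`x + ell >= L`) folds onto the filament:
   it leaves the channel and `L` grows by `dL = 0.47 nm`.  Only the
   tip-most monomer can reach the tip, because every other monomer is
   blocked by the one ahead.

The filament length is therefore an exact conservation law,
`L = L0 + 0.47 x n_crystallized`, which the test suite asserts to
machine precision.

### Why the growth rate bends

Below roughly 900 nm essentially every loading attempt succeeds and the
rate sits at the loading-limited ceiling `S_load x dL = 47.9 nm/min`.
As the filament lengthens, the round trip to the tip grows quadratically
with `L` while injections keep arriving at 1.7 Hz, so monomers accumulate
into a queue at the base; once more than `LS` residents block the entry
region, attempts start failing and the rate falls, approaching a
diffusion-limited regime at long lengths.  The model's mean rate over the
whole 400–1500 nm window therefore sits somewhat below both the ceiling
and the 50 nm/min plateau that a measurement extrapolates, because the
jam already builds within that window at the best-fit parameters; the
acceptance script computes exactly this mean.

## Numerical choices

* **Time step.**  `dt = dL^2 / D`, the step over which free diffusion
  moves about one crystallization increment.  The suite re-runs a short
  configuration at `dt/2` and checks that mean rate curves agree within
  replicate scatter.
* **Random numbers.**  The compiled core uses an explicitly seeded
  xoshiro256++ generator with a Marsaglia–Tsang ziggurat normal sampler,
  so traces are bit-reproducible across platforms and independent of R's
  RNG state; every trace records its seed.  Per-replicate seeds derive
  from the user-facing seed via R's RNG, so all entry points honour a
  single `--seed`/`seed` argument.
* **Update order.**  A fresh random permutation per step avoids the net
  transport bias a fixed sweep direction would introduce; collisions are
  resolved by clipping at contact (a partial move), not by rejecting the
  move.
* **Initial condition.**  An empty channel of length `L0 = ell = 56 nm`
  (the channel must be able to hold one monomer).  Growth-rate curves are
  insensitive to this choice beyond the first few samples.
* **Time cap.**  Runs stop at `t_max` (default 1e5 s) if the target
  length is not reached; such traces are flagged `truncated`, and fits
  exclude truncated grid cells from the arg-min (their cost is the NaN
  sentinel in exported contour tables).

## From traces to rate curves

Mirroring the measurement procedure, the instantaneous rate at trace time
`T` is `(L(T+dT) - L(T))/dT` in nm/min, assigned to the midpoint length
`L + dL_segment/2`; the default interval is 5 min (20 min was used for
long filaments experimentally).  On a linear trace every interval returns
the same slope, which the suite asserts exactly.  Simulated curves pool
the points of all replicate traces and smooth them with a running median
of 100 points; because a centred window needs odd length, 100 is widened
to 101, and endpoints use shrinking windows rather than invented padding
(the choice of a centred rather than trailing window is ours — either
reading is defensible).  Median filtering preserves the local range of
the data, which is also asserted.

## Projection geometry

Images record the 2D projection of a helical filament (radius 160 nm,
pitch 1500 nm for this organism).  The 3D arc length is exactly linear in
the axial coordinate, `L3D = sqrt((2 pi r z / c)^2 + z^2)`; the projected
arc length has no closed form and is integrated adaptively (tolerance
1e-8).  The conversion factor is the slope-through-origin least-squares
fit of (L2D, L3D) pairs sampled at 100 points over 0–10 um — through the
origin because both lengths vanish together, and insensitive to the
sampled range because both lengths are exactly additive over whole turns
(the per-turn ratio is the exact answer; the fit reproduces it to
quadrature tolerance).  For the stated helix the slope is 1.09.  The
projection model treats the helix axis as parallel to the imaging plane;
cell-body tilt is not modelled.

## Fitting

The experimental dataset is a table of (length, rate, interval) triples,
one per cell.  For each grid cell (D, LS) the package simulates replicate
traces (default 3), builds the median-filtered model curve, reads it by
linear interpolation at each measured length (nearest-endpoint
extrapolation, with a warning, outside the simulated span) and scores

    E(D, LS) = sum_i (V_i_model - V_i_exp)^2 / (N - 1).

The fit is the arg-min of the surface, ties broken toward smaller D then
smaller LS.  Default grids are the integers 0–25 for LS and 20
log-spaced values of D over 1500–2e5 nm^2/s; the published search range
is exactly this rectangle, but its grid spacing is unstated, so the
20-point logarithmic spacing is our choice.  Model curves do not depend
on the data, so `model_curve_grid()` lets one grid score many datasets —
the test suite uses this to run ten seeded recovery repeats against a
single grid.

## Energetics

With energies in thermal units the Einstein–Smoluchowski drag of one
monomer in the channel is `zeta = kT/D`, so pushing `n` residents a
distance `s` at velocity `v` costs `W = n kT v s / D`.  At the fitted
`D = 5000 nm^2/s`, inserting one monomer past 12 close-packed residents
(each pushed 56 nm) costs 75.3 kT if completed in 0.1 s and 12.5 kT if
spread over the full 0.6-s secretion cycle; the two differ exactly by
the velocity ratio 6.  The ATP conversion (default 20 kT/ATP) is
back-derived from the pair 75.3 kT ≈ 3.77 ATP and is configurable; the
kT figures are primary.  The slow-push velocity is computed as 56/0.6 =
93.33 nm/s rather than a rounded 93 nm/s so the 12.5 kT figure is exact.

## The synthetic-data generator

No deposited measurement tables exist, so the generator emulates the
measurement design: 72 cells at 5-min intervals over 400–2800 nm and 103
cells at 20-min intervals over 1000–7500 nm, one point per cell, lengths
sampled uniformly within each range (the real length distribution is
unstated).  For each cell the model rate is read off a simulated
median-filtered curve at the cell's midpoint length; the two endpoint
lengths implied by that rate are projected to 2D, snapped to the 65-nm
pixel grid, re-projected with the 1.09 factor and differenced; Gaussian
rate noise (default SD 5 nm/min — a stand-in, since the published
scatter is not quantified) is added, and negative noisy rates are
clipped at zero.  Quantization displaces a rate by at most one pixel per
endpoint, i.e. `65 x 1.09 / interval` nm/min.  With noise and
quantization disabled the points lie exactly on the generating curve, so
the cost at the generating parameters is exactly zero — the anchor of
the parameter-recovery tests.

What the generator deliberately does not emulate: cell-to-cell parameter
heterogeneity (a single parameter set generates every cell, as the
published fit assumes), correlated errors from contour tracing, surface
attachment artefacts, or photobleaching-limited trace lengths.  Passing
recovery tests therefore show the pipeline is consistent and invertible
under the model's own assumptions, not that those assumptions hold for
any particular microscope.

## Problem sizes used by the test suite

Simulating to 7500 nm at the best-fit parameters takes hours of CPU, so
the suite exercises the documented behaviours at reduced scale, chosen
so every check still discriminates: plateau checks run 3 replicates to
1600 nm; the decay check runs two replicates to 4200 nm and asserts
monotone decline with rate < 20 nm/min at 4000 nm; the limit checks run
LS = 0, D = 2500 nm^2/s (collapse toward zero rate at short lengths) and
D = 2e5 nm^2/s (loading-limited constant rate); parameter recovery uses
a 3 x 3 grid {2500, 5000, 10000} x {6, 12, 25} containing the truth,
datasets of 60 cells over 400–2200 nm at noise SD 5 nm/min, 3 replicate
curves per cell (the ten seeded repeats redraw cells, noise and
quantization against one independently simulated generating curve), and
requires at least 9 of 10 repeats to recover (5000, 12).  Structural
unit tests use coarser `dt` than `dL^2/D`, which changes numerical
accuracy but none of the exercised logic.

## Known limitations

* The entry rule is a formalization of a verbal description; we chose
  the minimal-displacement reading (push each blocking resident exactly
  to its packed position, fail if more than `LS` must move or any would
  pass the tip).  Other readings are conceivable and would shift where
  the rate curve bends.
* The loading clock is strictly periodic by default (a Poisson-arrival
  mode with the same mean rate exists for sensitivity checks), and a
  failed attempt never delays the next.
* The channel length equals the filament length: no hook/rod offset
  below the filament is modelled.
* No external force acts on monomers inside the channel (the push acts
  only at entry), and no monomer–monomer interactions exist beyond
  hard-core exclusion.
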