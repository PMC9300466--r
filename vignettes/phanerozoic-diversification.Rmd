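---
title: "Modelling Phanerozoic marine diversification on drifting seafloor habitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Phanerozoic marine diversification on drifting seafloor habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phanerodiv)
```

## The model

`phanerodiv` simulates the growth of marine invertebrate genus richness on a
set of Lagrangian seafloor points over Phanerozoic time scales and converts
the resulting regional diversity maps into a global diversity curve. Each
tracked point is either oceanic crust — born at a mid-ocean ridge, drifting
away, and ultimately lost to subduction — or a fixed continental point that
alternates between flooded-shelf and emergent stints as sea level and
topography change. Diversity accumulates only while a point is under water,
so habitat lifespan ("time-for-speciation") is a first-order control on the
richness a region can reach.

Regional diversity $D$ (genera per point, later per grid cell) evolves
under a per-capita net diversification rate $\rho$ that depends on the
local environment:

$$\rho = \rho_{\max} - (\rho_{\max} - \rho_{\min})\,(1 - Q_{\mathrm{temp}}\,Q_{\mathrm{food}})$$

with a temperature term normalized to the warm end of the per-slice
temperature envelope,

$$Q_{\mathrm{temp}} = \frac{Q_{10}^{(T - T_{\min})/10}}{Q_{10}^{(T_{\max} - T_{\min})/10}},$$

and a Michaelis–Menten food term driven by the particulate organic carbon
(POC) export flux reaching the seafloor,

$$Q_{\mathrm{food}} = \frac{\mathrm{POC}}{K_{\mathrm{food}} + \mathrm{POC}}.$$

Two growth laws are supported. The logistic model
$\partial D/\partial t = \rho D (1 - D/K_{\mathrm{eff}})$ bounds richness
by an effective carrying capacity that increases linearly with food supply
between $K_{\min}$ and $K_{\max}$ (anchored at the 0.01 and 0.99 quantiles
of the whole-run POC distribution); the exponential model
$\partial D/\partial t = \rho D$ is its unbounded limit. Mass extinctions
are imposed as external forcing: over an event of duration $\Delta t$
removing a fraction $f$ of diversity, every active point decays at the
imputed constant rate $\ln(1 - f)/\Delta t$, a non-selective
"field of bullets" kill rule.

Default parameters are the calibrated set of the full-scale analysis:
$\rho \in [0.001, 0.035]\ \mathrm{Myr^{-1}}$, $Q_{10} = 1.75$,
$K_{\mathrm{food}} = 0.5\ \mathrm{mol\,C\,m^{-2}\,yr^{-1}}$ and
$K_{\min}$–$K_{\max}$ of 12–123 genera per cell.

## Coupling rules

All active points start from a single genus ($D_0 = 1$) at the oldest
slice. Between slices the environment (hence $\rho$ and
$K_{\mathrm{eff}}$) is held constant and time advances in substeps of
`ode_step` (default 1 Myr). Arrival in an environment with
$K_{\mathrm{eff}} < D$ resets $D$ to $K_{\mathrm{eff}}$ (local
extinction). Continental points that emerge have $D$ set to 0; when they
re-flood they are seeded with the diversity of the nearest flooded
continental point with $D > 1$ (great-circle distance, ties broken by
lowest point id), emulating coastal recolonization, or with 1 if no such
neighbour exists. Subducted points disappear and their diversity is lost;
ridge-born points start at $D = 1$, the trough level.

### Integration scheme

Within a substep the coefficients are frozen, so both growth laws have
closed-form solutions; the engine advances each substep with those exact
solutions (an exponential-integrator scheme) rather than a forward Euler
increment. The only discretization left is the environmental lag itself,
which is the quantity the 1 Myr substep is meant to represent. This choice
keeps constant-environment trajectories on the analytic logistic and
exponential curves to machine precision — forward Euler at 1 Myr would
drift by 4–6% over 100 Myr at $\rho = 0.035$, an error of pure numerics
with no scientific content. The elementary Euler steps remain available as
`step_logistic()` / `step_exponential()` for didactic use and convergence
tests. Extinction forcing *replaces* the environmental dynamics during an
event window (no logistic term while the killing field is active), so a
scheduled 90% loss multiplies every surviving point's diversity by exactly
0.1; survivors are floored at one genus, the definition of a trough, since
a genus count below 1 is not meaningful.

## From regional maps to a global curve

Because the simulation tracks no taxonomic identities, summing cell
richnesses would overcount shared genera. The package instead integrates
diversity along peak-to-trough transects with a distance decay of
taxonomic similarity:

1. **Rasterize** point diversities onto the annotated grid, interpolating
   ocean and shelf points independently (a shelf cell is never filled from
   ocean points and vice versa; co-located points average).
2. **Peaks** are local maxima over the 8-neighbourhood (longitude wraps)
   whose value exceeds the 0.75 quantile of all local-maximum values; a
   flat plateau contributes its middle cell. If the threshold would retain
   nothing (a map with a single local maximum), the global argmax is kept.
3. **Troughs** are newly formed ocean cells (seafloor age 0), whose
   diversity is one genus by construction.
4. **Transects** run from each peak to its nearest trough along Bresenham
   cells in index space (shorter arc across the antimeridian), are
   rejected if more than 20% of their cells are continental, and keep the
   peak-side prefix up to 555 km (5° at the equator). Unpopulated path
   cells contribute a trough-level background of 1.
5. **Within a transect**, the Jaccard similarity implied by each per-step
   great-circle distance, $J = J_{\mathrm{off}} + (J_{\max} -
   J_{\mathrm{off}})e^{-\lambda d}$ (defaults 0.06, 1.0, 0.0024 km$^{-1}$),
   is converted to a Simpson overlap $V = (1+R)J/(1+J)$ with
   $R$ the richness ratio of the two cells, recomputed with $R = 1$
   whenever the conversion exceeds 1. The transect diversity is
   $\gamma = \alpha_1 + \sum_n (1 - V_{n,n+1})\,\alpha_{n+1}$ — each cell
   adds only its unshared fraction. For descending $\alpha$ and integer
   overlaps this is exactly the cardinality of the union of communities
   satisfying the pairwise overlaps and the nesting assumption, which the
   test suite verifies on hundreds of random set constructions.
6. **Across transects**, a zigzag accumulation sorts transects by
   descending $\gamma$ and discounts each by the overlap implied by the
   distance between its peak and the nearest already-integrated peak, with
   $R$ the ratio of the two transect diversities. Coincident peaks are
   absorbed entirely, which makes the total invariant to duplicated
   transects.

Slices without populated cells, troughs or accepted transects are flagged
as gaps rather than zeros.

## Calibration

Model curves are compared with a reference curve (e.g. a fossil richness
series) by min–max normalizing both series, aligning the reference to the
model ages by linear interpolation, and computing Lin's concordance
correlation coefficient with population (n-divisor) moments. The CCC is
evaluated on the concatenation of inter-extinction *rising segments* —
the closed age intervals from each event's end to the next event's start —
so the forced drops themselves do not inflate the fit. Serial correlation
is deliberately ignored: the comparison targets long-term trends, not
high-frequency structure. `k_bounds_grid_search()` enumerates the 28 pairs
$K_{\min} < K_{\max}$ from the base-2 sequence 2–256, runs the full
logistic pipeline for each, and `calibrate_bounds()` averages all pairs
with CCC > 0.70. On a self-generated reference the search recovers the
generating pair exactly (CCC = 1), the package's parameter-recovery check.

## The synthetic world generator

The generator supplies worlds with the statistical structure the analysis
assumes, not reconstructions of real paleogeography:

- **Continental points** never move (drift is irrelevant to the engine's
  mathematics); they alternate flooded/emergent stints with geometric
  lengths (defaults: mean 6 and 4 slices), a stationary renewal process
  standing in for sea-level cycles.
- **Ocean points** are born on a ridge meridian and drift away at
  `drift_speed` (default 0.5°/Myr, ≈55 km/Myr, within the observed range
  of plate speeds), dying by random subduction (3%/slice) or on reaching
  170° from the ridge. The initial cohort carries the pre-run age implied
  by its ridge distance so every slice has a realistic seafloor-age
  spectrum; a ridge cohort with age 0 exists from the first slice onward,
  guaranteeing troughs.
- **Environment**: temperature follows
  $T(\phi) = T_{\mathrm{pole}} + (T_{\mathrm{eq}} -
  T_{\mathrm{pole}})\cos\phi$ (defaults 28 to −2 °C) plus cell-level
  Gaussian noise; POC flux is lognormal around class means of 2 (shelf)
  and 0.1 (ocean) mol C m⁻² yr⁻¹, so food limitation separates habitats
  the way export flux does in the real ocean. Fields are sampled per cell,
  so co-located points of the same class see identical values.
- **Grids** are annotated with priority flooded-shelf > ocean >
  continental within a cell, which guarantees every flooded point lies in
  a shelf-annotated cell; empty cells default to ocean.
- One seeded random stream is consumed in a fixed, documented order, so a
  configuration and seed identify a world bit for bit.

What the generator does *not* emulate: coherent plate motions and
continental assembly/fragmentation cycles, coastline geometry, enclosed
seas, climate dynamics (no greenhouse transitions, no ocean circulation),
spatially correlated flooding, or provinciality structure in the decay of
similarity. Passing tests therefore demonstrate the correctness of the
machinery and its stated invariants on worlds with the assumed statistical
structure — not that the model reproduces the fossil record.

## Numerical choices and degenerate inputs

- Empirical quantiles use R's default type-7 interpolation everywhere
  (envelopes, peak thresholds, map normalization).
- Great-circle distances are haversine on a 6371 km sphere
  (via `geosphere`).
- Degenerate temperature envelope ($T_{\min} = T_{\max}$):
  $Q_{\mathrm{temp}} = 1$. Degenerate POC envelope: $K_{\mathrm{eff}} =
  K_{\max}$.
- Ties: nearest troughs by smallest cell index; equal-$\gamma$ transects
  by peak cell index; recolonization donors by lowest point id.
- A constant series cannot be min–max normalized and raises an error
  rather than returning NaN.
- Transect integration applies the accumulation rule literally even where
  $\alpha$ is locally non-monotone along the path; cells are not
  re-sorted.

## Problem sizes

The test suite and the bundled examples run on deliberately small worlds,
chosen as the smallest sizes at which every code path is exercised: 16–30
slices at 5 Myr spacing with 90–230 point trajectories on 4–15° grids for
pipeline tests, a 24-slice, 541 Myr world on a 4° grid with ~370
trajectories for the carrying-capacity recovery check, and 0.5° grids only
for single-slice geometry tests. The full-scale configuration of the
original analysis (82 slices, 0.5° grids, ~50,000 active points) is the
generator's documented default and runs in minutes rather than seconds.

## Limitations

Beyond the generator simplifications above: extinction forcing is
non-selective and replaces (rather than adds to) environmental dynamics,
so explosive post-extinction radiations are outside the model; oxygen is
not a limiting resource; a single distance-decay function is used for all
times and places; and the 555 km truncation measures great-circle length
along the traced cells, one of several defensible readings of a "5°"
cut. These mirror the stated scope of the modelling framework the package
implements.
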