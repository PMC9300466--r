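# phanerodiv

Spatially explicit diversification modelling of marine invertebrate genus
richness over Phanerozoic time scales.

Whether global marine diversity has grown toward an ecological ceiling or
expanded largely unchecked is a long-standing question in macroevolution.
`phanerodiv` is for researchers who want to explore that question with a
mechanistic, spatially resolved model: genus richness accumulates on
individual seafloor habitats — drifting oceanic crust and flooding/emerging
continental shelves — under environmental control, is knocked down by mass
extinctions, and is then aggregated into a global diversity curve the way a
taxonomically blind simulation must be: by integrating along transects with
a distance decay of taxonomic similarity.

## The model in brief

Each active seafloor point carries a genus count `D` with net per-capita
diversification rate

    rho = rho_max − (rho_max − rho_min) (1 − Q_temp · Q_food)

where `Q_temp = Q10^((T − T_min)/10) / Q10^((T_max − T_min)/10)` is a
Q10-type temperature sensitivity normalized to the per-slice temperature
envelope, and `Q_food = POC / (K_food + POC)` is Michaelis–Menten
saturation of the particulate organic carbon export flux. Growth follows
either the logistic law `dD/dt = rho D (1 − D/K_eff)`, with the effective
carrying capacity `K_eff` a linear function of POC flux between `K_min`
and `K_max`, or its unbounded exponential limit `dD/dt = rho D`. Mass
extinctions impose a constant negative rate `ln(1 − loss)/duration` on all
active points (non-selective, "field of bullets").

Regional maps are reduced to a global estimate per time slice by tracing
transects from diversity peaks to the nearest newly formed ocean cells
(troughs), accumulating `gamma = alpha_1 + sum (1 − V) alpha_n` with the
Simpson overlap `V` derived from the fitted Jaccard distance decay
`J = 0.06 + 0.94 exp(−0.0024 d)`, and then zigzag-integrating the
transects themselves. Carrying-capacity bounds are calibrated against a
reference curve with Lin's concordance correlation coefficient on
inter-extinction rising segments.

Default parameters are the calibrated set: `rho` in 0.001–0.035 Myr⁻¹,
`Q10 = 1.75`, `K_food = 0.5` mol C m⁻² yr⁻¹, `K_min`–`K_max` 12–123
genera per cell.

## Worked example

A 541 Myr run on a synthetic world with five scheduled mass extinctions:

```r
library(phanerodiv)

cfg <- world_config(n_slices = 24, start_age = 541, grid_resolution = 4,
                    n_continental_points = 60, n_ocean_points = 140,
                    ridge_birth_rate = 0.05, subduction_rate = 0.04,
                    seed = 101)
world <- build_world(cfg)

schedule <- make_extinction_schedule(data.frame(
  start_age     = c(445, 372, 252, 201, 66),   # Ma
  duration      = c(5, 10, 5, 5, 2),           # Myr
  loss_fraction = c(0.6, 0.5, 0.85, 0.5, 0.65)))

history <- simulate_diversity(world, model_params(), schedule)
curve <- global_diversity_curve(history, world)
tail(as.data.frame(curve)[, c("age_ma", "gamma_total", "n_transects")], 6)
#>    age_ma gamma_total n_transects
#> 19 117.61       541.5          25
#> 20  94.09       755.4          25
#> 21  70.57       985.2          26
#> 22  47.04       456.7          25
#> 23  23.52       546.0          24
#> 24   0.00       972.2          27
```

`gamma_total` is the global genus richness integrated from that slice's
transects (`n_transects` of them). The drop from 985 to 457 genera across
66 Ma is the scheduled end-Cretaceous-style loss; the recovery afterwards
is re-diversification under the same environmental control. How close the
shelf biota sits to its ecological ceiling at the present-day slice:

```r
sat <- saturation_ratio_map(history, world, slice = 24)
area_weighted_histogram(sat, class = "flooded_shelf")
#>   bin_lo bin_hi  pct
#> 1   0.00   0.25 16.5
#> 2   0.25   0.50 28.7
#> 3   0.50   1.00 54.8
```

Area percentages of the diversity-to-`K_eff` ratio on flooded shelves: on
this small synthetic world, long-lived shelves under constant high food
supply saturate far more than the real, tectonically reworked shelves
would. Calibration against a reference curve runs
`k_bounds_grid_search(world, model_params(), schedule, reference)` over
the 28 base-2 pairs of `(K_min, K_max)` and averages the pairs with
CCC > 0.70 via `calibrate_bounds()`.

A thin command-line dispatcher over the same functions is installed at
`inst/scripts/phanerodiv` (subcommands `world`, `simulate`, `integrate`,
`calibrate`).

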