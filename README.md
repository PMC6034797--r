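# herringmse

Food-web modelling and closed-loop management strategy evaluation (MSE)
for Pacific herring fisheries.

Pacific herring is a forage fish: an energy conduit from zooplankton to
piscivorous fish, marine mammals and seabirds, and at the same time the
target of roe and spawn-on-kelp fisheries. Whether a harvest control rule
that looks safe from a single-species standpoint is also safe for the
predators that depend on herring is an ecosystem question, and answering
it requires simulating the assessment–decision–fishery–food-web loop, not
just the stock. `herringmse` provides that chain for researchers and
analysts working on ecosystem-based forage-fish management:

1. **Static mass balance** (`solve_mass_balance`) — for every functional
   group *i*, production retained in the system equals predation plus
   catch: *B·(P/B)·EE = Σⱼ Bⱼ·(Q/B)ⱼ·DCᵢⱼ + Y + BA*, with unknown *B* or
   *EE* solved jointly, trophic levels from the diet fixed point, and a
   predator-rebalancing procedure for infeasible webs.
2. **Trophic dynamics** (`run_dynamics`) — foraging-arena consumption
   *Q = a·v·Bᵢ·Bⱼ / (2v + a·Bⱼ)* calibrated so the balanced web is the
   exact dynamic equilibrium; juvenile/adult herring pools linked by
   Beverton–Holt recruitment; producer forcing for climate anomalies;
   unfished biomass **B₀** (`equilibrium_b0`) and single-species vs
   ecosystem **FMSY** (`estimate_fmsy`).
3. **Closed-loop MSE** (`run_closed_loop`, `build_scenarios`) — annual
   stock assessment with CV = 0.3 error on adult herring, constant / step /
   hockey-stick harvest control rules on reference points B_lim and
   B_Ftarget (fractions of B₀), quota-based fishing, climate-regime
   resampling, 100 runs × 100 years with common random numbers across
   scenarios.
4. **Metrics** (`metrics_report`) — grand-mean biomass changes against the
   unfished baseline, the μ − 0.675σ risk statistic (lower quartile of
   run outcomes), closure and collapse probabilities, mean trophic level,
   Shannon–Wiener H′, and catch summaries.
5. **Synthetic reference web** (`generate_reference_web`) — a packaged,
   seed-deterministic 18-group herring-centric Northeast Pacific shelf web
   (herring at trophic level 3.14, four predators with ≥ 20 % herring
   diets, planktivorous competitors, roe/SOK/groundfish fleets) so every
   analysis is reproducible without external data.

## Worked example

Evaluate the British Columbia step rule (B_lim = 0.25 B₀,
F_target = 0.2) against an unfished baseline:

```r
library(herringmse)

web <- generate_reference_web()
b0  <- equilibrium_b0(web)
sprintf("B0 = %.2f t/km^2 (adult share %.2f)", b0, attr(b0, "adult_share"))
#> "B0 = 3.66 t/km^2 (adult share 0.89)"

series <- generate_productivity_series()
scens  <- build_scenarios(codes = c("Base", "BC"), f_targets = 0.2,
                          n_runs = 100, years = 100, seed = 1)
grid   <- run_scenario_grid(web, scenarios = scens, series = series, b0 = b0)
metrics_report(grid$BC_0.2, grid$Base, web)
#> metrics for scenario 'BC_0.2' vs baseline
#>   p(closure) = 0.023  p(collapse) = 0.000
#>   herring catch: mean 0.4878 (+/- 0.0032), max 1.7848 t/km^2/yr
#>   MTL 2.1287 (-0.42%)  H' 1.9036 (-0.96%)
#>             group grand_mean_pct risk_pct ci2se_pct
#>     phytoplankton           -0.1     -1.9      0.51
#>       euphausiids            1.7     -0.6      0.68
#>  juvenile herring           -8.0     -9.1      0.33
#>     adult herring          -25.1    -26.6      0.43
#>              hake           -9.6    -13.2      1.07
#>             seals           -8.8    -11.6      0.82
#>          dolphins           -9.7    -12.5      0.80
#>   humpback whales           -6.2     -8.6      0.73
#>   transient orcas           -6.4     -9.3      0.87
#>   ...
```

Reading the output: under the BC rule the fishery closes in 2.3 % of
fishery-years and the stock never collapses, but adult herring averages
25 % below its unfished level, and the predators that take ≥ 20 % of
their diet as herring (hake, seals, dolphins, humpback whales) sit 6–10 %
below baseline — several percent lower again at the μ − 0.675σ risk
quantile, which folds in assessment error and low-productivity years.
Planktivorous competitors (euphausiid feeders) gain slightly. Food-web
structure barely moves (MTL −0.4 %, H′ −1 %).

Other entry points: `run_dynamics(web, F_schedule = ...)` for open-loop
projections (e.g. the F = 2.4 collapse experiment), `estimate_fmsy(web,
mode = "ecosystem")` for yield curves, `perturb_web(web, seed, 0.1)` for
parameter-uncertainty variants, and `write_web_csv` / `read_web_csv` /
`write_ensemble_csv` / `write_manifest` for file exchange. A thin
command-line wrapper over these functions ships in
`inst/scripts/herringmse.R`.

## Documentation

The methods vignette (`vignettes/herring-foodweb-mse.Rmd`) describes the
mass-balance and foraging-arena equations, the stanza calibration, the
MSE loop, the metrics, the synthetic-web design and its limitations, and
every numerical choice (integration scheme, tolerances, tie-breaks,
seeds). Function-level documentation lives in the roxygen comments in
`R/`.
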