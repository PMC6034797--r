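---
title: "Trophic dynamics and management strategy evaluation for Pacific herring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic dynamics and management strategy evaluation for Pacific herring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herringmse)
```

`herringmse` implements a complete simulation chain for evaluating herring
harvest strategies in a food-web context: a static mass-balanced trophic
model, a dynamic projection with foraging-arena functional responses, a
closed-loop management strategy evaluation (MSE) with stochastic
stock-assessment error, and the risk and ecosystem-structure metrics used
to compare strategies.  This vignette explains the models, their
assumptions, the tunable parameters, and the numerical choices, in that
order.

## The static mass balance

Each functional group $i$ (a species or aggregate treated as one node) is
described by biomass $B_i$ (t/km^2^), production rate $P/B_i$ (/yr),
consumption rate $Q/B_i$ (/yr), and ecotrophic efficiency $EE_i$, the
fraction of production consumed by predators, caught or accumulated.  The
balance for every living group is

$$B_i \, (P/B)_i \, EE_i \;=\; \sum_j B_j \, (Q/B)_j \, DC_{ij} + Y_i + BA_i,$$

where $DC_{ij}$ is the fraction of predator $j$'s diet made up of prey
$i$, $Y_i$ the fishery landings and $BA_i$ a biomass accumulation term
(zero by default).  Per group at most one of $\{B_i, EE_i\}$ may be left
unknown; `solve_mass_balance()` solves the induced linear system jointly
and refuses (with a named report, never a silent clip) any solution with
$EE \notin [0, 1]$.  Detritus is a passive pool receiving egestion
($GS_j \cdot Q_j$) and non-predation deaths; its implied $EE$ is reported
but unconstrained, a simplification justified because none of the
evaluated dynamics propagate appreciably below the trophic level of
herring.  Imported diet is supported (treated as trophic level 1 by
default) and zero in the packaged web.

Trophic levels solve $TL_j = 1 + \sum_i DC_{ij} TL_i$ with producers and
detritus anchored at 1.  `rebalance_predators()` reproduces the standard
workflow step in which predator biomasses are lowered to the largest
values compatible with $EE \le 1$ after a reduction in prey biomass: a
proportional scale-down of all adjustable groups to joint feasibility
(shared prey constraints bind symmetrically), followed by per-group
bisection back up towards the bounds so the result is maximal.

## Herring age structure

Herring is split into juvenile and adult pools linked by Beverton-Holt
recruitment $R(S) = \alpha S / (1 + S/\beta)$ (spawners $S$ = adult
biomass) and maturation at rate $1/\tau$ with transition age $\tau = 1$
yr.  Both flows are calibrated so the balanced web is an exact dynamic
equilibrium: baseline recruitment equals baseline maturation outflow, and
an adult turnover term returns the maturation inflow.  Because no
steepness estimate is available for the modelled stocks, $\beta$ is set
so that baseline spawner biomass sits at 50% of the recruitment asymptote
(overridable through `stanza_link()`); $\alpha$ then follows from the
calibration contract.  The curve has the high steepness near the origin
characteristic of forage fish: $dR/dS|_0 = \alpha > R(S)/S$ for all
$S > 0$.

## Dynamic projection

Per trophic link, consumption follows the foraging-arena form

$$Q_{ij}(B_i, B_j) = \frac{a_{ij} v_{ij} B_i B_j}{2 v_{ij} + a_{ij} B_j},$$

with the exchange rate $v_{ij}$ and search rate $a_{ij}$ solved per link
from two conditions: the flow equals the Ecopath baseline flow at
baseline biomasses, and predation mortality $Q_{ij}/B_i$ saturates at
`vul` times its baseline value as predator biomass grows.  The
vulnerability multiplier defaults to 2 on every link — the conventional
mixed trophic control setting — and `vul = 1` is handled exactly as the
donor-control limit $Q = v B_i$.  Producers get saturating production
$P(B) = f(t)\, r B / (1 + h B)$ with $r = 2 (P/B)$ and $h = 1/B^0$, so
baseline production is reproduced, production saturates at twice baseline,
and the implied carrying capacity is finite; the forcing multiplier
$f(t)$ carries the phytoplankton anomaly.

Integration is exponential-Euler on per-capita rates,
$B \leftarrow B \exp(\rho\, dt)$ with $\rho = (dB/dt)/B$, at a monthly
default step.  This scheme is positivity-preserving and exactly
stationary at the calibrated equilibrium (baseline runs drift by
$<10^{-12}$ over a century).  Plankton turnover (tens per year) is faster
than a monthly step can follow, so each step subdivides adaptively until
no group loses more than about 70% of itself per substep; halving the
outer step changes century-scale herring biomass by well under 0.5%.
Biomass is floored at $10^{-6}$ of baseline, and collapse runs floor and
continue rather than aborting.  The whole integrator advances a matrix of
states at once, which is what keeps 100-run Monte Carlo ensembles and
whole FMSY grids fast in pure R.

Reference quantities derived from the dynamics:

* `equilibrium_b0()`: unfished herring biomass $B_0$, total
  (adult + juvenile) herring after 1000 years with herring fleets off and
  other fleets at baseline, with a convergence warning if the final
  century still oscillates by more than 1%.
* `estimate_fmsy()`: equilibrium yield over an F grid (resolution 0.02 by
  default), in single-species mode (all non-herring groups pinned at
  baseline) and ecosystem mode (full dynamics).  On the packaged web the
  ecosystem estimate exceeds the single-species one because predator
  depletion relaxes herring predation mortality.

## The closed MSE loop

Each simulated year, in order: the phytoplankton anomaly is resampled
from the scenario's regime pool; adult herring biomass is assessed with
error; the harvest control rule turns the estimate into a decided F; the
quota (decided F times *estimated* biomass) is fixed for the year; and
the web advances twelve monthly steps under the realized F (quota over
*true* biomass, capped at 2.4).  Overestimates therefore translate
directly into realized F above the decided F — the mechanism by which
assessment error creates depletion risk.  Assessment error is normal with
CV 0.3 on adult herring (all other groups assessed exactly), truncated at
zero through the inverse CDF, which is distribution-identical to
redrawing negative values but consumes exactly one uniform deviate per
year and so preserves common random numbers.

Three rule shapes are supported: constant ($F_{target}$ always), step
(closed below $B_{lim}$), and hockey-stick (closed below $B_{lim}$,
linear ramp reaching $F_{target}$ at $B_{Ftarget}$).  Reference points
are fractions of $B_0$.  Because the error model applies to adult herring
while $B_0$ is total herring, the rule compares the assessed adult
biomass against reference points scaled by the adult share of $B_0$
(about 0.89 at the unfished equilibrium of the packaged web); this
convention is a package decision where either reading was defensible, and
the conversion constant is recorded in run manifests.  Assessment happens
at the start of the year and the quota holds for the year.

Ensembles run 100 repetitions of 100 years.  Sub-seeds depend only on the
master seed and the run index — never on the scenario — and all uniform
deviates are drawn up-front in fixed order, so paired scenarios see
identical forcing and error histories (common random numbers), which is
what makes small between-strategy differences detectable.  The scenario
grid (`build_scenarios()`) spans: no fishery (Base); spawn-on-kelp only
at the incidental mortality F = 0.01 (SOK, a non-capture egg fishery);
constant F at 0.1/0.2 (K); step rules at $B_{lim} = 0.25 B_0$ (BC, the
British Columbia rule) and $0.40 B_0$ (LF1); hockey rules with
$B_{Ftarget} = 0.95 B_0$ (LF2/LF3); step rules at the two MSY estimates
(F = 0.4 and 0.6, MSYs/MSYe, each at both $B_{lim}$ values); and the BC
rule under truncated climate regimes (BC075: anomalies strictly below the
75th percentile; BC025: below the 25th), using linear-interpolation
sample quantiles (a convention that must be pinned for reproducibility;
with the integer series lengths involved, the only consequential choice
is the strict inequality).

## Metrics

Grand means average over all run-years; percentage changes are against
the paired unfished Base ensemble.  The risk statistic
$\mu - 0.675\sigma$ takes $\sigma$ across per-run means (between-run
variability), so it is the lower quartile of scenario outcomes under
normality ($\Phi(-0.675) = 0.25$); it can never exceed the grand-mean
change.  Closure probability is closed fishery-years over total
fishery-years (per-run variants are also emitted, the per-year figure is
primary; the denominator convention is a package decision).  Collapse is
a run-year with total herring below $0.05 B_0$.  Mean trophic level is
biomass-weighted over living groups — the indicator describes the food
web, not the catch, though a catch-weighted variant is available — and
$H'$ is the Shannon-Wiener entropy of biomass proportions.  Confidence
intervals are $\pm 2$ standard errors of per-run means.

## The synthetic reference web

The packaged generator (`generate_reference_web()`) emulates the
statistical structure of a herring-centric Northeast Pacific shelf web at
desk scale: 17 living groups plus detritus, adult herring at trophic
level 3.14 (pinned through the fixed plankton and herring diet columns),
four predators — hake, seals, dolphins, humpback whales — taking at least
20% of their diet as herring, planktivorous competitors (other forage
fish, pollock, sei whales) sharing euphausiid prey, an apex predator
(transient orcas), and roe, spawn-on-kelp and groundfish fleets with
baseline herring F of 0.2.  Template rates sit in the ranges typical of
temperate shelf mass-balance models, with biomasses spread evenly enough
that the diversity index is not dominated by one or two pools; the
template was fixed so that the web balances with headroom
(all $EE \lesssim 0.93$), its dynamic equilibrium is stable, sustained
F = 2.4 collapses herring while strategies below FMSY are sustainable,
and the ecosystem/single-species MSY ordering holds — i.e. so that the
synthetic system behaves like the ecosystem it stands in for.  A seeded
3% lognormal jitter on non-pinned parameters (with diet renormalization
and constraint re-checks under bounded retries) makes each seed a
distinct but structurally equivalent web.  Unfished $B_0$ is about
3.7 t/km^2^, a few t/km^2^ as observed for such stocks.

The phytoplankton anomaly series is 51 i.i.d. lognormal annual
multipliers (a 1950--2000-like record), mean-corrected to exactly 1 so
baseline calibration is preserved, with CV 0.25 — interannual variability
strong enough that low-productivity draws are consequential, as chosen
once for all analyses; an AR(1) flag exists but independent years are the
default because the evaluation design resamples years independently.
Whale-recovery forcing is a logistic biomass ramp on the whale groups
with an on/off toggle; it defaults to off in MSE runs so the Base
ensemble remains at its calibrated equilibrium and paired comparisons
isolate fishery effects.

What the generator does *not* emulate: the taxonomic resolution of a full
regional model (~50 groups), observed diet or catch proportions beyond
the stated inequality constraints, seasonal dynamics, spatial structure,
or age structure in non-herring fish; seabird and eulachon treatment is
deliberately coarse.  Tests passing on this web therefore demonstrate
properties of the method and of webs with this trophic architecture, not
numerical predictions for any real region.

`perturb_web()` supports robustness suites: 10% lognormal jitter on
biomasses and rates with every EE re-solved and unbalanced candidates
rejected.  The qualitative strategy ordering (hockey at least as
conservative as step, step as constant) holds on at least 80% of such
variants.

## Problem sizes and runtimes

The packaged analyses use the full evaluation sizes: 100 runs by 100
years per scenario, a 1000-year unfished run for $B_0$, FMSY grids at
0.02 resolution, and 20 perturbed webs for the robustness suite.  On one
CPU the full scenario grid takes about a minute and the complete test
suite a few minutes.

## Known limitations

* The two-pool stanza is a reduced form of full multi-stanza age
  bookkeeping; it reproduces the recruitment-mediated coupling that
  drives the evaluated results but not within-stanza size structure.
* A single smooth Beverton-Holt curve cannot be simultaneously very
  compensatory near baseline and weakly compensatory near zero; the
  packaged calibration (baseline at half the asymptote) is a middle
  course, and stanza parameters are user-overridable.
* Quota removal uses linear $F \cdot B$ with a cap of 2.4 rather than the
  Baranov catch equation; the difference is second-order at the fishing
  mortalities evaluated ($F \le 0.6$).
* Detritus is passive and non-consumptive behavioural (fear-mediated)
  effects are unmodelled.
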