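---
title: "Transpiration-driven nutrient mass balance: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transpiration-driven nutrient mass balance: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertimass)
library(dplyr)
```

## The problem

In containerized fertigation (hydroponic or soilless substrate culture),
nutrient delivery is usually recipe-driven: a fixed solution is supplied
regardless of what the crop actually removes. A mass-balance view instead
treats the plant as a flow system: elements enter dissolved in the water the
plant transpires, and essentially all absorbed element mass is retained in
tissue. Two complementary measurements then constrain uptake:

1. **Solution depletion** — how much an element's concentration drops in the
   root-zone solution over a known uptake interval, relative to the water
   transpired; and
2. **Tissue accumulation** — how much element mass ends up in harvested
   organs, relative to total water use.

`fertimass` implements both sides for vegetative-phase cannabis-type trials
(two cultivars, replicated containers, gravimetric balances, repeated
pour-through sampling), plus the statistics used to compare them, and a
synthetic trial generator that makes the whole pipeline testable without any
external data.

## Core model

Three quantities connect tissue chemistry to fertigation recipes:

* **Water-use efficiency** (`compute_wue()`):
  $\mathrm{WUE} = M_{dry} / V_{irrigation}$, g dry biomass per litre
  transpired over the phase. $V_{irrigation}$ comes from the gravimetric
  record; $M_{dry}$ from harvest.
* **Predicted input concentration** (`predict_input()`):
  $C_{input} = C_{tissue} \times \mathrm{WUE}$ (mg L$^{-1}$), applied
  element-wise. The intuition: if a gram of biomass requires $C_{tissue}$ mg
  of the element and costs $1/\mathrm{WUE}$ litres of transpired water, the
  water stream must carry $C_{tissue}\cdot\mathrm{WUE}$ mg per litre.
* **Organ biomass-weighted mean** (`biomass_weighted_mean()`):
  $C_{weighted} = \sum_o C_o \, B_o / B_{total}$, aggregating organ panels
  (leaf, stem, root, flower) into a whole-plant concentration. Weights are
  biomass fractions and sum to one, so the result always lies within the
  organ range, and weighting commutes with the WUE product (predicting from
  the weighted tissue equals weighting per-organ predictions).

### Uptake from pour-through depletion

The pour-through protocol never states an inversion formula, so we derive it
from conservation under the deionized-water refill procedure. A 12-h cycle
starts with the substrate at solution capacity $V_{cap}$ holding the supply
solution $C_{in}$. The plant transpires $V_t$ litres, removing
$C_{up} V_t$ mg of the element (where $C_{up}$ is uptake per litre
transpired, the quantity of interest). DI refill restores volume $V_{cap}$
without adding element mass, so the sampled leachate concentration is

$$C_{leach} = \frac{C_{in} V_{cap} - C_{up} V_t}{V_{cap}}
\quad\Longleftrightarrow\quad
C_{up} = (C_{in} - C_{leach}) \frac{V_{cap}}{V_t}.$$

`uptake_from_depletion()` applies the right-hand inversion. Negative values
(leachate more concentrated than supply — exclusion, mineralization, or
assay error) are returned with `negative_flag = TRUE`, never clipped:
clipping would silently hide conservation violations. The tests validate the
inversion against a forward cycle simulation over randomized cycles,
including mass closure $C_{in}V_{cap} = C_{leach}V_{cap} + C_{up}V_t$ to
numerical precision.

Two assumptions are inherited from the protocol: the 230 mL leachate draw is
a perfect sample of the bulk substrate solution (no stratification
correction), and the substrate returns to the base recipe between events.

### Deviations and best predictors

`deviation_percent()` scores a prediction as
$100 (C_{pred} - C_{up}) / C_{up}$; positive means overprediction. Reported
values are rounded to one decimal, half away from zero (the convention used
in percentage reporting; full precision is retained internally). Per
cultivar and element, `best_predictor()` selects the source with smallest
absolute deviation; ties at reporting precision are broken by the fixed
priority weighted > leaf > root > stem and flagged. Ties are rare in real
panels but must be deterministic.

## Gravimetric processing

Container mass logs (10-minute cadence) are decomposed by
`detect_irrigation_events()` (consecutive-sample gains at or above a
threshold; default 50 g, far above balance noise for drip refills, and
configurable downward for lightly transpiring plants) and
`segment_water_loss()` (start-minus-end mass per inter-event span, clipped
at zero, 1 g = 1 mL). Segments end at the last sample *before* an event so
refill gains never contaminate losses; the cost is that transpiration during
the irrigation dwell itself is unobservable, which is negligible at 10-min
cadence. `daily_water_loss()` aggregates by calendar day,
`window_water_loss()` measures the fixed 07:00–19:00 day-course window used
for the 12-h uptake cycles (configurable: exact clock bounds per event are a
protocol choice), and `cumulative_water_use()` totals the phase for the WUE
denominator.

Numerical choices: rolling-median smoothing (window 3) is available but off
by default. It suppresses single-sample spikes, but at refill kinks the
median substitutes a neighbouring sample and biases segment endpoints by up
to one sample interval's transpiration (~1% of a day's loss), whereas raw
endpoint noise contributes well under 0.5%; so thresholding alone is the
default and smoothing is reserved for spiky traces. Evaporation is treated
as negligible (covered containers) and balances as drift-free.

## Statistical layer

Per element, uptake records form a balanced repeated-measures layout:
cultivar between subjects, sampling date within, replicate plants as
subjects. `rm_anova()` computes the univariate split-plot analysis (cultivar
tested against subject-within-cultivar; date and cultivar×date against the
subject×date residual), requiring a complete balanced design and directing
unbalanced data to listwise handling upstream. Sphericity is not corrected —
the Greenhouse–Geisser epsilon is reported informationally — matching
common practice for this design. `pairwise_contrasts()` builds
marginal-means contrasts from the balanced closed forms: cultivar contrasts
at each date combine strata,
$\mathrm{Var} = \tfrac{2}{n}\,[\mathrm{MS}_{subj} + (d-1)\mathrm{MS}_{res}]/d$
with Welch–Satterthwaite degrees of freedom; date contrasts within cultivar
use the residual stratum alone. The default Bonferroni family is one family
per element — all cultivar contrasts across the $d$ dates ($m = d$) — since
each element is analyzed independently; the family is configurable because
reasonable analysts differ here. p-values are floored at 1e-16 and
two-tailed throughout. `welch_t_test()` covers the tissue-level cultivar
comparisons (unpooled variances, small $n$), and
`influence_diagnostics()` returns hat-matrix leverage and Cook's distance
from the cell-means fixed-effects fit, the standard assumption checks for
this analysis. A mixed-effects re-fit is deliberately out of scope.

## The synthetic trial generator

`simulate_trial()` emulates the study design end to end: 2 cultivars × 4
replicate containers, a 38-day vegetative phase, ten pour-through events,
two daily refills (07:00, 20:00), 10-minute balance logging, and a harvest
tissue panel — with a ground-truth ledger (true transpiration, true
per-event uptake concentrations, cumulative absorbed mass) so that recovery
tests have exact references.

Design choices, each a study condition rather than a tuning knob:

* **Growth**: exponential at constant relative growth rate from 15 g to
  ~188 g (CJ2-like) / ~184 g (FirstLight-like) dry mass; no growth-curve data
  exist for the emulated design, and constant-RGR is the default null model
  for vegetative growth.
* **Transpiration**: proportional to daily biomass gain, scaled so that
  total transpiration equals $M_{final}/\mathrm{WUE}$ exactly (WUE presets
  4.71 and 4.59 g L$^{-1}$; ~40 L per plant). The scaling — increments
  divided by $M_{final} - M_0$ rather than by $M_{final}$ — is what makes
  the harvest-derived WUE estimate recover the preset exactly when the
  initial mass is nonzero. Within a day, 92% of transpiration falls in the
  07:00–19:00 day-course window, 5% before 07:00, 1% from 19:00–19:50 and
  2% after the 20:00 refill; the 10 minutes before each refill are treated
  as irrigation dwell with no transpiration, which keeps refill gains and
  segment losses exactly separable at the 10-min grid. The trace is
  container + water mass only; plant fresh-mass gain (a few percent of
  daily water flux) is not modelled, matching how gravimetric protocols
  read all mass loss as transpiration.
* **Uptake trajectories**: linear between phase-start and phase-end
  concentrations. Presets follow the reported vegetative ranges: N and K
  start high and decline (e.g. CJ2-like N 135→75 mg L$^{-1}$), Ca and Mg
  rise, P rises, and micronutrients rise mildly with biomass.
* **Sampling schedule**: ten events every second day over phase days 20–38.
  The emulated trial's active measurement window was the final three weeks
  of the phase (after root-zone establishment), and ten events cannot fit a
  3-day spacing inside it; the 2-day spacing inside the active window is
  the consistent reading. It also matters quantitatively: depletion signal
  scales with the transpired fraction $V_t/V_{cap}$, so sampling before
  plants transpire ~25% of container capacity per cycle leaves the
  inversion dominated by assay noise.
* **Capacity**: 3.0 L of solution held at container capacity (an 11-L
  container with ~1.5 kg perlite; holding capacity is a per-container
  configuration, not a printed value).
* **Noise**: additive Gaussian on balance readings (SD 2 g, typical of
  30-kg-class bench balances) and multiplicative Gaussian on leachate
  assay concentrations (1% relative SD, ICP-OES replicate precision).
  Supply concentrations are exact (the recipe is known). All randomness
  flows from one seed; a fixed config + seed reproduces the dataset
  byte-identically.
* **Element partitioning**: absorbed mass is allocated to organs by biomass
  fraction times a per-element organ affinity (leaf-enriched N/Ca/Mg/B,
  root-enriched Fe/P/Cu, …). Conservation fixes the whole-plant totals, so
  the biomass-weighted mean is unaffected by the affinity pattern — only
  organ-level contrasts are.

Pre-noise, the generator satisfies element conservation exactly
(`ledger_audit()` verifies absorbed mass against the tissue panel per plant
and element, and localizes any corrupted leachate record as the largest
per-event residual).

### What passing tests do and do not show

The generator emulates the trial's *structure* — growth-linked
transpiration, mass-conserving depletion cycles, organ partitioning,
realistic noise magnitudes. It does not emulate ion antagonism or
transporter kinetics, nutrient remobilization between organs,
root-zone retention or precipitation, evaporation, balance drift, or
flowering-phase physiology. Parameter-recovery results therefore
demonstrate that the *pipeline arithmetic* is faithful (the estimators
invert the generating model), not that the mass-balance framework captures
every process in a real greenhouse; on real data, discrepancies such as the
systematic underprediction of K uptake by tissue-based estimates remain
informative rather than errors.

## Worked-example comparison

The bundled `cannabis_vegetative_means()` table (measured uptake and
tissue-predicted input concentrations for two cultivars) exercises the
deviation scoring on realistic numbers:

```{r deviations}
ref <- cannabis_vegetative_means()
dev <- compare_predictions(
  ref |> filter(source != "uptake") |>
    select(cultivar, element, source, predicted_mg_per_l = mean),
  ref |> filter(source == "uptake") |>
    select(cultivar, element, uptake_mg_per_l = mean)
)
dev |> filter(element == "N")
```

The organ biomass-weighted mean is the best N predictor in both cultivars
(deviations +2.9% and −3.1%); no single organ wins across elements — root
tissue is best for P in both cultivars, leaf for Mg — which is the central
argument for multi-organ assessment in fertigation planning.

## Problem sizes and tolerances used in validation

The test suite runs the full default trial (8 plants × 5473 balance samples
× 10 events × 10 elements), checks zero-noise recovery of every per-event
uptake concentration to 1e-6 relative error and WUE to 1e-9, mass closure
over 1,500 randomized cycles to 1e-9, agreement of the split-plot ANOVA
with an explicit design-matrix projection oracle to 1e-8 and of the Welch
test with its closed form to 1e-10, and the type-I rate of the cultivar
test against 99% binomial bounds over 1,000 null replicates. Noisy-recovery
properties average over 100 seeded trials. These sizes keep the suite
comfortably reproducible on a single CPU while leaving the statistical
checks well-powered.

## Known limitations

* The depletion inversion assumes the leachate draw samples the bulk
  solution; stratified substrates violate this.
* `rm_anova()` requires balance by design; missing cycles must be handled
  upstream, and no REML/unbalanced machinery is provided.
* Steady-state tissue chemistry: $C_{input} = C_{tissue}\times\mathrm{WUE}$
  presumes tissue concentration is stable over the phase; strongly
  remobilizing elements blur this.
* One supply recipe per phase; staged recipes would need per-interval
  supply panels.
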