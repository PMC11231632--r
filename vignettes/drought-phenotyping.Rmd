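---
title: "Whole-plant drought phenotyping from gravimetric lysimeter series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plant drought phenotyping from gravimetric lysimeter series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolys)
```

## The measurement problem

A gravimetric lysimeter platform weighs each potted plant every few minutes
through a three-phase protocol: a well-watered pre-treatment with nightly
irrigation to pot capacity, a drought phase in which irrigation is withheld
until the plant's own soil water content (SWC) falls below a stop threshold
(15 % of capacity by default), and a rewatering phase. Everything the
analysis needs — transpiration, plant growth, soil water status — must be
disentangled from a single noisy weight signal plus the irrigation record
and a weather trace (temperature, relative humidity, photosynthetically
active radiation, PAR).

phenolys implements that disentanglement as a tested pipeline and pairs it
with a water-balance simulator of the same system, so that every estimator
can be validated against known ground truth.

## The water-balance model

The simulator tracks soil water $S(t)$ and plant fresh weight $W(t)$ on a
3-minute grid. Per step:

* potential normalized transpiration
  $e_\mathrm{pot} = E_{max}\,\frac{\mathrm{PAR}}{\mathrm{PAR}_{ref}}\,
  \frac{\mathrm{VPD}}{\mathrm{VPD}_{ref}}$, where the reference forcing is
  the midday mean of the scenario's own environment series;
* a linear-plateau stomatal factor of soil water content:
  $f = 1$ for $s \ge \theta_c$ and
  $f = \max(0,\, 1 - b\,(\theta_c - s))$ below it — the same functional
  form the analysis fits, so parameter recovery is well posed;
* transpired mass $e_\mathrm{pot}\, f\, W\, \Delta t$, converted to grams
  with the molar mass of water (18.015 g mol⁻¹);
* soil evaporation as a constant daylight fraction of pot capacity
  (default 0.5 % per day);
* growth $\Delta W = g_e \cdot \mathrm{transpired} \cdot (1 - W/W_{max})$,
  where $g_e$ is the genotype's growth efficiency (g fresh weight per g
  water). The logistic damping term is ours: without it, compounding
  growth diverges over a 29-day rewatering phase. $W_{max}$ defaults to
  300 g, high enough that damping stays mild through the analysis windows;
* irrigation: nightly refill to capacity (22:00) in pre-treatment and
  rewatering. During drought, the first pre-dawn reading (04:00) below the
  stop SWC "terminates" the drought for that plant; thereafter nightly
  maintenance irrigation holds it **at the stop SWC** rather than refilling
  to capacity. A full refill would make early-terminating,
  high-transpiration genotypes transpire maximally during the nominal
  drought window, inverting the characteristic negative correlation
  between well-watered and drought transpiration across lines; holding at
  the stop level reproduces the observed phenotype of water-spending lines
  showing the *lowest* drought-window transpiration;
* the observed weight is the exact system weight plus Gaussian load-cell
  noise (default sd 1 g, typical lysimeter precision; no drift by
  default).

On the noise-free trajectory the identity
$\Delta W_{system} = \mathrm{irrigation} - \mathrm{transpired} -
\mathrm{evaporated} + \Delta W_{plant}$ holds to machine precision at every
step, and the test suite asserts it below $10^{-9}$ relative error.

## Units: the platform scale

Published platform traits report normalized transpiration $E$ and canopy
conductance $G_{Sc}$ with magnitudes near 8–15 and 400–800 "mmol s⁻¹ g⁻¹"
while daily transpiration is 50–350 g day⁻¹. Taken literally (18.015 mg per
mmol), a 40 g plant at $E = 15$ would transpire over $10^4$ g day⁻¹ — the
normalization basis behind those printed units is not stated anywhere we
could find. We therefore treat the trait scale as a convention: internal
computation is strict (grams, mmol s⁻¹ for whole-plant transpiration), and
$E$ and $G_{Sc}$ are reported on a *platform scale* of 2500 units per
mmol s⁻¹ g⁻¹ (1 unit = 0.4 µmol s⁻¹ g⁻¹). Two consistency checks motivate
this choice: $G_{Sc} = E/(\mathrm{VPD}/P_{atm})$ reproduces the published
conductance range from the published $E$ range at typical VPD, and a
40–70 g plant at $E \approx 12$ platform units transpires a realistic
100–150 g day⁻¹. Because simulator and extractor share the convention, all
recovery results are scale-consistent.

## Trait extraction

* **Irrigation events** come from the log when present, otherwise from
  jump detection (between-sample increases above 20 g, consecutive jumps
  merged). Weight smoothing (centered moving average over 5 samples,
  symmetric shrinking half-width at segment edges so linear trends are
  preserved exactly) never crosses an event.
* **Momentary transpiration** is the negative centered-difference slope of
  the smoothed weight on irrigation-free segments, minus the daylight
  evaporation allowance, in mmol s⁻¹. The exported stream is floored at
  zero, but window aggregates are computed from the signed rate and floored
  afterwards: flooring each noisy sample first would bias midday means
  upward exactly where the plant has shut its stomata.
* **Daily transpiration (DT)** is the summed net decline over the day's
  irrigation-free segments minus the daily evaporation allowance. Net
  weight decline understates transpiration by the mass the plant gained
  while transpiring, so the trait table corrects DT by the plant's own
  estimated growth efficiency (below); the uncorrected day-level
  accounting remains available as `daily_transpiration()`.
* **Calculated plant weight (CPW)** is read directly on days whose
  pre-dawn reading follows a refill to capacity:
  $\mathrm{CPW} = W_{predawn} - \mathrm{tare} - \mathrm{dry\ soil} -
  \mathrm{capacity}$, averaging the pre-dawn window 02:00–05:00 (fluxes are
  negligible at night, so the average only suppresses noise). A refill
  event alone is not sufficient — the implied plant weight must be
  positive, which excludes partial maintenance irrigation. On drought days
  CPW is carried by bookkeeping from the last capacity day using the
  plant's own pre-treatment regression of day-to-day CPW change on DT
  (through the origin). Growth efficiency estimated this way is mildly
  conservative when growth is damped near $W_{max}$; the drought
  bookkeeping tolerance (10 %) absorbs this.
* **SWC** is the smoothed weight minus tare, dry soil and the day's CPW,
  as percent of capacity, clipped to [0, 100] with a flag. A day's fit
  point is only discarded as clipped when most of its midday window
  clips — noise around 100 % at pre-dawn is harmless.
* **Midday aggregation** uses 11:00–14:00 for the reported traits
  ($E$, $G_{Sc}$, whole-plant TR). Canopy conductance applies a VPD floor
  (0.1 kPa) below which the value is flagged missing rather than allowed
  to diverge.

## Estimating the critical SWC

The response model is the broken stick: transpiration constant at
$TR_{max}$ above $\theta_c$, declining linearly below, continuous at the
breakpoint, decline slope constrained non-negative. For every candidate
breakpoint on a 0.01-point grid over the observed SWC range the two
remaining parameters have an exact conditional least-squares solution; the
global minimizer is polished by a continuous local optimization between its
neighboring grid knots, ties broken toward the larger breakpoint (the
conservative physiological reading: earlier detection of limitation). Fits
are invalid on boundary minimizers, vanishing slopes, fewer than 6 points,
or an SWC span under 10 points. The test suite holds the fit to the
optimum of an independent exhaustive fine-grid search on 200 random
instances.

Three estimator choices matter for accuracy and are deliberate:

* **Response variable.** The default response is *normalized, demand-
  corrected* midday transpiration: $E$ divided by the day's midday demand
  factor $(\mathrm{PAR}/\mathrm{PAR}_{ref})(\mathrm{VPD}/\mathrm{VPD}_{ref})$.
  Normalizing by plant weight removes growth non-stationarity (a
  whole-plant TR plateau drifts upward as the plant grows across drought
  days); normalizing by demand removes day-to-day atmospheric variance
  that otherwise inflates plateau scatter. Whole-plant TR and plain $E$
  remain available via the `response` argument.
* **Pairing window.** Fit points pair the response with SWC over a tight
  solar-noon window (12:00–13:00). On fast-drying days SWC falls by
  several points across the full midday window, which smears the
  breakpoint upward by roughly half the intraday drawdown.
* **Dead-day exclusion.** Days whose response has collapsed below 5 % of
  the observed maximum are excluded: past full stomatal closure the true
  response saturates at zero (a second hinge the single-kink model does
  not represent), and such days no longer inform the linear decline.

With these choices, recovery simulations at load-cell noise of 1 g recover
$\theta_c \in \{25, 30, 35, 40\}$ with a median absolute error well under
1.5 SWC points (asserted by the test suite at 100 simulations per level),
and the plateau recovers the generator's $E_{max}$ within a few percent.

## Line metrics and statistics

Vigor is the mean daily CPW gain over a well-watered reference window;
resilience the ratio of rewatering to pre-treatment CPW gain rate (the
gain-rate basis is the default; a level basis is available); recovery the
ratio of rewatering to drought DT; WUE the end-of-experiment dry biomass
over cumulative transpiration. Ratios are computed per replicate and then
summarized per line as mean ± SE. Default windows follow the replicated
55-day protocol (days 7–11, 22–26, 51–55, 51–54 vs 18–26); for other
schedules `auto_windows()` selects the most stable consecutive
pre-treatment and rewatering days by minimizing the summed squared
coefficients of variation of daily mean VPD and PAR, while the drought
window is always the final days of the phase: pots start at capacity, so
the stomatal contrast between lines only develops late in the drydown,
and an early window would compare lines before any of them is water
limited.

The statistical surface is deliberately plain: Pearson correlations of
line means across phases; one-way ANOVA with all-pairs Tukey HSD
(Tukey–Kramer standard errors under unbalanced replication, via R's
`TukeyHSD`); and a compact letter display built by insert-and-absorb, for
which the package maintains the exact invariant that two lines share a
letter if and only if their Tukey-adjusted difference is not significant —
verified against an independent studentized-range computation on a
thousand random instances.

Strategy classification is a declared convention, not an inference: lines
in the top pre-treatment DT tertile, bottom drought DT tertile and top half
of $\theta_c$ are called *dynamic* (water-spending but early-curtailing);
the mirrored rule gives *anisohydric*; everything else *isohydric*.
Degenerate rankings (no separation) classify everything isohydric, and
missing $\theta_c$ downgrades the call to low confidence.

## The synthetic cohorts

No raw data are available for the barley experiments this pipeline
emulates, so the package ships synthetic parameter panels anchored to the
published trait *ranges*: 18 named lines whose $E_{max}$ (8.8–15.1
platform units), $\theta_c$ (26.7–42.6 % SWC), decline slopes and recovery
factors span the published envelope, with the two extreme genotypes
pinned to their printed values, plus a deterministic 81-line diversity
panel. Growth efficiencies (0.015–0.03 g g⁻¹) and the dry-matter fraction
(0.30) were chosen once so that simulated water-use efficiencies fall in
the published 0.004–0.009 g g⁻¹ band; we use 0.30 rather than a more
typical 0.12 because with growth efficiency pinned by drought pacing (a
pot must take one-to-two weeks to dry), 0.12 cannot reach that band.
These tables are simulator ground truth — they are not measurements, and
per-line agreement with published values beyond the anchors is neither
expected nor claimed.

What the generator does **not** emulate: weather fronts and multi-day
autocorrelated forcing; load-cell drift and discrete re-taring; soil
hydraulic limitation (SWC is the only soil state); osmotic adjustment and
other slow acclimation; root-zone heterogeneity; and the actual growth
trajectories of the real platform, which are not published. Passing
recovery tests therefore demonstrates that the estimators are unbiased and
precise *under the model's assumptions*, not that the pipeline is robust
to every failure mode of real platform data.

## Problem sizes and runtime choices

The validation suite runs the full chain at realistic sizes: 480 samples
per plant per day, 29-day (9 + 11 + 9) and 55-day (11 + 15 + 29)
protocols, cohorts of up to 18 lines × 2–5 replicates, and 100 recovery
simulations per $\theta_c$ level. These sizes were chosen so the whole
suite completes in a few minutes on one core while keeping every estimate
within its stated tolerance.

## Known limitations

* The growth-efficiency regression assumes growth proportional to
  transpiration within pre-treatment; under strong damping near
  $W_{max}$ it underestimates $g_e$ and the drought CPW bookkeeping
  inherits that bias (bounded by the 10 % tolerance in validation).
* $\theta_c$ estimates carry a small positive bias (a few tenths of a
  point) from daily discretization of a continuously drying system.
* The strategy rule is rank-based and cohort-relative: calls are only
  meaningful within a cohort, and a cohort without genuine contrast
  degenerates to all-isohydric.
* The 81-line scenario has no replication, so its letter displays are
  undefined and its per-line estimates rest on single plants, exactly as
  in a real unreplicated screening.
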