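---
title: "Quasi-fuzzy neural estimation of reference evapotranspiration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-fuzzy neural estimation of reference evapotranspiration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evatcrop)
```

## The estimation problem

Daily reference evapotranspiration ET0 (mm/day) is the evaporative demand
of a hypothetical well-watered grass surface. The FAO-56 Penman–Monteith
equation is the accepted benchmark, but it needs five daily inputs — Tmin,
Tmax (°C), wind speed at 2 m (m/s), mean relative humidity (%) and solar
radiation (MJ m⁻² d⁻¹) — and most stations in data-poor regions record
only some of them. This package learns a direct mapping from whichever
inputs are available to the FAO-56 value, one model head per input
combination. The always-paired temperature extremes form the base
combination C1; the three optional variables appear in all subsets, giving
the eight combinations C1–C8 of `standard_combinations()`.

## The FAO-56 engine (the supervised target)

`reference_et0()` implements the daily combination equation with the
standard auxiliary equations: saturation vapour pressure
`e°(T) = 0.6108 exp(17.27T/(T+237.3))`; `es` as the mean of `e°(Tmax)` and
`e°(Tmin)` and `ea = RH/100 · es`; the psychrometric constant from
elevation via the standard-atmosphere pressure profile; extraterrestrial
radiation from the inverse relative earth–sun distance, solar declination
and sunset hour angle, with day-of-year the 1-based ordinal within the
calendar year; clear-sky ceiling `Rso = (0.75 + 2·10⁻⁵ z) Ra`; net
shortwave with reference albedo 0.23; and net longwave with the
`0.34 − 0.14√ea` humidity correction and the `1.35 sr/Rso − 0.35`
cloudiness factor.

Numerical choices worth stating:

* **Net radiation, not extraterrestrial.** The combination equation is
  evaluated with net radiation Rn. Using extraterrestrial radiation Ra in
  its place would be physically wrong (Ra never reaches the surface), and
  the two symbols are easy to conflate in print.
* **G = 0** at the daily time step, the standard recommendation.
* The cloudiness ratio `sr/Rso` is clamped to `[0.05, 1]` inside the
  longwave term so near-zero radiation days cannot blow up the budget;
  `sr` exceeding `Rso` beyond a small tolerance additionally warns.
* Negative ET0 (possible on strongly negative-Rn days) is reported as
  computed; `floor_negative = TRUE` opts into flooring at zero. The
  default preserves the mathematical definition.
* Wind is assumed measured at 2 m; no log-profile height conversion is
  applied.
* `ea` is derived from daily *mean* relative humidity. Variants using
  RHmax/RHmin exist; with only a single daily humidity value the mean-RH
  form is the defensible choice, and the test suite checks the engine
  against an independently written scalar reference to below
  0.05 mm/day over randomized physical inputs.

## The quasi-fuzzy transform

Each variable gets one triangular low/medium/high partition, fit on the
**training split only**: `l` and `h` are the observed minimum and maximum
and the medium peak sits at the midpoint `m = (l + h)/2`. Two deliberate
corrections to the fuzzification as sometimes printed in the neuro-fuzzy
literature: a peak defined as `(h − l)/2` falls below `l` whenever
`l > h/3` (true of any Celsius temperature range in this climate) and
cannot parameterise a triangle, so the midpoint is used; and the
decreasing branch of the medium label uses denominator `(h − m)`, because
`(h − l)` would make the membership jump discontinuously from 1 to 0.5 at
the peak. With these choices the three memberships form an exact partition
of unity at every x.

Out-of-range values — inevitable at prediction time when test weather
exceeds the training extremes — are clamped: below `l` the low label holds
degree 1, above `h` the high label does. This keeps every record
processable and is the design-level answer to the out-of-range failure
mode that grid-partition ANFIS models exhibit on held-out data. One
partition set per site is shared by all combinations (a single
fuzzification of each variable), which is what a single-fuzzifier,
multi-head architecture implies.

A k-variable combination has the exhaustive rule base of all 3^k label
assignments — 9/27/27/27/81/81/81/243 for C1–C8, 576 rules over the eight
groups — ordered lexicographically (variable order Tmin, Tmax, Ws, Rh, Sr;
label order low < medium < high). The ordering is a package convention:
any fixed order works, but it must be reproducible because the neural
head's input weights are aligned to it and persist across save/load.
Every rule fires on every record with the product t-norm, and the firing
vector is normalised to sum to one (`normalize_firings()`), producing the
interim output vector fed to the head. With the symmetric default
partitions the firing vector already sums to one (a product of partitions
of unity expands to one), making normalisation the identity; it is kept
because user-supplied partition overrides with other shapes or overlaps
need not satisfy that identity.

## The neural heads

Each combination's head is a one-hidden-layer perceptron with a linear
output unit, trained by limited-memory BFGS (`stats::optim`,
`method = "L-BFGS-B"`, history size 10) on the mean-squared-error loss
with analytic gradients: the quasi-Newton update `w_{k+1} = w_k + η_k d_k`
with `d_k = −H_k ∇E(w_k)`, the step length chosen by the optimizer's line
search. Weights are initialised as uniform values scaled by 1/√fan-in
under a caller-supplied seed, so training is bit-reproducible. The
alternative first-order optimizers (SGD, Adam) are deliberately out of
scope: the full-batch quasi-Newton path is stable on these small dense
problems and needs no learning-rate tuning.

Hidden size and activation are chosen by grid search under k-fold
cross-validation (`grid_search_head()`, default five folds, hidden sizes
2–16, activations identity/logistic/tanh/relu). Folds are assigned by a
deterministic interleaved rule rather than by shuffling, keeping the whole
pipeline free of hidden randomness. Ties break toward fewer hidden units,
then earlier activation — the smaller, simpler model wins when scores are
equal. The experiment configurations used in the package's own test runs
restrict the grid (e.g. a single tanh head of 8 units, or {4, 8}): on the
synthetic benchmark the interim vector is informative enough that
accuracy saturates at small hidden sizes, and the restricted grid keeps a
full eight-combination run in the minutes range on one CPU. The full
2–16 grid remains the default for real analyses.

## Baselines

`fit_baselines()` fits, per combination, (i) a CART regression tree
(`rpart`) on the raw variables with maximum depth 2–16 and minimal
cost-complexity pruning strength in [0, 1] grid-searched by five-fold CV,
and (ii) a one-hidden-layer network on standardised raw inputs with the
same hidden-size grid. Both consume raw inputs, not interim vectors; they
are the conventional competitors the quasi-fuzzy transform is compared
against. The ANFIS comparator is not implemented (third-party method,
different toolbox lineage); externally produced prediction series can be
scored with `metric_report()` directly.

## Metrics

`metric_report()` computes R² (the standard `1 − SSres/SStot` about the
reference mean), Willmott's degree of agreement
`d = 1 − Σ(p−r)² / Σ(|p−r̄|+|r−r̄|)²`, RMSE, and RMSRE (errors scaled by
the reference values), plus the averages Ag = (R²+d)/2 and
Ae = (RMSE+RMSRE)/2. Ae knowingly mixes units (mm/day with a ratio); it is
reproduced as defined because it is used only to rank models on the same
data. A ratio variant of R² that scores a perfect fit as 0 rather than 1
circulates in print; it is available behind
`coefficient_of_determination(..., printed_form = TRUE)` for auditing
published tables but is used nowhere else — reported "best" values near 1
are only consistent with the standard form. Degenerate cases (constant
reference, zero reference values for RMSRE) return `NA` markers rather
than infinities or silent exclusions.

## The synthetic weather generator

`generate_synthetic_weather()` stands in for the multi-year reanalysis
records the method is normally trained on, emulating a humid subtropical
(Terai-like) site: Tmax as an annual sinusoid (mean 28 °C, amplitude 4 °C,
peak around day 140) with Gaussian noise; Tmin as Tmax minus a seasonal
positive diurnal range (larger in the dry winter); relative humidity as a
monsoon-phased sinusoid clamped to [20, 100] %; wind speed i.i.d.
Weibull(shape 1.8, scale 1.4), whose shape < 3.6 guarantees the positive
sample skewness that observational wind records in the region show; and
solar radiation as a seasonal clearness fraction in [0.25, 1] times the
clear-sky ceiling, so `sr ≤ Rso` holds by construction. The parameter
values are fixed once to match the region's published monthly climate
normals (winter Tmin near 14 °C, monsoon humidity near 90 %, mean wind
near 1.2 m/s) and are exposed through `params` for other climates.

What the generator does **not** emulate: day-to-day autocorrelation of
weather regimes, rainfall and its coupling to radiation/humidity, missing
records, and instrument error. Passing the synthetic benchmark therefore
shows that the pipeline learns a smooth five-variable physical functional
under realistic marginal distributions — it does not certify accuracy on
real station data, where autocorrelated regimes shrink the effective
sample size.

## Experiment protocol and problem sizes

`run_experiment()` computes FAO-56 targets for the full series, splits
chronologically (training share 0.7, training count floored — observed
records are split as they are, with no reindexing against the calendar),
fits partitions and heads on the training part only, and scores both
phases. Mutating the test block provably leaves the fitted model unchanged
(asserted in the test suite). The package's own end-to-end runs use 4,876
synthetic days — about 13.4 years, the scale of a typical reanalysis
extract, giving 3,413 training and 1,463 test days — with a single-tanh or
{4, 8} hidden grid; a full run completes in roughly one to two minutes on
one CPU.

## Persistence

`save_model()` writes one plain-text JSON bundle: format version,
partitions, head architectures and weights at 17 significant digits (so
doubles round-trip exactly and reloaded predictions are bitwise identical),
provenance (seed, training window, rule counts) and an md5 checksum over
the canonical payload encoding. `load_model()` rejects unknown versions
and any checksum mismatch.

## Known limitations

* Accuracy claims transfer to real data only to the extent the generator's
  idealisations hold; site-specific validation on observed records is the
  user's task.
* Partitions are data-driven triangles; expert-elicited shapes can be
  supplied as `fuzzy_partition()` overrides but no elicitation tooling is
  provided.
* The rule base grows as 3^k; with the five standard variables this tops
  out at a manageable 243, but the design does not extend cheaply to many
  more inputs.
* RMSRE is undefined when any reference value is zero; daily ET0 in the
  target climate is strictly positive, so this arises only in synthetic
  edge cases.
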