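---
title: "Methods: an ecoclimatic suitability and voltinism model for an invasive stink bug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ecoclimatic suitability and voltinism model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climsuit)
```

## The model

`climsuit` implements a CLIMEX-style semi-mechanistic bioclimatic model for
poikilothermic organisms, parameterised for the brown marmorated stink bug
*Halyomorpha halys*, and the analysis pipeline needed to apply it to a
high-resolution gridded monthly climatology of a topographically complex
country: scenario construction by the delta-change method, suitability and
voltinism mapping, per-location phenology, and validation against
georeferenced occurrence records.

The engine works on a 52-week year (exactly 364 days; the remainder day is
ignored, and closed-form test values assume this convention). For each grid
cell and week $w$:

* **Temperature index** $TI_w$: a piecewise-linear trapezoid over the four
  cardinal temperatures $(DV0, DV1, DV2, DV3) = (12, 27, 30, 33)\,°C$ —
  zero at or below $DV0$ and at or above $DV3$, one on the optimal plateau
  $[DV1, DV2]$. The source parameter table defines only the four points;
  the trapezoid is the standard published depiction of this response and is
  fully determined by them.
* **Moisture index** $MI_w$: the same trapezoid over soil moisture
  $(SM0, SM1, SM2, SM3) = (0.1, 0.5, 1, 1.5)$, in units of fraction of the
  soil's water-holding capacity, driven by a weekly one-bucket water
  balance (below).
* **Diapause indicator** $DI_w \in \{0, 1\}$: winter diapause is induced at
  the first week in the shortening-day half of the year with day length
  below $DPD0 = 12$ h and mean temperature below $DPT0 = 5\,°C$, and
  terminated at the first subsequent lengthening-day week warmer than
  $DPT1 = 5\,°C$ (the fitted development requirement is $DPD = 0$ days, so
  termination is instantaneous once conditions are met). The year is
  treated as periodic, so a winter spanning the calendar wrap is handled by
  iterating the switching rule to its annual fixed point. Summer diapause
  ($DPSW = 1$) is not implemented; the fitted parameter set does not use it.
* **Growth index** $GI_w = TI_w \cdot MI_w \cdot DI_w$, and annually
  $GI_A = 100 \sum_w GI_w / 52$.
* **Stress accumulation**: cold, heat, dry, wet and hot-wet stress
  accumulate linearly in the weekly exceedance of their thresholds at the
  published weekly rates and are capped at 100, e.g.
  $CS = \min(100, \sum_w 100\,|THCS| \max(0, TTCS - tmin_w))$. Rates
  printed with a negative sign enter by magnitude. The proprietary engine's
  exponential stress compounding is not reproduced: in the Swiss-range
  regime all stresses are zero, which makes the result insensitive to the
  compounding choice, and the linear rule is the simplest testable one.
* **Degree days and voltinism**: $DD_w = 7 \max(0, tavg_w - DV0)$ with
  $tavg_w = (tmin_w + tmax_w)/2$ (monthly-mean inputs do not support
  within-day sinusoidal integration); generations per year
  $= \sum_w DD_w / PDD$ with the thermal constant $PDD = 595\,°C$ days,
  reported as a real number. Area statistics use generations $\ge 1$ and
  $\ge 2$.
* **Ecoclimatic Index**:
  $EI = GI_A \prod_s (1 - S_s/100)$ over the five stresses, set to zero
  when annual degree days fall short of $PDD$ (the growing season cannot
  complete one generation — in the alpine study region this gate, not
  stress, is what produces $EI = 0$), clamped to $[0, 100]$. A location is
  unsuitable below 1, marginal on $[1, 5]$, suitable above 5 and highly
  suitable above 15; both upper thresholds are strict.

One deliberate simplification mirrors the fitted model itself: the 148
degree-day preoviposition period of overwintered females is *not*
subtracted from the generation budget.

The hot-wet interaction uses $TTHW = 28\,°C$ as its temperature threshold
and $MTHW = 1.5$ as its moisture threshold. Printed parameter tables
occasionally transpose the two labels; dimensional consistency with the
temperature and moisture ranges fixes the interpretation.

## The water balance

The weekly potential evaporation is a bulk temperature–saturation-deficit
formula, $E_w = k_e \cdot 7 \cdot \max(0, tavg_w)(1 - (rh_{09} +
rh_{15})/200)$ mm with $k_e = 0.8$ mm °C⁻¹ day⁻¹, and the soil store obeys

$$S_w = \min\!\big(s_{max}, \max(0,\; S_{w-1} + (rain_w - E_w)/capacity)\big)$$

with $capacity = 100$ mm, iterated around the year until a 52-periodic
steady state (pass-to-pass change below $10^{-9}$, at most 20 passes;
convergence is exact once the store touches a boundary, which is what makes
the steady state independent of the initial value $S_0 = 0.5$).

The storage ceiling defaults to $s_{max} = 1$: moisture above field
capacity is shed immediately as runoff. This is the one place the package
deliberately departs from allowing storage up to twice capacity. In any
realistically humid temperate climate the winter surplus pins a hard-capped
bucket at its ceiling for the whole cold season; a ceiling of 2 would
therefore hold the store above the wet-stress threshold of 1.5 all winter
and accrue spurious wet stress in every cell, contradicting the observed
stress-free regime of the study region. With runoff at field capacity, wet
stress is unreachable in humid climates — which is exactly the published
finding — while `s_max` remains an argument so super-capacity storage (and
hence wet stress) can be exercised where wanted.

## From monthly grids to weekly series

Inputs are monthly normals of daily minimum and maximum temperature and
precipitation sums on a regular longitude–latitude lattice (0.02° in the
study design). Temperatures (and the derived humidities) are interpolated
linearly between month midpoints (day-of-year centres of a 365-day
calendar, periodic wrap) and sampled at the 52 week midpoints of the
364-day year; the final week absorbs the one-day calendar mismatch.
Precipitation is apportioned, not interpolated: each month's sum is split
across weeks in proportion to the number of that month's days falling in
each week, so annual totals are conserved to machine precision — the
property that matters for the water balance.

Relative humidity at 09:00 and 15:00 is derived from the temperature
climatology alone: the dewpoint is assumed equal to the daily minimum (so
the actual vapour pressure is $e_s(tmin)$ by the Magnus formula
$e_s(T) = 6.112 \exp(17.62\,T/(243.12 + T))$ hPa), and the 09:00 / 15:00
temperatures sit at fractions 0.4 / 0.9 of the diurnal range above the
minimum. These two fractions are a completion — the upstream climatology's
actual diurnal positioning is not documented — chosen as standard practice
when vapour-pressure observations are absent. Day length follows the
standard solar-declination formula at the week's middle day; polar
latitudes are rejected as out of scope.

Cell membership of a query point is half-open (`[low, high)` in both axes,
so a point on a shared edge belongs to the cell whose low edge it is), and
is computed in index space with a $10^{-9}$ epsilon because raw
floating-point box comparisons leave gaps at representable cell edges.

Of the interchange formats in the original design (NetCDF, GeoTIFF stacks,
long CSV) only the CSV dialect is implemented, with a lossless round-trip
writer (17 significant digits); no NetCDF- or GeoTIFF-capable R package is
among this package's dependencies, and the text format is sufficient for
the full pipeline.

## Scenarios

Future climates are built by the delta-change method: monthly temperature
deltas are added to both tmin and tmax (leaving the diurnal range
unchanged), monthly precipitation deltas are applied as percentages (so
precipitation cannot go negative), and humidity is re-derived from the new
temperatures. A zero signal reproduces the baseline bit for bit, and
interannual variability is unchanged by construction — the delta method
cannot represent changes in variability, wet-day frequency or dry spells.
The bundled nine-signal suite (RCP3PD / A1B / A2 × 2020–2049 / 2045–2074 /
2070–2099) uses annual-mean warming from +1.2 to +4.1 °C with mild summer
drying, shaped seasonally as $\Delta_m = \Delta(1 + 0.3\cos(2\pi(m-7)/12))$
so the requested annual means hold exactly; the magnitudes follow the
Swiss CH2011-class scenario products, whose gridded deltas are not
redistributable.

## The synthetic alpine world

Because the 0.02° national climatology and the scenario grids are
proprietary, the package generates a Switzerland-like test world: a
valley floor at 300 m with smooth Gaussian ridges (one per ~130 cells,
footprints scaling with domain size over the square root of the ridge
count, so the alpine share of the landscape is the same at every grid
size), elevation capped at 2600 m; a sea-level annual mean of 14 °C with
9 °C seasonal amplitude, lapsed at −6.5 °C km⁻¹; an 8 °C diurnal range;
and precipitation of 85 mm/month plus 25 mm/month per km of altitude with
a summer-peaked seasonal shape. Temperature noise (SD 0.3 °C per cell and
month) adds spatial texture. All draws come from one explicitly seeded
stream per generator call; the caller's RNG state is untouched.

These values were fixed once from alpine climatology. Two consequences are
by construction, mirroring the published regime rather than calibrated to
any test outcome: weekly minima stay above the −18 °C cold-stress
threshold and maxima below the 33 °C heat-stress threshold, and the humid
precipitation regime keeps the soil store within the stress-free moisture
band — so the reference climate accrues no stress of any kind, and
suitability is limited solely by the degree-day gate, which declines with
altitude. The `"swiss_size"` preset has 111 × 101 = 11,211 cells, the cell
count of the study design; the default 20 × 15 = 300-cell grid keeps test
runtimes in seconds. Synthetic occurrence records are drawn from cells
with probability proportional to $\max(0, EI - 5)$ and jittered uniformly
within the cell, so every record lies in a suitable cell — the overlap
validation on generated data is a self-check of the overlay machinery, not
evidence about real observations.

What the synthetic world does *not* emulate: real topography and its
rain-shadow asymmetries, snow storage, lakes and land masks, station
interpolation error, and interannual variability. Passing tests on this
world therefore demonstrate the correctness and internal consistency of
the modelling chain, not the Swiss numbers themselves, which require the
proprietary inputs.

## Numerical choices and degenerate inputs

* Soil-bucket iteration: tolerance $10^{-9}$, at most 20 annual passes;
  starting value 0.5 of capacity.
* Diapause fixed point: at most 4 annual passes (two suffice for a single
  winter spanning the year wrap); day-length ties (exactly constant
  photoperiod) count as neither shortening nor lengthening.
* The vectorised grid engine performs, per cell, the same per-cell
  arithmetic in the same order as `run_cell()`, so the two routes agree to
  floating-point roundoff; the test suite also checks both against an
  independently coded straight-line scalar oracle at $10^{-10}$.
* Grid validation rejects `tmin > tmax` (reporting offending coordinates),
  negative precipitation, |T| > 60 °C, monthly precipitation > 5000 mm and
  irregular lattices (spacing must be an integer multiple of the cell
  size within $10^{-9}$ degrees).
* Empty grids, all-zero growth series (undefined phenology windows),
  occurrence files with no in-bounds records and missing weeks all raise
  informative errors rather than producing silent zeros.
* Rounding happens only at presentation: location tables print EI to
  integers, generations to two decimals, weeks to integers; area
  percentages are exact until printed.

## Known limitations

* **Moisture knife-edge under strong warming.** The bucket consumes
  *potential* evaporation regardless of how dry the store already is, so
  sustained warm-season deficits integrate linearly and can drive valley
  cells from comfortable moisture to an empty store within one season of
  +3 to +4 °C warming, collapsing their growth index and accruing dry
  stress. A moisture-limited drawdown ($E = E_{pot} \cdot S$) would soften
  this, but would change the bucket's documented closed-form behaviour;
  the simple rule is kept and the effect is visible in the scenario
  analysis as suitability losses at the warmest, driest sites — the same
  qualitative mechanism the original study reports for its hottest
  location, amplified here by the simpler hydrology.
* The engine-level monotonicity guarantee (warming a thermally sub-optimal
  cell never lowers its indices) holds through the temperature pathway,
  i.e. when soil moisture sits on its optimal plateau; through the
  moisture pathway, warming raises evaporation and can lower $MI$ — that
  is a modelled feature, not a violation.
* Exponential stress compounding, within-week time stepping, irrigation,
  overwintering mortality, intraspecific trait variation and natural-enemy
  interactions are out of scope.
* The binary diapause indicator is a choice; a continuous diapause
  development index would interpolate the on/off transition but there is
  no published trace to fit one against.

## Problem sizes

The test suite exercises 300-cell grids throughout and one full
11,211-cell pipeline (baseline plus nine scenarios); the acceptance script
runs the closed forms, a 300-cell dual-route comparison and two
11,211-cell engine runs. All of it completes in well under a minute on one
CPU.
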