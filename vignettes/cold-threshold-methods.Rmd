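---
title: "Methods: soil-water-modified phenology and cold-temperature yield thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil-water-modified phenology and cold-temperature yield thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(chickcold)
```

# The problem

Chickpea is unusually sensitive to cold during its reproductive phase: frost
(screen minimum at or below 0 °C) kills flowers and young pods outright, and
sub-freezing "chilling" nights abort pod set well above 0 °C. Where the onset
of damage sits — the cold-temperature threshold $T_C$ — varies from site to
site, and knowing it matters for choosing sowing windows and cultivars.
`chickcold` implements a complete, testable pipeline for estimating $T_C$ and
its yield cost from daily weather and annual yields:

1. a **phenology engine** that predicts flowering and pod fill from thermal
   time, modified by photoperiod and soil water, so the reproductive period
   (RP) can be located in each season;
2. a **frost module** that counts post-flowering frost events, applies a
   per-event yield penalty, and measures how much frost timing overlaps peak
   flowering;
3. a **threshold detector** that grid-searches $T_C$ by repeated regression
   of frost-affected yield on cold-day exposure and RP rainfall;
4. **goodness-of-fit statistics** (RMSD, Willmott's $d$, $R^2$) for
   comparing simulated and measured series; and
5. a **synthetic-data generator** that creates weather, soil water and yields
   with a *known implanted* threshold, so the whole chain can be verified by
   parameter recovery rather than trusted on faith.

# Phenology

## Daily thermal time

Daily thermal time is computed the way Australian cropping-systems models do
it: eight three-hourly temperatures are interpolated between the day's
minimum and maximum, each is pushed through a piecewise-linear response —
zero at the base temperature, rising to $T_{opt} - T_{base}$ at the optimum,
falling to zero at the maximum — and the eight responses are averaged. The
cardinal temperatures are cultivar configuration; the shipped fixture uses
0/30/40 °C, documented as calibration values rather than measured constants.

## The soil-water modifier

Wet soil delays chickpea flowering. The engine implements this as a
multiplier on daily thermal time:

$$\mathrm{TTm} = \mathrm{TT} \times (1.65 - \mathrm{FASW}),
  \qquad \mathrm{FASW} > 0.65 \text{ and stage} \ge \text{emergence},$$

where fractional available soil water over the top 60 cm of the profile is

$$\mathrm{FASW} = \frac{\sum_n (sw - ll15)}{\sum_n (dul - ll15)},$$

clipped to $[0, 1]$ (the defining identities are 1 at field capacity and 0 at
the crop lower limit, so super-saturated profiles count as 1). At the
activation boundary the multiplier equals exactly one, so the package treats
the boundary itself as unmodified; that reading is mathematically identical
to applying the multiplier from the boundary upward and keeps the boundary
identity exact in floating point (1.65 − 0.65 is not exactly 1 in binary
arithmetic). At field capacity the crop perceives only 65 % of the day's
thermal time.

```{r}
cv <- cultivar_hattrick()
modify_thermal_time(10, fasw = c(0.5, 0.65, 0.9, 1.0), stage = 5, cv)
```

## Photoperiod

Short days increase the thermal-time requirement to flower. The engine uses a
linear ramp: the accumulation factor is 1 at or above the saturating day
length, $1 - s$ at or below the critical day length, linear between. The
functional form is a package design choice (the underlying physiology is only
known qualitatively); setting sensitivity $s = 0$ disables it, which the unit
tests use to probe the soil-water modifier in isolation. The photoperiod
factor and the soil-water multiplier both scale the same day's thermal time,
so their order is immaterial; both apply only after emergence.

## Stages and accumulation

Stages are numbered 1 sowing … 8 maturity. Accumulation restarts at each
stage entry (a day's surplus beyond the target is discarded — targets behave
like ceilings), except that flowering, end of flowering and end of pod fill
share one accumulator started at flowering, since both later targets are
specified from flowering. Peak flowering is the mid-point of the flowering
span, floored to a whole day. The daily loop evaluates FASW at the start of
the day. Sowing follows the operational rule: the first day in the window
whose trailing 7-day rainfall (inclusive) reaches 25 mm while whole-profile
plant-available water exceeds 80 mm; failing that, the last day of the
window, flagged `forced`.

A deliberate consequence of the modifier, asserted as a property test:
raising FASW on any post-emergence day (within the active region) can only
delay flowering, never hasten it.

# The bucket water balance

The package needs a *plausible* daily FASW trajectory, not a research-grade
soil model, so soil water is a cascading bucket: rain infiltrates the top
layer; water above saturation overflows downward immediately; a fraction
(default 0.5/day) of water above the drained upper limit drains to the layer
below; evapotranspiration demand `et_coef × max(0, Tmean − et_base)` is
extracted top-down from the layers starting within 600 mm of the surface,
never below the crop lower limit. Defaults (`et_coef` = 0.08 mm/day/°C,
extraction limited to the top 600 mm) were chosen so a Wagga Wagga-like
climate produces the right *shape*: FASW near capacity in late winter and
early spring, a dry summer trough, and autumn recharge. On every
1 November the profile is reset to FASW = 0.5, mimicking the low water left
after a winter fallow ahead of summer rains. The reset, the start-of-day
evaluation, and the per-layer bounds ($ll15 \le sw \le sat$) are all covered
by unit tests with hand-computed sequences.

# Frost events and the yield penalty

A frost event is a day with screen minimum at or below 0 °C inside the
assessment window, here the reproductive period [flowering start, end of pod
fill]. Each post-flowering event costs about 5 % of yield. Whether repeated
events compound multiplicatively or additively is not determined by the
evidence behind the 5 % figure, so both are implemented:
$YF = Y(1-\ell)^k$ (default; bounded, never negative) and
$YF = Y\max(0, 1-\ell k)$. They agree at a single event, where the headline
5 % check is made.

Frost *risk* at a site is summarised by the overlap coefficient between two
kernel density estimates on the day-of-year axis — frost events and peak
flowering across years — $\int \min(\hat f, \hat g)$ evaluated on a day
1–366 grid with Silverman bandwidths. A site with no frost reports 0 with a
`no_frost` flag. Wrap-around at the year boundary is ignored; all relevant
timing falls mid-year in the southern hemisphere, which is the package's
scope.

# Threshold detection

For season $t$, let $YF_t$ be frost-affected yield, $R_t$ total RP rainfall,
and

$$P_t(T_C) = 100 \times \frac{\#\{\text{RP days with } T_{min} \le T_C\}}
  {\#\text{RP days}}$$

(the inclusive $\le$ follows the defining formula of the statistic). The
detector fits

$$YF_t = \beta_0 + \beta_1 P_t(T_C) + \beta_2 R_t + e_t$$

by OLS at every candidate $T_C \in \{0.0, 0.1, \dots, 19.0\}$ °C and keeps
the candidate with the smallest $\beta_1$ p-value (two-sided $t$, $N-3$
degrees of freedom, residual-estimated error variance). Ties — p-values equal
to within a *relative* $10^{-12}$ — resolve to the largest candidate. A
relative rather than absolute tie tolerance matters: under a strong implanted
effect the p-value profile passes through values like $10^{-40}$, where an
absolute window would spuriously tie half the grid and the max-tie-break
would drag the estimate upward. Detection additionally requires
$p < 0.05$ and $q_1 \le T_C \le q_3$, the quartiles of the RP minima pooled
across years (linear-interpolation quantiles) — this keeps $P$ away from the
degenerate 0 %/100 % corners. Candidates whose design is rank deficient
($P$ constant across years) are unfittable and skipped; a constant-yield
response is reported as a null association ($\beta_1 = 0$, $p = 1$) rather
than letting rounding noise manufacture a t-statistic. No multiplicity
correction is applied across the 191 candidates; the selection criteria are
used verbatim.

At the selected threshold the model is refitted; $\hat\beta_1$ is the yield
change (kg/ha) per percentage-point increase in cold-day exposure with
rainfall held fixed. Across sites, detected thresholds are regressed on
latitude and longitude to describe spatial structure. The error variance in
the season regression is estimated from residuals; a fixed unit variance
would make kg/ha effect sizes dimensionally incoherent, so the normality
statement behind the model is read as generic.

# The synthetic study

## Generator

`synthetic_spec()` holds the whole design. Daily mean temperature is an
annual sinusoid (coldest mid-July at southern latitudes) plus a per-year
anomaly (sd 0.3 °C) plus an AR(1) daily anomaly (stationary sd 2.5 °C, lag-1
autocorrelation 0.7). The AR(1) persistence is load-bearing: real cold
arrives in multi-day synoptic spells, and it is precisely those spells that
give the cold-day percentage its year-to-year contrast near a threshold.
With iid daily noise the $P_t(T_C)$ columns across the candidate grid are
nearly collinear and the threshold location is barely identified; with
realistic spell structure it is sharply identified. The diurnal range is
constant in the mean (13 °C) with its own noise; rain is Bernoulli(0.28) ×
Gamma(1.2, 4.5) mm (≈ 550 mm/year); radiation is a deterministic seasonal
curve. The default site (35 °S, 147 °E, mean 16 °C, amplitude 8.5 °C) is a
frosty inland south-eastern Australian climate whose May-sown crop flowers in
late September — these values were calibrated once against that target
phenology and then frozen.

Annual potential yield is linear with a sharp implanted threshold:

$$Y_t = \gamma_0 + \gamma_2 R_t - \gamma_1 P_t(T_C^{true}) + \varepsilon_t,$$

defaults $\gamma_0 = 1000$ kg/ha, $\gamma_2 = 2$ kg/ha/mm,
$\gamma_1 = 5$ kg/ha per percentage point, $T_C^{true} = 10$ °C,
$\sigma_\varepsilon = 100$ kg/ha, floored at zero. The sharp threshold makes
parameter recovery well-posed; smooth (logistic) cold responses are a
deliberate non-goal of this version. All randomness derives from one master
seed through per-(year, component) substreams, so extending the year range
never perturbs earlier years, and every output is a pure function of the
spec.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis needs: seasonality with
a frost tail, persistent spells, variable season rainfall, bucket-plausible
FASW trajectories, and a known linear yield signal. It does **not** emulate
spatial correlation between sites, climate trends, crop physiology (biomass,
transpiration, nitrogen), disease, or smooth chilling responses. Passing
recovery tests therefore demonstrates that the *inference machinery* is
correct under its own assumptions — not that any real site has a sharp
10 °C threshold.

## Recovery experiments

Two seeded experiments close the loop (they are the heavyweight blocks of the
test suite; each uses 50 replicates of a 70-year study at the default site,
with the frost penalty disabled so the implanted linear truth is exact):

* **Recovery** — with $\gamma_1 = 5$ and noise 100, the detected threshold
  should fall within ±1 °C of the implanted 10 °C in at least 45 of 50
  replicates; and in a noise-free run the refitted $\hat\beta_1$ must equal
  $-5$ to $10^{-6}$ and the threshold must be recovered at the grid point.
* **Null control** — with $\gamma_1 = 0$ the detection rate must stay at or
  below 10 %, checking that the min-p selection plus the quartile band do
  not manufacture thresholds from noise.

The frost penalty is excluded from these two experiments because the
noise-free clause is only exactly attainable for the pure linear model; the
penalty's own contract is tested separately (exact 5 % single-event check,
monotonicity, homogeneity).

# Numerical choices

* Grid candidates are computed as `lo + step * 0:n` and rounded to 6
  decimals, so the nominal values (10.0, not 10.000000000000002) are carried
  through and reported.
* The modifier boundary is handled as described above, keeping
  TTm = TT exact at FASW ≤ 0.65.
* Quantiles everywhere are R's default type-7 (linear interpolation).
* KDE overlap uses `stats::density` with Silverman's rule, a shared
  day-1–366 grid, and a 1-day bandwidth fallback for degenerate (constant or
  singleton) samples.
* OLS goes through QR; the test suite cross-checks every fit against an
  independent normal-equations + closed-form-$t$ oracle to $10^{-8}$.
* RMSD uses the $N-1$ divisor as its defining convention here, with
  `divisor = "n"` available as an escape hatch; $R^2$ is the squared Pearson
  correlation, not regression-through-the-1:1-line $R^2$.
* Crops that fail to complete pod fill before the weather (or the 450-day
  horizon) ends are recorded with missing phenology fields and excluded from
  season records used in detection, rather than silently dropped.

# Problem sizes

The shipped experiments use one synthetic site with 70-year runs (50
replicates per experiment) for the recovery and null studies, 40 years for
the single-site end-to-end check, and 6–7 years for the determinism and
cardinality checks of the scenario orchestrator. These sizes keep the whole
suite comfortably reproducible on a laptop while leaving the recovery
experiments enough replicates for a meaningful frequency claim.

# Known limitations

* The min-p grid selection inherits winner's-curse scatter: neighbouring
  candidates' cold-day percentages are highly correlated, so when the
  implanted signal is moderate relative to yield noise the selected
  threshold can land a degree or more from the truth in a minority of
  replicates even though detection itself is near-certain. The recovery
  experiment in the test suite measures this frequency directly.
* The bucket water balance is a stand-in with a plausibility contract, not a
  calibrated soil model; its ET demand is a single temperature-scaled term.
* Germination is treated as immediate at sowing; the seed phase is driven by
  raw thermal time only.
* Day-of-year densities ignore year-boundary wrap-around.
* The yield model is linear with a sharp threshold by design; real chilling
  damage is certainly smoother.
* The spatial regression describes variation across synthetic sites; with
  fewer than three detecting sites it is not attempted.

# Reproducing the headline constants

`scripts/acceptance.R` (repository root) recomputes, from the installed
package, the two constants that define the soil-water modifier — the linear
multiplier's intercept recovered by extrapolating TTm/TT ratios to FASW = 0,
and the activation boundary recovered by scanning FASW in 0.01 steps — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
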