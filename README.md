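# chickcold

Cold temperature during the reproductive phase is a major yield constraint
for chickpea (*Cicer arietinum* L.): frost (screen minimum ≤ 0 °C) kills
flowers and pods outright, and milder "chilling" nights abort pod set well
above freezing. The temperature at which damage starts — the
cold-temperature threshold *T<sub>C</sub>* — varies from site to site.
`chickcold` is an R package for agronomists and crop modellers that
estimates *T<sub>C</sub>* and its yield cost from daily weather and annual
yields, and ships a synthetic-data generator with a known implanted
threshold so the whole pipeline is verifiable by parameter recovery.

## What it implements

**Phenology.** Daily thermal time (eight-point three-hourly interpolation
through a piecewise-linear response), modified by soil water and
photoperiod. Wet soil slows perceived thermal time:

```
TTm = TT × (1.65 − FASW)     when FASW > 0.65 and stage ≥ emergence
FASW = Σ(sw − ll15) / Σ(dul − ll15)   over the top 60 cm of the profile
```

plus an operational sowing rule (trailing 7-day rain ≥ 25 mm and
plant-available water > 80 mm, else the last day of the sowing window) and
stage prediction through emergence, flowering, peak flowering (mid-point of
the flowering span) and end of pod fill.

**Frost.** Post-flowering frost events (Tmin ≤ 0 °C during the reproductive
period) each remove ~5 % of yield — multiplicative by default, additive as a
sensitivity option — and frost risk is summarised as the kernel-density
overlap between frost timing and peak flowering across years.

**Threshold detection.** For seasons *t*, with *P<sub>t</sub>(T<sub>C</sub>)*
the percentage of reproductive-period days with minimum temperature at or
below a candidate threshold and *R<sub>t</sub>* the reproductive-period
rainfall, the model

```
YF_t = β0 + β1·P_t(T_C) + β2·R_t + e_t
```

is fitted by OLS at every candidate on the 0.0–19.0 °C grid (0.1 °C steps).
The candidate with the smallest β₁ p-value wins (ties go to the largest
threshold); detection requires p < 0.05 and the threshold to lie between the
quartiles of the pooled reproductive-period minima. β₁ is the yield change
(kg/ha) per percentage-point increase in cold-day exposure. Detected
thresholds across sites can be regressed on latitude and longitude.

**Evaluation.** RMSD (with the N−1 divisor), Willmott's index of agreement
*d*, and *R*² for simulated-vs-measured comparisons.

## Worked example

Run a 40-year synthetic study at the default site (a frosty inland
south-eastern Australian climate, implanted threshold 10 °C, chilling cost
5 kg/ha per percentage point) and detect the threshold:

```r
library(chickcold)

spec  <- synthetic_spec(years = 1980:2019, seed = 42)
study <- simulate_study(spec)   # weather → soil water → phenology → yields → detection

study$threshold
#> <tc_result> detected T_C = 10.5 C (beta1 = -8.38 kg/ha per %, p = 4.69e-06)
#>   quartile band of pooled RP minima: [8.04, 13.27] C

quantify_effect(study$records, study$threshold)
#>     tc    beta0  beta1 beta2  p_beta1
#>   10.5 1195.512 -8.384  1.68 4.69e-06

study$overlap
#>   overlap_coefficient n_frost_days n_years no_frost
#>                 0.183            4      40 FALSE
```

The detector recovers the implanted 10 °C threshold at 10.5 °C (one grid
neighbourhood away). The fitted β₁ ≈ −8.4 kg/ha per % says each additional
percentage point of cold reproductive-period days costs about 8 kg/ha; it
exceeds the implanted 5 because the frost penalty (active in this run)
removes additional yield in the same cold years. The overlap coefficient
0.18 reflects a site where frost timing only partially intersects peak
flowering. `autoplot(study$scan, study$threshold)` draws the p-value
profile across the candidate grid; `plot_frost_overlap()` draws the timing
densities.

Multi-site factorial runs (locations × cultivars × sowing windows) go
through `scenario_config()` / `read_scenario_config()` and
`run_scenarios()`, which also fits the spatial regression of detected
thresholds on latitude and longitude; `write_results()` emits deterministic
CSVs. An example YAML configuration ships in `inst/extdata/`.

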