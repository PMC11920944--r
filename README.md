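# fluxdebt

Hurricane impact and carbon recovery-debt analysis for mangrove
eddy-covariance data.

Coastal mangroves are among the densest carbon sinks on Earth, and
hurricanes periodically defoliate them. Given a multi-year half-hourly flux
record (NEE, shortwave radiation, air temperature) spanning a storm, plus an
8-day LAI series, `fluxdebt` quantifies **how long** each component of
carbon exchange stays perturbed and **how much carbon** the disturbance
costs before the ecosystem recaptures it — at the tower and, via LAI
scaling, across a landscape. It is written for ecosystem scientists working
with AmeriFlux-style tower data and MODIS-style LAI products.

The pipeline:

1. **Preprocess** — range-filter NEE to ±100 µmol CO₂ m⁻² s⁻¹, split
   day/night at Rg = 50 W m⁻², tile each year with 24-day periods from
   January 1, composite 8-day LAI to period maxima and gap-fill linearly.
2. **Response curves** — per period, fit daytime NEE with a
   Michaelis–Menten light response,
   `NEE = QY·Amax·Rg / (QY·Rg + Amax) + Reco`,
   and nighttime NEE with Lloyd–Taylor respiration,
   `Reco = rb · exp[E0 (1/(Tref−T0) − 1/(Tair−T0))]`
   (Tref = 15 °C, T0 = −46.02 °C), by bounded nonlinear least squares,
   refusing any period with under 40% data coverage.
3. **Impact detection** — relative non-stationarity `RN = dx / x̄` over
   trailing 45-period (~3-year) windows, with annual harmonics absorbed in
   the trend computation; impact thresholds are the 85th/90th/95th
   percentiles of |RN| over the whole record, and the impact duration is
   the days from landfall to the last exceedance.
4. **Landscape scaling** — least-squares scaling of each parameter onto
   exp(LAI) (or a log link), time since disturbance, stature class
   (scrub: LAI ≤ 4; tall: LAI > 4) and air temperature; per-pixel NEE
   reconstruction in LRC and LRC+TRC variants.
5. **Recovery debt** — `debt = Σ (NEE_post − mean NEE_pre)` in g C m⁻²
   per landfall-anniversary year (positive = debt, negative = enhanced
   capture), cumulative sums, and landscape totals in Mt C.

A synthetic flux-tower and landscape simulator with known ground truth
(`simulate_tower()`, `simulate_landscape()`, analytic `expected_debt()`)
makes every stage testable without any external download.

## Worked example

Simulate a tall-forest tower struck by a hurricane in September 2016
(45% LAI loss, 120-day e-folding recovery), fit per-period parameters, and
compute the recovery debt:

```r
library(fluxdebt)

cfg <- sim_config(n_years = 6, landfall_date = "2016-09-10",
                  lai_drop_frac = 0.45, lai_recovery_days = 120,
                  noise_sd = 0, missing_frac = 0, seed = 1)
sim  <- simulate_tower(cfg)
fits <- fit_period_curves(filter_range(sim$series), sim$calendar)
fits[fits$year == 2016 & fits$period %in% 10:12,
     c("year", "period", "qy", "amax", "reco", "rb", "e0")]
#>    year period     qy  amax  reco    rb    e0
#> 1  2016     10 -0.137 -32.1  7.49  3.22  107.   # periods before landfall
#> 2  2016     11 -0.137 -32.1  7.49  3.22  107.
#> 3  2016     12 -0.137 -28.7  6.68  2.87  107.   # post-storm canopy loss
```

The fitted Amax weakens from −32.1 to −28.7 µmol CO₂ m⁻² s⁻¹ in the first
post-landfall period (period 12 contains the September 10 landfall date),
and the respiration terms drop with it. The debt accounting:

```r
debt <- recovery_debt(sim$series, cfg$landfall_day)
debt
#>   year_since_landfall annual_debt cumulative_debt
#> 1                   1    17.8             17.8
#> 2                   2     0.678           18.5
#> 3                   3     0.0321          18.5
#> 4                   4     0.00150         18.5
attr(debt, "reference_nee")
#> [1] -4.7691   # mean pre-storm NEE, umol CO2 m-2 s-1
```

Year 1 carries a 17.8 g C m⁻² carbon debt (the sink weakened relative to
the −4.77 µmol m⁻² s⁻¹ pre-storm mean); by year 3 the canopy has
refoliated and annual debt is near zero. Under this generating law uptake
and respiration scale together with LAI, so their responses largely cancel
— decouple them (`default_param_law(resp_lai_coupling = 0.2)`) to explore
storms whose respiration stays elevated while uptake collapses, which
yields debts an order of magnitude larger.

For the landscape version, `validate_landscape_pipeline(n_pixels = 1000)`
runs two calibration towers, fits the scaling model across both stature
classes, reconstructs per-pixel NEE for a bimodal-LAI landscape in both
variants, and compares the resulting cumulative-debt trajectory with the
generating truth.

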