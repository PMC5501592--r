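# batpva

Climate-driven population viability analysis for forest bats.

Insectivorous bats of arid western North America — the package's reference
species is the fringed myotis (*Myotis thysanodes*) — are long-lived, breed
once a year, and usually raise a single pup, so their populations hinge on
adult females reproducing regularly. Field series from the Colorado Front
Range show the proportion of reproductively active females falling in hot,
dry years. `batpva` turns that observation into a quantitative question:
what happens to such a population over the rest of the century if climate
keeps trending?

The package implements, as tested and reusable functions:

* a four-class female-only Leslie-type matrix model
  (pups / yearlings / 2 yr / 3+ yr) with birth-pulse census, fertility
  entries `a_1j = S_j F_j / 2`, dominant eigenvalue λ, stable age
  distribution **w**, and −10 % finite-difference sensitivity and
  elasticity analysis (plus the analytic eigenvector elasticities
  `e_ij = (a_ij/λ) ∂λ/∂a_ij` as a cross-check);
* the binary logistic climate–fertility link
  `Pr{Y=1} = logit⁻¹(β₀ + β_T·T + β_P·P)` with packaged coefficients
  (2.6419, −0.2534, 0.0040), plus an IRLS fitter for new record tables;
* scenario drivers that turn climate inputs into per-year fertility series:
  stable conditions, yearly projected series with envelope corners, linear
  step ramps to a 2070 endpoint, and range-wide ensemble pooling over
  occurrence locations and climate models, with per-location fertility
  change tables (Δᵢ, Δ̄);
* a Monte Carlo engine: 10,000 replicates × 77 years (2009–2086 censuses)
  from 2,000 females, one triangular draw per vital rate, age class, year
  and replicate (demographic ±10 %; environmental fertility envelopes),
  reproducible per-replicate random streams, and Mean / % Change / Min /
  Max / SD summaries;
* synthetic-data generators for all external inputs (climate series,
  reproductive-status records, occurrence-climate tables), so the entire
  pipeline runs and is tested offline.

## Worked example

```r
library(batpva)

rates <- vital_rates()          # S_P = 0.64, S_A = 0.79, F_A = 0.85
A <- projection_matrix(rates)
eigen_analysis(A)
#> lambda = 1.000299
#> stable age distribution: 0.2473 0.1582 0.1250 0.4695

perturbation_analysis(A, "S_3plus")
#> S_3plus (a[4,4], -10%): sensitivity 0.4853, elasticity 0.3833

res <- run_simulation(simulation_config(stable_scenario(rates),
                                        n_runs = 10000L, seed = 1L))
res
#> Stable Population (stable): 10000 runs x 77 years, seed 1
#>   mean 2011 (+0.57%), min 818, max 4457, sd 432.6
```

λ ≈ 1.0003 says the baseline parameterisation is essentially stationary.
The elasticity line says survival of the 3+ class is the lever that moves
λ most — proportionally about 3.4× more than adult fertility. The Monte
Carlo row is the stable-conditions reference run: starting from 2,000
females the mean 2086 population is ~2,011 (+0.6 %), with wide replicate
spread (SD ≈ 433) from compounding vital-rate noise. Declining-fertility
scenarios are one line more:

```r
crash <- step_scenario(0.85, 0.70, name = "General model", rcp = "RCP8.5")
run_simulation(simulation_config(crash, n_runs = 10000L, seed = 1L))
#> General model (RCP8.5): 10000 runs x 77 years, seed 1
#>   mean 434 (-78.28%), min 174, max 989, sd 95.8
```

A fertility decline to 0.70 by 2070 — about 18 % — costs the population
nearly four-fifths of its size by 2086: small persistent fertility losses
compound over 77 years.

The numbered scripts under `analysis/` walk the full study:
`01_demography.R` (matrix, λ, elasticities), `02_fertility_model.R`
(logistic link and parameter recovery), `03_scenarios.R` (drivers and
fertility-change tables), `04_simulate.R` (multi-scenario Monte Carlo
report). Each writes its tables under `results/`.

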