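# popreconstruct

Bayesian reconstruction of an annual population series from incomplete
parish baptism and burial registers anchored to noisy census
benchmarks, with full posterior uncertainty.

## The problem and the model

Historical demographers who want an annual population series for the
pre-census era have two ingredients: parish registers of baptisms and
burials (incomplete, under-registered, and kept by a slowly growing set
of parishes) and occasional enumerated censuses (noisy, and themselves
in need of correction). Classical inverse projection welds these
together with deterministic corrections whose effect on the final
series is hard to audit and which produce no uncertainty statement.

This package treats the reconstruction as inference in one hierarchical
state-space model. With births β_t, deaths δ_t and military casualties
s_t, the latent population follows gamma transitions around the
accounting identity (shape–rate form):

```
μ_t ~ Gamma(ψ_μ (μ_{t-1} + β_t − δ_t − s_t), ψ_μ)
C_t ~ N(μ_t, σ_c²)                                 at census years
```

Vital totals are built from unit-level registers through logistic
coverage curves λ_t that absorb under-registration and the units with
no surviving records:

```
β_t = (Σ_{i∈Ω_t} b_{t,i} + Σ_{i∉Ω_t} b̂_{t,i}) / λ_t^b
b_{t,i} ~ Gamma(ψ_bd exp(ν_{t,i}), ψ_bd)
ν_{t,i} = ν_{t-1,i} + η_t + ε_{t,i},   η_t a common random-walk drift
```

Completely missing parish-years are imputed inside the model. One
configured crisis year gets special treatment: its transition is
replaced by μ_c ~ Gamma(ψ_μ π μ_{c-2}, ψ_μ) with a survival ratio π,
and its registered burials are inflated by a parish-level factor φ_d,
so a demographic catastrophe is neither smoothed away nor double
counted. Inference is by the No-U-Turn Sampler over a compiled joint
posterior, with split R-hat / ESS diagnostics, posterior predictive
checks, and derived quantities (growth-rate probabilities, crisis drop
magnitudes, peak and trough years, recovery years).

A generative simulator reproduces every stage — availability schedules,
coverage curves, crisis year, casualties, censuses — so the whole
pipeline is testable without historical data. See the vignette
(`vignettes/population-reconstruction.Rmd`) for the complete model,
priors and design choices.

## Worked example

```r
library(popreconstruct)

scen <- desk_scenario()            # 15 units, 80 years, 8 censuses, 1 crisis
ds   <- simulate_dataset(scen, seed = 42)
ds
#> synthetic population dataset (seed 42)
#> observed_data: 15 units (of 17 total), event years 1701 - 1779
#>   availability: baptisms 79%, burials 78%
#>   censuses: 8  casualties total: 1600

ft <- fit(ds$data, scen$config,
          fit_config(chains = 2, iter = 650, warmup = 300, seed = 7))

diagnostics(ft, quantities = c("pi", "lambda_end", "psi_bd", "sigma_c"))
#>     quantity     mean    q2.5    q97.5   ess rhat
#> 1    sigma_c 2436.649 691.235 5734.537  97.5 1.00
#> 2         pi    0.785   0.739    0.828 106.4 1.00
#> 3     psi_bd    0.328   0.300    0.358 121.1 1.00
#> 4 lambda_end    0.869   0.634    0.991 112.2 1.01
```

The survival ratio π (truth 0.78), the count dispersion ψ_bd (truth
0.33) and the terminal coverage λ (truth 0.85) are all recovered inside
their 95% intervals; the crisis-year drop follows directly:

```r
drop <- drop_magnitude(ft, 1724, 1725)
round(100 * c(drop$mean, drop$q2.5, drop$q97.5), 1)
#> [1] 20.9 16.4 25.6     # per cent; the generated drop was 20.9
```

`population_summary(ft)` tabulates the annual posterior mean and 95%
interval; `posterior_predictive(ft)` replays the generative path from
the posterior for a census-level calibration check;
`growth_rate_probabilities()`, `extremum_years()` and
`first_return_year()` compute the derived demographic statistics.

A command-line front end covering simulate / prepare / priors / fit /
analyze / ppc lives in `inst/cli/popreconstruct.R`:

```sh
Rscript inst/cli/popreconstruct.R simulate --config cfg.yaml --seed 9 --out data/
```

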