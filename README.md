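# chiraflux

Analysis of enantiomerically resolved monoterpene and isoprene emissions
from a semi-enclosed rainforest mesocosm under progressive drought.

Most atmospheric measurements and emission models pool the (−) and (+)
mirror forms of chiral monoterpenes, implicitly assuming identical sources.
Inside an enclosed tropical-rainforest mesocosm, however, the enantiomers
show *distinct* diel emission peaks: (−)-α-pinene and (−)-β-pinene track
assimilation and peak near noon (de novo synthesis from freshly assimilated
carbon), while (+)-α-pinene and (+)-limonene track temperature and vapour
pressure deficit and peak mid-afternoon (release from leaf lipid storage
pools). Under drought, the de novo compounds shift toward storage-pool
behaviour. `chiraflux` is the full analysis chain for such a campaign, for
ecosystem scientists and atmospheric chemists working with chamber or
mesocosm VOC data:

* **Air exchange & leakage correction** — the exchange rate ER (%/h) from
  log-linear fits of SF6 tracer decay, `ln(SF6 − bg) ~ t`, interpolated
  over the campaign; mixing ratios corrected as `VMRc = VMRu (1 + ER_frac)`.
* **Chamber CO2 budget** — NEE per 15-min step from the semi-enclosed mass
  balance (storage change + exchange, ideal-gas moles, uptake-positive),
  respiration from night-time NEE (PAR ≤ 0.1 μmol m⁻² s⁻¹), assimilation
  `A = NEE − R`, and `VPD = 0.6108 (1 − RH/100) e^{17.27T/(237.3+T)}` kPa.
* **Isotope source attribution** — 13C enrichment offsets
  `ε = R_pulse/R_ambient − 1` per compound and 13CO2 pulse, one-tailed
  Welch tests against the ambient scatter (α = 0.05), and de novo /
  storage / ambiguous classification; isoprene single-label fractions with
  the 5.5% (5 × 1.1%) natural-abundance background subtracted.
* **Diel analysis** — Savitzky–Golay trend smoothing with uncertainty
  propagation, day/night splitting, stage-resolved diel cycles (hourly bin
  means, moving median of 5, normalized to a unit global maximum), peak
  hours, drought proxies and enantiomer correlation matrices.
* **Two-reservoir emission model** — per enzyme group, synthesis
  `P = ε·(A/A_ref)` (light-activated groups) splits into direct emission
  `E_dn = (1−φ)P` and a lipid pool `dS/dt = φP − k_eff S` leaking as
  `E_store = k_eff S`, `k_eff = k0 e^{β(T−30°C)}(1 + γ·VPD)`; plus the
  pooled light × temperature baseline (`C_L · C_T` activity factors) it
  outperforms, and least-squares parameter estimation.
* **Synthetic mesocosm generator** — a seeded, self-consistent campaign
  (forcing, tracer, VMRs, CO2, isotope samples) with full ground truth, so
  every estimator above is testable end to end.

## Worked example

Simulate the default 105-day campaign (day of year 252–356, five stages:
pre-drought PD, early/severe drought ED/SD, deep-water rewet DRW, rain
rewet RRW) and run the whole pipeline:

```r
library(chiraflux)

report <- run_pipeline(pipeline_config("report", scenario = scenario_config(seed = 1)))

round(report$summary$er_mean_pct_per_h, 1)
#> [1] 149.6

report$source_classes[, 1:2]
#>          compound source_class
#>  (-)-alpha-pinene      de_novo
#>   (-)-beta-pinene      de_novo
#>      (-)-limonene      de_novo
#>      (-)-camphene      de_novo
#>   gamma-terpinene      de_novo
#>  (+)-alpha-pinene      storage
#>      (+)-limonene      storage
#>      (+)-camphene      storage

print(report$proxies[, 1:4], digits = 3)
#>  stage plus_a_over_minus_b afternoon_morning_ratio beta_pinene_fraction
#>     PD                5.93                   0.959               0.0565
#>     ED                1.81                   0.973               0.1666
#>     SD                2.09                   1.054               0.1746
#>    DRW                4.26                   1.146               0.1082
#>    RRW                3.61                   0.987               0.0999
```

Reading the output: the tracer fits recover the scenario's true exchange
rate (150 %/h). The 13CO2 pulse tests label every light-activated compound
de novo and every (+) compound storage — exactly the generator's truth. The
drought proxies move as drought proxies should: the (−)-β-pinene fraction
of total monoterpenes roughly triples from pre-drought to severe drought,
the (+)-α-pinene/(−)-β-pinene ratio falls with severity, and the
afternoon-to-morning ratio of (−)-α-pinene rises as its emission shifts
from noon-peaked de novo synthesis to afternoon storage release, then
relaxes after rewetting.

Each stage is also available as a standalone function (`fit_exchange_rate`,
`correct_vmr`, `nee_series`, `assimilation`, `epsilon13c`,
`enrichment_table`, `diel_cycle`, `drought_proxies`, `simulate_reservoir`,
`fit_reservoir`, `compare_to_baseline`, …); see the help pages and the
methods vignette (`vignettes/chiral-monoterpene-drought-pipeline.Rmd`) for
the models, parameter defaults and design decisions. A thin command-line
wrapper with `simulate` / `fit-er` / `budget` / `isotope` / `diel` /
`report` subcommands lives at `inst/scripts/chiraflux.R`.

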