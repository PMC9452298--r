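---
title: "Methods: chiral monoterpene emission analysis for an enclosed mesocosm drought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chiral monoterpene emission analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiraflux)
```

## The scientific problem

Monoterpene enantiomers — the (−) and (+) mirror forms of compounds such as
α-pinene — have identical physics and atmospheric chemistry but are made by
different terpene synthases, so their emissions can respond differently to
stress. In a semi-enclosed rainforest mesocosm under a controlled
multi-month drought, two diel emission types appear: compounds tracking
photosynthesis (peaking near noon, de novo synthesis from freshly
assimilated carbon) and compounds tracking temperature and vapour pressure
deficit (peaking mid-afternoon, released from leaf lipid storage pools).
13CO2 pulse labelling separates the two sources directly: de novo emissions
become transiently 13C-enriched, storage emissions do not.

`chiraflux` implements the full chain from raw mesocosm time series to
source-attributed, stage-resolved emission statistics, plus a forward
three-enzyme-group/two-reservoir emission model, and a synthetic campaign
generator that provides ground truth for every analysis stage.

## Pipeline stages and their models

### Air exchange from tracer decay

The enclosure leaks: an inert SF6 tracer injected to ~1000 ppt above its
~8 ppt background decays exponentially at the air-exchange rate ER. We fit
ordinary least squares to `ln(SF6 − background)` versus time
(`fit_exchange_rate()`), which is the closed-form maximum-likelihood
estimator under multiplicative measurement noise and matches the
exponential-decay model exactly. Window estimates are interpolated linearly
between window midpoints with constant end extrapolation
(`interpolate_er()`). Negative fitted slopes are clamped to ER = 0 with a
warning: a sealed volume cannot un-leak.

Mixing ratios are then corrected for leakage dilution as
`VMRc = VMRu × (1 + ER_frac)` (`correct_vmr()`), with incoming VOC assumed
negligible. The correction factor is dimensionless, so we interpret the
rate as the fraction of chamber air replaced during one sampling interval,
`ER[%/h]/100 × Δt[h]`; a series can be corrected only once (the function
refuses double correction).

### Chamber CO2 budget

Net ecosystem exchange per 15-min step is the storage change of CO2 moles
inside the enclosure plus the net moles imported by exchange, per soil
area (`nee_series()`). Moles come from the ideal gas law
(`moles_co2()`, R = 8.314 J mol⁻¹ K⁻¹). Two choices are deliberate:

* **Sign convention: uptake-positive.** With NEE positive for net
  ecosystem CO2 uptake, `A = NEE − R` gives positive daytime assimilation,
  which is the natural orientation for the light-response figures. The raw
  storage-plus-exchange numerator is therefore negated.
* **Exchange term discretization.** The outflow-minus-outside
  concentration difference uses the trapezoidal mean over the step rather
  than the endpoint value; this makes the discrete budget close against an
  integrated truth to well under a percent at a 15-min step.

Respiration R is the mean night-time NEE (night = PAR ≤ 0.1 μmol m⁻² s⁻¹,
strictly greater is day) computed per calendar day by default — a windowed
choice that tracks drought-driven respiration change — or as a single
campaign constant (`assimilation(window = "campaign")`). VPD uses the
Tetens-type form `0.6108 (1 − RH/100) e^{17.27T/(237.3+T)}` kPa.

### Isotope source attribution

GC-IRMS peak integration cannot give absolute δ13C for partially coeluting
compounds, so enrichment is a *relative* offset between pulse and ambient
ratios: `ε = R_pulse / R_ambient − 1` (`epsilon13c()`). We compute ε on
13C/12C ratios so that 13C uptake gives ε > 0; an inverted-ratio mode
(`orientation = "12/13"`) accepts 12C/13C inputs and still reports
enrichment-positive values. The ambient reference is the mean over all
ambient-context samples of a compound, and the ambient ε scatter defines
the no-label band.

Significance is a one-tailed, two-sample, unequal-variance (Welch) t-test
of pulse ε against ambient ε at α = 0.05 (`enrichment_test()`).
Classification (`classify_source()`): significant enrichment in any pulse →
de novo; never significant → storage; flagged ambiguous only when a pulse
just misses significance (p ≤ 0.1) *while* showing a mean enrichment above
twice the within-pulse scatter — an evidence-of-effect-short-on-samples
case, deliberately excluding ordinary null fluctuation near α.

The isoprene label fraction uses the field's linear background convention:
five carbons × 1.1% natural 13C = 5.5% singly-labelled background,
subtracted from the measured single/total ratio
(`isoprene_label_fraction()`). The exact binomial background (≈5.26%) is
available via `exact = TRUE` but off by default to match the linear
convention.

### Diel analysis

Long-term trends use a Savitzky–Golay filter (`smooth_trend()`); defaults
window 25 points, order 3, chosen to retain multi-day drought trends while
removing diel-scale fluctuation in hourly data. Uncertainties are
propagated through the same filter weights (including the edge rows of the
projection matrix), so smoothed values match `signal::sgolayfilt()`
exactly and the output variance of white noise is `Σw²` times the input
variance.

Diel cycles (`diel_cycle()`) are stage-grouped hour-of-day bin means,
smoothed with a centered moving median of window five (truncated at the
edges), and normalized by the maximum across **all** stage bins per
compound — the normalization is global, not per stage, so stages are
directly comparable and the global maximum bin is exactly 1.

Drought proxies (`drought_proxies()`): the (+)-α-pinene/(−)-β-pinene
ratio, the afternoon-to-morning ratio of (−)-α-pinene, and the
(−)-β-pinene fraction of the eight quantified monoterpenes. The
afternoon/morning windows are not fixed by the measurement protocol; we
use 13:00–17:00 and 08:00–12:00 (half-open) and document them in the
output.

Stage boundaries default to PD doy 252–280, drought 281–337 split into
ED/SD at doy 306 (the split is defined observationally by two
relative-humidity minima and is configurable), DRW from 337, RRW 347–356.
The deep-water-rewet band is extended to the start of RRW (doy 347) so the
five stages partition the campaign without gaps. The drought window is
kept at its doy boundaries (281–337) even though it is sometimes described
as 9.5 weeks; the doy span (8 weeks) is authoritative here.

## The two-reservoir emission model

Enzyme group 1 (isoprene synthase) and group 2 ((−)-α-pinene,
(−)-β-pinene) are light-activated; group 3 ((+)-α-pinene, (+)-limonene)
synthesizes continuously without light activation. Per group, synthesis

> P = ε · (A/A_ref if light-activated, else 1) · (1 + s·stress)

splits into direct (de novo) emission `E_dn = (1 − φ_eff) P` and filling of
a lipid storage pool, `dS/dt = φ_eff P − k_eff S`, which leaks as
`E_store = k_eff S` with

> k_eff = k0 · exp(β (T − 30 °C)) · (1 + γ·VPD).

Synthesis equals emission plus pool change at every instant. The published
description of this model is conceptual, so first-order pool kinetics with
an exponential temperature response is our minimal concrete mechanism; its
defaults are set by the two observed diel peak windows:

| parameter | default | units | why |
|---|---|---|---|
| k0 | 0.02 | h⁻¹ | ~2-day pool turnover keeps S quasi-constant within a day, so storage release tracks k(T) and peaks with mid-afternoon temperature |
| β | 0.09 | K⁻¹ | standard storage-emission temperature sensitivity from the emission-model literature |
| γ | 0.3 | kPa⁻¹ | mild VPD enhancement of release under dry air |
| φ (group 2) | 0.10 | – | pre-drought group-2 emission is predominantly de novo, with a small stored fraction; larger φ drags the group-2 diel peak past noon |
| φ (group 3) | 1 | – | group-3 products partition wholly to the lipid pool |
| t_ref | 30 | °C | mid-range of the daytime enclosure temperature |

Integration is fixed-step RK4 at the forcing resolution with inputs
interpolated linearly at half steps; the pool is clamped non-negative.

Two open modelling questions were decided as follows:

* **Does drought increase storage filling, or only release?** Filling
  increases (φ_eff moves from φ towards φ_stress with stress). At
  quasi-steady state release equals filling, so a release-only modifier
  cannot raise total emission under drought; observed severe-drought
  increases therefore require the filling (or synthesis) route. Both knobs
  remain configurable per compound.
* **Drought modifiers.** De novo synthesis scales with normalized
  assimilation A/A_ref; release scales with (1 + γ·VPD) — the simplest
  forms consistent with emissions becoming "less de novo, more storage" as
  drought progresses.

The pooled baseline (`g93_emission()`) is the canonical light × temperature
activity-factor model: `C_L = α c_L1 L/√(1+α²L²)` and the exponential /
logistic `C_T`, with standard constants (α = 0.0027, c_L1 = 1.066,
c_T1 = 95 000 J mol⁻¹, c_T2 = 230 000 J mol⁻¹, T_s = 303 K, T_M = 314 K).
Because `C_L` vanishes at night and both factors peak between the light and
temperature maxima, this baseline can reproduce neither the distinct
noon/afternoon enantiomer peaks nor their drought shift —
`compare_to_baseline()` quantifies that as per-stage observed/predicted
ratios and peak-hour offsets.

`fit_reservoir()` estimates (ε, φ, k0, β) for one group by
Levenberg–Marquardt least squares on transformed scales (log for rates,
logit for φ) with seeded multi-start. With φ = 0 the pool never fills and
k0/β are structurally unidentifiable; the fit then reduces to the linear ε
scale and says so. Flat observations are refused as unidentifiable.

## What the synthetic campaign emulates — and what it does not

`gen_campaign()` composes: deterministic diel forcing with a seeded
day-to-day cloudiness factor; a five-stage drought trajectory (topsoil
moisture 35% → 26% before drought onset, → 15% by end of severe drought,
recovering after rain; two depressed RH minima during the drought); SF6
injections decaying at the true exchange rate; per-compound two-reservoir
emissions driven by the true assimilation and a soil-moisture stress index;
an explicit-Euler chamber mass balance
`dC/dt = e − ER(C − C_out) − v_d·C` at 1-min substeps (15-min output,
hourly VOC averages); a CO2 balance driven by the true NEE; and 13CO2
pulse samples in the campaign's five contexts (ambient/pulse 1/post 1/
pulse 2/post 2 with 5/16/36/11/14 cartridges).

Default conditions follow the campaign design where stated: doy 252–356,
PAR peaking at noon with a 12-h photoperiod, temperature 28–32 °C by day
and 21–24 °C at night peaking at 14:30, pressure 89 kPa (the site sits at
~1.2 km elevation), 27 700 m³ volume over 1950 m² of soil, tracer
background 8 ppt with ~1000 ppt injections, two morning labelling pulses
(pre-drought and severe drought, the second larger to offset reduced
assimilation). Quantities the campaign description leaves open were fixed
once at field-plausible values and documented here:

* **Exchange rate 150 %/h (constant by default).** A continually flushed
  enclosure with a ~40-min residence time; fast enough that hourly mixing
  ratios track emissions with sub-hour lag, which is required for the
  observed noon-vs-afternoon VMR peak separation to be visible in
  concentrations at all. A parametric diel profile (amplitude, peak hour)
  is available.
* **Drought modulation magnitudes.** Per-compound stress responses
  (synthesis multipliers `s_stress`, stressed storage fractions
  `phi_stress`) are tuned once so the campaign reproduces the qualitative
  drought pattern: an early-drought concentration peak followed by a
  larger severe-drought peak, a roughly threefold rise of the
  (−)-β-pinene fraction, the (+)/(−) proxy ratio falling with severity,
  and the severe-drought shift of group-2 diel peaks into the afternoon.
* **Noise model.** Multiplicative lognormal noise on hourly VMRs
  (5% default, instrument-style relative uncertainty), additive Gaussian
  on CO2 (0.2 ppm), multiplicative on the tracer excess (2%), and 0.3%
  relative noise on isotope ratios. Ambient δ13C is −28‰ vs VPDB; pulse
  enrichments (ε = 3% and 5%) wash out post-pulse at the chamber exchange
  rate. All noise derives from the scenario seed; identical seed and
  config give bit-identical campaigns.
* **Ecosystem carbon truth.** Assimilation is light-saturating in PAR
  (half-saturation 400 μmol m⁻² s⁻¹, maximum 4 μmol m⁻² s⁻¹ ground-area
  basis) scaled by a soil-moisture factor; respiration is constant
  (1.5 μmol m⁻² s⁻¹). The chamber CO2 conversion uses a fixed reference
  air temperature: the air-density modulation by the diel temperature
  cycle is deliberately neglected so the mass-balance oracle is exact up
  to discretization.

The generator does **not** emulate: canopy gradients or turbulence
(perfectly mixed single volume), species-resolved plant behaviour
(ecosystem-aggregate emissions only), chromatographic artifacts and
coelution (isotope ratios arrive as clean numbers; the real GC-IRMS
integration caveat is handled by using relative ε offsets, not modelled),
instrument drift/gaps, or atmospheric chemistry (the enclosure blocks the
UV needed for OH formation). Passing tests therefore demonstrate that the
pipeline's estimators recover known truths under the stated statistical
structure — not that the generator's parameter values match the real
campaign's instrument record, whose headline concentrations are not
reproducible at desk scale.

## Numerical choices and degenerate inputs

* Chamber integration: explicit Euler, 1-min substeps — adequate because
  the fastest rate (ER = 1.5 h⁻¹) gives a step Courant number of 0.025.
* Reservoir integration: RK4 at the 15-min forcing step.
* Day/night split: strictly PAR > 0.1 μmol m⁻² s⁻¹ is day; PAR exactly at
  the threshold is night; missing PAR excludes the point and is counted.
* Diel peak ties break to the earliest hour and are flagged; all-equal
  cycles are flagged degenerate.
* Moving-median edges use truncated (shrinking) windows.
* Zero denominators in proxies and observed/predicted ratios return NA
  with a named flag, never silent zeros.
* Tracer fits require ≥5 points above background; logs of non-positive
  excess are refused as data errors.
* Fits are deterministic: multi-start perturbations use a caller-supplied
  seed, and generator/fit functions restore the caller's RNG state.

Problem sizes used in the shipped tests and acceptance script: the full
105-day campaign at 15-min resolution (10 080 forcing steps, nine
compounds) for end-to-end checks, and 10 pre-drought days (960 steps) for
model fitting and peak-timing runs.

## Known limitations

* The exchange-rate correction is the linear `VMRu × ER_frac` convention;
  for large per-interval exchange fractions an exponential correction
  would differ, but the linear form is retained as the field convention.
* `fit_reservoir()` fits one enzyme group at a time against a single
  observed series; joint multi-compound fits with shared pool parameters
  are out of scope.
* Respiration from night-time NEE assumes night respiration represents
  the full day (the standard tropical-forest assumption); no temperature
  correction of R is applied.
* The stage partition assumes stages are a function of day of year only.
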