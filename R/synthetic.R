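#' Default compound table for the synthetic mesocosm
#'
#' One row per measured compound, mapping each to its enzyme group and
#' giving its synthesis capacity (`epsilon`, chamber-mean mixing-ratio units
#' per hour, here ppt/h), storage behaviour and first-order soil-uptake
#' velocity (`vd`, 1/h). `phi_stress` and `s_stress` are the drought
#' modifiers: under full stress the storage fraction moves from `phi` to
#' `phi_stress` and synthesis is multiplied by `(1 + s_stress)`. The strong
#' `s_stress` of (-)-beta-pinene reproduces its disproportionate
#' severe-drought rise (and hence the rising beta-pinene fraction drought
#' proxy); group-3 compounds get a moderate stress boost so that storage
#' emissions rise under drought.
#'
#' @return data.frame, one row per compound.
#' @export
default_compounds <- function() {
  data.frame(
    compound = c("isoprene",
                 "(-)-alpha-pinene", "(-)-beta-pinene", "(-)-limonene",
                 "(-)-camphene", "gamma-terpinene",
                 "(+)-alpha-pinene", "(+)-limonene", "(+)-camphene"),
    group = c(1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
    epsilon = c(500000, 1200, 240, 200, 120, 100, 500, 240, 100),
    phi = c(0, 0.10, 0.10, 0.10, 0.10, 0.10, 1, 1, 1),
    phi_stress = c(0, 0.70, 0.80, 0.70, 0.70, 0.70, 1, 1, 1),
    s_stress = c(0, 3, 25, 3, 3, 3, 2, 2, 2),
    vd = c(0.15, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration for the synthetic mesocosm campaign
#'
#' Bundles every knob of the synthetic campaign: the diel forcing, the
#' five-stage drought trajectory, the tracer injections, the chamber
#' exchange, the compound table driving the two-reservoir emission model and
#' the 13CO2 labelling pulses. Defaults emulate the enclosed-rainforest
#' drought experiment: 15-min forcing over doy 252--356, PAR peaking at
#' noon, temperature 28--32 degC by day / 21--24 degC by night peaking at
#' 14:30, topsoil moisture declining 35% -> 26% before the drought and to
#' 15% by the end of severe drought, two depressed RH minima during the
#' drought, SF6 injections of ~1000 ppt over an 8 ppt background, and two
#' morning 13CO2 pulses (pre-drought and severe drought).
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param doy_start,doy_end campaign window, day of year.
#' @param dt_min forcing time step, minutes.
#' @param stage_boundaries stage list ([default_stage_boundaries()]).
#' @param par_peak_hour,par_max,daylength_h,cloud_sd PAR forcing: peak hour,
#'   clear-sky amplitude (umol m-2 s-1), photoperiod (h) and lognormal sd of
#'   the day-to-day cloudiness factor.
#' @param temp_peak_hour,day_temp_range,night_temp_range temperature
#'   forcing, degrees C.
#' @param rh_base,rh_temp_coef,rh_dips relative humidity model: baseline %,
#'   anti-correlation slope with temperature (%/K), and a data.frame
#'   (`center`, `depth`, `width`, in doy/%/days) of Gaussian drought
#'   depressions giving the two RH minima.
#' @param soil_moisture_nodes data.frame (`doy`, `sm`) interpolated linearly
#'   for topsoil volumetric moisture (%).
#' @param pressure air pressure, Pa.
#' @param volume,area enclosure volume (m3) and soil surface area (m2).
#' @param er_mean_pct_per_h,er_diel_amp,er_peak_hour true air-exchange-rate
#'   profile: `ER(t) = mean * (1 + amp * cos(2*pi*(hour - peak)/24))` in %/h.
#'   The default is a constant 150 %/h (a continually flushed enclosure with
#'   a ~40-min residence time, fast enough that mixing ratios track
#'   emissions); a nonzero `er_diel_amp` lets ventilation follow the
#'   afternoon heat load.
#' @param tracer_background,tracer_delta,tracer_injection_doys,tracer_injection_hour,tracer_noise_sd
#'   SF6 tracer: background (ppt), injected concentration step (ppt),
#'   injection times and multiplicative noise sd.
#' @param co2_outside,co2_noise_sd,t_ref_air outside CO2 (ppm), additive
#'   noise sd (ppm) and the fixed reference air temperature (degC) used for
#'   the chamber air-density conversion.
#' @param a_max,par_half,resp ecosystem CO2 truth: light-saturated
#'   assimilation (umol m-2 s-1), PAR half-saturation and respiration.
#' @param sm_hi,sm_lo,f_min soil-moisture-to-assimilation mapping: f_A
#'   declines linearly from 1 at `sm_hi` to `f_min` at/below `sm_lo`;
#'   drought stress is `1 - f_A`.
#' @param compounds compound table ([default_compounds()]).
#' @param k0,beta,gamma_vpd,t_ref shared lipid-pool kinetics (see
#'   [reservoir_params()]).
#' @param vmr_noise_sd multiplicative (lognormal) relative noise on hourly
#'   VMRs.
#' @param pulses data.frame (`doy`, `hour`, `duration_h`, `epsilon`) of
#'   13CO2 pulses; `epsilon` is the peak relative 13C enrichment imparted to
#'   de novo emissions.
#' @param isotope_counts named integer vector of cartridge counts per
#'   context (`ambient, pulse1, post1, pulse2, post2`).
#' @param delta13c_ambient ambient compound delta13C, per mil vs VPDB.
#' @param isotope_noise_sd relative sd of isotope-ratio measurement noise.
#' @param chamber_substep_min Euler substep for the chamber balance, minutes.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1,
    doy_start = 252, doy_end = 356, dt_min = 15,
    stage_boundaries = default_stage_boundaries(),
    par_peak_hour = 12, par_max = 800, daylength_h = 12, cloud_sd = 0.1,
    temp_peak_hour = 14.5,
    day_temp_range = c(28, 32), night_temp_range = c(21, 24),
    rh_base = 80, rh_temp_coef = 2.5,
    rh_dips = data.frame(center = c(300, 327), depth = c(25, 35),
                         width = c(10, 9)),
    soil_moisture_nodes = data.frame(
      doy = c(252, 281, 337, 347, 350, 357),
      sm = c(35, 26, 15, 15, 30, 32)),
    pressure = 89000,
    volume = 27700, area = 1950,
    er_mean_pct_per_h = 150, er_diel_amp = 0, er_peak_hour = 14.5,
    tracer_background = 8, tracer_delta = 1000,
    tracer_injection_doys = seq(253, 353, by = 10),
    tracer_injection_hour = 10, tracer_noise_sd = 0.02,
    co2_outside = 415, co2_noise_sd = 0.2, t_ref_air = 28,
    a_max = 4, par_half = 400, resp = 1.5,
    sm_hi = 26, sm_lo = 13, f_min = 0.15,
    compounds = default_compounds(),
    k0 = 0.02, beta = 0.09, gamma_vpd = 0.3, t_ref = 30,
    vmr_noise_sd = 0.05,
    pulses = data.frame(doy = c(278, 327), hour = c(8, 9),
                        duration_h = c(4, 5.2), epsilon = c(0.03, 0.05)),
    isotope_counts = c(ambient = 5, pulse1 = 16, post1 = 36,
                       pulse2 = 11, post2 = 14),
    delta13c_ambient = -28, isotope_noise_sd = 0.003,
    chamber_substep_min = 1) {
  cfg <- as.list(environment())
  # validate: stage_partition() errors on overlapping/unordered boundaries
  stage_partition(doy_start, stage_boundaries)
  if (er_diel_amp < 0 || er_diel_amp > 1) {
    stop("`er_diel_amp` must lie in [0, 1] (exchange rate must stay >= 0)")
  }
  rates <- c(cfg$er_mean_pct_per_h,
             cfg$par_max, cfg$cloud_sd, cfg$tracer_noise_sd, cfg$co2_noise_sd,
             cfg$a_max, cfg$par_half, cfg$resp, cfg$k0, cfg$beta,
             cfg$gamma_vpd, cfg$vmr_noise_sd, cfg$isotope_noise_sd,
             compounds$epsilon, compounds$vd)
  if (any(rates < 0)) stop("all rates in a scenario must be >= 0")
  if (doy_end <= doy_start) stop("`doy_end` must exceed `doy_start`")
  class(cfg) <- "scenario_config"
  cfg
}

# Regular 15-min campaign time grid for a config.
campaign_grid <- function(config) {
  step_d <- config$dt_min / 1440
  doy <- seq(config$doy_start, config$doy_end + 1 - step_d, by = step_d)
  list(time = doy_to_time(doy), doy = doy, hour = (doy %% 1) * 24,
       dt_h = config$dt_min / 60)
}

#' Generate the synthetic environmental forcing series
#'
#' Deterministic diel cycles plus a seeded day-to-day cloudiness factor:
#' PAR is a clipped half-sinusoid peaking at `par_peak_hour` and zero at
#' night; temperature is a sinusoid between the day and night range
#' midpoints peaking at `temp_peak_hour`; RH is anti-correlated with
#' temperature and depressed by two Gaussian dips during the drought; soil
#' moisture follows the configured piecewise-linear trajectory.
#'
#' @param config a [scenario_config()].
#' @return data.frame `time, doy, hour, par, temp, rh, pressure,
#'   soil_moisture, stage` at `dt_min` resolution.
#' @export
gen_forcing <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  g <- campaign_grid(config)
  n_days <- floor(config$doy_end) - floor(config$doy_start) + 1
  cloud <- with_seed(config$seed,
                     exp(stats::rnorm(n_days, 0, config$cloud_sd)))
  day_idx <- floor(g$doy) - floor(config$doy_start) + 1

  sunrise <- config$par_peak_hour - config$daylength_h / 2
  par <- config$par_max * cloud[day_idx] *
    pmax(0, sin(pi * (g$hour - sunrise) / config$daylength_h))

  t_max <- mean(config$day_temp_range)
  t_min <- mean(config$night_temp_range)
  t_mean <- (t_max + t_min) / 2
  t_amp <- (t_max - t_min) / 2
  temp <- t_mean + t_amp * cos(2 * pi * (g$hour - config$temp_peak_hour) / 24)

  dip <- rep(0, length(g$doy))
  for (i in seq_len(nrow(config$rh_dips))) {
    d <- config$rh_dips[i, ]
    dip <- dip + d$depth * exp(-((g$doy - d$center) / d$width)^2)
  }
  rh <- pmin(100, pmax(2, config$rh_base -
                         config$rh_temp_coef * (temp - t_mean) - dip))

  sm <- stats::approx(config$soil_moisture_nodes$doy,
                      config$soil_moisture_nodes$sm,
                      xout = g$doy, rule = 2)$y

  data.frame(
    time = g$time, doy = g$doy, hour = g$hour,
    par = par, temp = temp, rh = rh,
    pressure = config$pressure, soil_moisture = sm,
    stage = stage_partition(g$doy, config$stage_boundaries)
  )
}

#' Generate the SF6 tracer series
#'
#' After each injection the above-background concentration decays as
#' `exp(-integral of ER dt)`; multiplicative lognormal noise is applied on
#' the above-background excess (noise-free when `tracer_noise_sd = 0`).
#'
#' @param config a [scenario_config()].
#' @param er_pct_per_h true exchange rate, %/h; scalar, per-grid-point
#'   vector, or `NULL` to use the config value.
#' @return data.frame `time, doy, hour, sf6, injection` (ppt; logical flag).
#' @export
gen_tracer <- function(config = scenario_config(), er_pct_per_h = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  g <- campaign_grid(config)
  n <- length(g$doy)
  er <- er_series_from_config(config, g$doy, er_pct_per_h)
  if (any(er < 0)) stop("exchange rate must be >= 0")
  bg <- config$tracer_background
  inj_doys <- config$tracer_injection_doys + config$tracer_injection_hour / 24
  inj_doys <- inj_doys[inj_doys >= min(g$doy) & inj_doys <= max(g$doy)]
  if (length(inj_doys) == 0) stop("no tracer injection falls inside the campaign window")
  inj_idx <- vapply(inj_doys, function(d) which.min(abs(g$doy - d)),
                    integer(1))
  injection <- seq_len(n) %in% inj_idx
  excess <- numeric(n)
  if (injection[1]) excess[1] <- config$tracer_delta
  for (i in 2:n) {
    excess[i] <- excess[i - 1] * exp(-er[i - 1] / 100 * g$dt_h)
    if (injection[i]) excess[i] <- excess[i] + config$tracer_delta
  }
  if (config$tracer_noise_sd > 0) {
    fac <- with_seed(config$seed + 1,
                     exp(stats::rnorm(n, 0, config$tracer_noise_sd)))
    excess <- excess * fac
  }
  data.frame(time = g$time, doy = g$doy, hour = g$hour,
             sf6 = bg + excess, injection = injection)
}

#' Tracer enrichment factor of an injection
#'
#' Ratio of the post-injection concentration to background; an injection
#' bringing the chamber to ~1 ppb SF6 over an ~8 ppt background is a
#' 125-fold enrichment.
#'
#' @param c0 concentration immediately after injection (same units as
#'   `background`).
#' @param background background concentration (> 0).
#' @return dimensionless enrichment factor.
#' @export
tracer_enrichment_factor <- function(c0, background) {
  if (any(background <= 0)) stop("`background` must be positive")
  c0 / background
}

#' Integrate the chamber mixing-ratio mass balance
#'
#' Explicit-Euler integration of
#' `dC/dt = e - ER * (C - c_out) - vd * C`
#' where `e` is the chamber-mean emission rate in mixing-ratio units per
#' hour, `ER` the fractional air-exchange rate (1/h) and `vd` a first-order
#' deposition (soil uptake) sink (1/h). Inputs given at the output grid are
#' interpolated linearly across `substeps` Euler substeps per grid interval.
#'
#' @param time output time grid (POSIXct, equally spaced).
#' @param emission,er_frac_h,vd per-grid-point (or scalar) rates.
#' @param c_out incoming-air mixing ratio.
#' @param c0 initial concentration; default is the steady state at the
#'   first step.
#' @param substeps Euler substeps per grid interval.
#' @return numeric vector of concentrations at `time`.
#' @export
chamber_balance <- function(time, emission, er_frac_h, vd = 0, c_out = 0,
                            c0 = NULL, substeps = 15) {
  n <- length(time)
  emission <- rep_len(emission, n)
  er_frac_h <- rep_len(er_frac_h, n)
  vd <- rep_len(vd, n)
  dt_h <- as.numeric(diff(time), units = "hours")[1]
  h <- dt_h / substeps
  loss1 <- er_frac_h[1] + vd[1]
  if (is.null(c0)) {
    c0 <- if (loss1 > 0) {
      (emission[1] + er_frac_h[1] * c_out) / loss1
    } else 0
  }
  conc <- numeric(n)
  conc[1] <- c0
  cc <- c0
  for (i in seq_len(n - 1)) {
    for (j in seq_len(substeps)) {
      w <- (j - 1) / substeps
      e <- emission[i] * (1 - w) + emission[i + 1] * w
      er <- er_frac_h[i] * (1 - w) + er_frac_h[i + 1] * w
      vdd <- vd[i] * (1 - w) + vd[i + 1] * w
      cc <- cc + h * (e - er * (cc - c_out) - vdd * cc)
    }
    conc[i + 1] <- cc
  }
  conc
}

# Resolve the configured true exchange-rate profile on a doy grid.
er_series_from_config <- function(config, doy, override = NULL) {
  if (!is.null(override)) {
    return(rep_len(override, length(doy)))
  }
  hour <- (doy %% 1) * 24
  config$er_mean_pct_per_h *
    (1 + config$er_diel_amp * cos(2 * pi * (hour - config$er_peak_hour) / 24))
}

#' True ecosystem carbon state implied by a scenario
#'
#' The generator's ground-truth carbon terms: assimilation is
#' light-saturating in PAR (`a_max * PAR / (PAR + par_half)`) scaled by a
#' soil-moisture factor `f_a` that declines linearly from 1 at `sm_hi` to
#' `f_min` at `sm_lo`; NEE (uptake-positive) subtracts the constant
#' respiration; drought stress is `1 - f_a`. These series drive the
#' synthetic emissions and CO2 and serve as recovery oracles.
#'
#' @param config a [scenario_config()].
#' @param forcing forcing from [gen_forcing()] for the same config.
#' @return list `a`, `nee` (umol m-2 s-1), `stress`, `f_a`, aligned with
#'   `forcing`.
#' @export
ecosystem_truth <- function(config, forcing) {
  f_a <- pmin(1, pmax(config$f_min,
                      (forcing$soil_moisture - config$sm_lo) /
                        (config$sm_hi - config$sm_lo)))
  a <- config$a_max * forcing$par / (forcing$par + config$par_half) * f_a
  list(a = a, nee = a - config$resp, stress = 1 - f_a, f_a = f_a)
}

#' Generate a full synthetic campaign with ground truth
#'
#' Composes the forcing, the true exchange-rate profile, the SF6 tracer, the
#' two-reservoir emissions for every compound, the chamber mass balance
#' (15-min, averaged to hourly VOC mixing ratios with multiplicative noise),
#' the chamber CO2 balance (15-min, additive noise) and the 13CO2
#' pulse-labelling isotope samples. De novo compounds (enzyme groups 1--2)
#' become transiently 13C-enriched during/after each pulse with a washout
#' set by the chamber exchange rate; storage compounds (group 3) retain
#' ambient ratios.
#'
#' @param config a [scenario_config()].
#' @return list with elements `forcing`, `tracer`, `vmr` (named list of
#'   hourly per-compound data.frames: `time, doy, hour, vmr, uncertainty,
#'   compound, unit`), `co2` (15-min `time, co2_inside, co2_outside`),
#'   `isotope_samples` (`compound, context, time, doy, ratio_13_12`) and
#'   `truth` (true ER series, true emissions, per-interval-mean and
#'   instantaneous NEE, assimilation, stress, source class per compound).
#' @export
gen_campaign <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  forcing <- gen_forcing(config)
  g <- campaign_grid(config)
  er_pct <- er_series_from_config(config, g$doy)
  er_frac_h <- er_pct / 100
  tracer <- gen_tracer(config)
  ct <- ecosystem_truth(config, forcing)

  cmp <- config$compounds
  params <- data.frame(
    group = cmp$group, label = cmp$compound,
    light_activated = cmp$group %in% c(1L, 2L),
    epsilon = cmp$epsilon, phi = cmp$phi,
    k0 = config$k0, beta = config$beta, gamma_vpd = config$gamma_vpd,
    t_ref = config$t_ref, s_stress = cmp$s_stress,
    phi_stress = cmp$phi_stress, stringsAsFactors = FALSE
  )
  a_ref <- max(ct$a[forcing$stage == "PD"], na.rm = TRUE)
  emis <- simulate_reservoir(params, forcing, a = ct$a, a_ref = a_ref,
                             stress = ct$stress)

  substeps <- max(1L, round(config$dt_min / config$chamber_substep_min))
  vmr <- list()
  noise_seed <- config$seed + 2
  for (k in seq_len(nrow(cmp))) {
    ek <- emis[emis$label == cmp$compound[k], ]
    e_tot <- ek$e_dn + ek$e_store
    vd_k <- if (cmp$group[k] == 1L) {
      # soil uptake of isoprene weakens as the topsoil dries
      cmp$vd[k] * forcing$soil_moisture / forcing$soil_moisture[1]
    } else {
      rep(cmp$vd[k], nrow(forcing))
    }
    conc <- chamber_balance(forcing$time, e_tot, er_frac_h, vd = vd_k,
                            c_out = 0, substeps = substeps)
    hm <- hourly_mean(forcing$time, conc)
    v <- hm$value
    if (config$vmr_noise_sd > 0) {
      fac <- with_seed(noise_seed + k,
                       exp(stats::rnorm(length(v), 0, config$vmr_noise_sd)))
      v <- v * fac
    }
    vmr[[cmp$compound[k]]] <- data.frame(
      time = hm$time, doy = frac_doy(hm$time),
      hour = (frac_doy(hm$time) %% 1) * 24,
      vmr = v, uncertainty = v * config$vmr_noise_sd,
      compound = cmp$compound[k], unit = "ppt",
      stringsAsFactors = FALSE
    )
  }

  # chamber CO2 balance driven by the true NEE (fixed air-density reference)
  n_air <- config$volume * config$pressure /
    (8.314 * (273.15 + config$t_ref_air))
  conv <- config$area * 3600 / n_air   # ppm/h per (umol m-2 s-1) uptake
  n <- nrow(forcing)
  co2 <- numeric(n)
  co2[1] <- config$co2_outside
  h <- g$dt_h / substeps
  nee_step <- numeric(n - 1)
  cc <- co2[1]
  for (i in seq_len(n - 1)) {
    acc <- 0
    for (j in seq_len(substeps)) {
      w <- (j - 1) / substeps
      u <- ct$nee[i] * (1 - w) + ct$nee[i + 1] * w
      er <- er_frac_h[i] * (1 - w) + er_frac_h[i + 1] * w
      cc <- cc + h * (-conv * u + er * (config$co2_outside - cc))
      acc <- acc + u
    }
    nee_step[i] <- acc / substeps
    co2[i + 1] <- cc
  }
  if (config$co2_noise_sd > 0) {
    co2 <- co2 + with_seed(config$seed + 100,
                           stats::rnorm(n, 0, config$co2_noise_sd))
  }
  co2_df <- data.frame(time = forcing$time, doy = forcing$doy,
                       co2_inside = co2, co2_outside = config$co2_outside)

  isotope <- gen_isotope_samples(config, er_frac_h_mean = mean(er_frac_h))

  source_class <- ifelse(cmp$group %in% c(1L, 2L), "de_novo", "storage")
  names(source_class) <- cmp$compound

  list(
    forcing = forcing, tracer = tracer, vmr = vmr, co2 = co2_df,
    isotope_samples = isotope,
    truth = list(
      er_pct_per_h = data.frame(time = forcing$time, doy = forcing$doy,
                                er_pct_per_h = er_pct),
      emissions = emis,
      nee = data.frame(time = forcing$time, nee_inst = ct$nee,
                       nee_step = c(NA_real_, nee_step)),
      a = data.frame(time = forcing$time, a = ct$a),
      a_ref = a_ref,
      stress = ct$stress,
      source_class = source_class,
      n_air_mol = n_air
    )
  )
}

# 13CO2 pulse-labelling samples. De novo compounds carry the pulse
# enrichment (washed out post-pulse at the chamber exchange rate); storage
# compounds stay at the ambient ratio. Per-context cartridge counts follow
# the campaign design (5/16/36/11/14).
gen_isotope_samples <- function(config, er_frac_h_mean) {
  cmp <- config$compounds
  # monoterpene enantiomers only; isoprene is handled by the PTR label
  # fraction, not GC-IRMS
  cmp <- cmp[cmp$group != 1L, ]
  r_amb <- 0.0111802 * (1 + config$delta13c_ambient / 1000)
  p <- config$pulses
  cnt <- config$isotope_counts
  ctx <- data.frame(
    context = c(rep("ambient", cnt[["ambient"]]),
                rep("pulse1", cnt[["pulse1"]]),
                rep("post1", cnt[["post1"]]),
                rep("pulse2", cnt[["pulse2"]]),
                rep("post2", cnt[["post2"]])),
    doy = c(
      270 + seq(0, 4, length.out = cnt[["ambient"]]),
      p$doy[1] + (p$hour[1] + seq(0.5, p$duration_h[1],
                                  length.out = cnt[["pulse1"]])) / 24,
      p$doy[1] + 1 + seq(0, 5, length.out = cnt[["post1"]]) + 10 / 24,
      p$doy[2] + (p$hour[2] + seq(0.5, p$duration_h[2],
                                  length.out = cnt[["pulse2"]])) / 24,
      p$doy[2] + 1 + seq(0, 4, length.out = cnt[["post2"]]) + 10 / 24
    ),
    stringsAsFactors = FALSE
  )
  pulse_end <- p$doy + (p$hour + p$duration_h) / 24
  out <- list()
  with_seed(config$seed + 200, {
    for (k in seq_len(nrow(cmp))) {
      de_novo <- cmp$group[k] == 2L
      eps_true <- numeric(nrow(ctx))
      if (de_novo) {
        for (pi in 1:2) {
          in_pulse <- ctx$context == paste0("pulse", pi)
          post <- ctx$context == paste0("post", pi)
          eps_true[in_pulse] <- p$epsilon[pi]
          dt_h <- (ctx$doy[post] - pulse_end[pi]) * 24
          eps_true[post] <- p$epsilon[pi] * exp(-er_frac_h_mean * dt_h)
        }
      }
      ratio <- r_amb * (1 + eps_true) *
        (1 + stats::rnorm(nrow(ctx), 0, config$isotope_noise_sd))
      out[[k]] <- data.frame(
        compound = cmp$compound[k], context = ctx$context,
        time = doy_to_time(ctx$doy), doy = ctx$doy,
        ratio_13_12 = ratio, stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, out)
}
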