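test_that("forcing obeys its physical invariants and configured geometry", {
  f <- gen_forcing(scenario_config())

  expect_true(all(f$par >= 0))
  expect_true(all(f$rh >= 0 & f$rh <= 100))
  dt <- diff(as.numeric(f$time))
  expect_true(all(dt > 0))
  expect_lt(max(abs(dt - dt[1])), 1e-9)

  # PAR maximum sits at the configured peak hour
  day1 <- f[f$doy < 253, ]
  expect_equal(day1$hour[which.max(day1$par)], 12)

  # topsoil drying trajectory: 35% at campaign start, 15% by end of SD
  expect_equal(f$soil_moisture[1], 35)
  sd_end <- f$soil_moisture[f$doy < 337]
  expect_equal(tail(sd_end, 1), 15, tolerance = 1e-3)

  # temperature within the configured day/night bands
  expect_true(all(f$temp <= 32 & f$temp >= 21))

  # stages partition the campaign window with no gaps
  expect_false(anyNA(f$stage))
  expect_setequal(levels(f$stage), c("PD", "ED", "SD", "DRW", "RRW"))
})

test_that("degenerate temperature peak alignment removes the PAR lag", {
  f <- gen_forcing(scenario_config(temp_peak_hour = 12, cloud_sd = 0))
  day1 <- f[f$doy < 253, ]
  expect_equal(day1$hour[which.max(day1$par)],
               day1$hour[which.max(day1$temp)])
})

test_that("invalid scenarios are rejected", {
  bad <- list(PD = c(252, 290), ED = c(281, 306), SD = c(306, 337),
              DRW = c(337, 347), RRW = c(347, 357))
  expect_error(scenario_config(stage_boundaries = bad), "overlap")
  expect_error(scenario_config(a_max = -1), ">= 0")
  expect_error(scenario_config(er_diel_amp = 1.5), "er_diel_amp")
})

test_that("generator is deterministic given seed and config", {
  cfg <- scenario_config(doy_start = 252, doy_end = 256)
  c1 <- gen_campaign(cfg)
  c2 <- gen_campaign(cfg)
  expect_identical(c1, c2)
  c3 <- gen_campaign(scenario_config(doy_start = 252, doy_end = 256,
                                     seed = 99))
  expect_false(identical(c1$vmr, c3$vmr))
})

test_that("tracer decays exponentially between injections", {
  # zero exchange: constant after injection
  cfg0 <- scenario_config(doy_start = 252, doy_end = 256, tracer_noise_sd = 0)
  tr0 <- gen_tracer(cfg0, er_pct_per_h = 0)
  after <- tr0$sf6[tr0$doy > 253.5 & tr0$doy < 262]
  expect_equal(diff(range(after)), 0)

  # closed form: 10 %/h for 10 h leaves 1000 * exp(-1) above background
  tr <- gen_tracer(cfg0, er_pct_per_h = 10)
  inj <- which(tr$injection)[1]
  t10 <- inj + 40                       # 40 x 15 min = 10 h
  expect_equal(tr$sf6[t10] - 8, 1000 * exp(-1), tolerance = 1e-9)

  # decay is monotone between injections when noise-free
  seg <- tr$sf6[inj:(inj + 200)]
  expect_true(all(diff(seg) <= 0))
  expect_true(all(tr$sf6 >= 8))
})

test_that("a 1 ppb injection over the 8 ppt background is a 125-fold enrichment", {
  expect_equal(tracer_enrichment_factor(1000, 8), 125)
  expect_error(tracer_enrichment_factor(1000, 0), "positive")
})

test_that("chamber balance reaches the analytic steady state", {
  tt <- as.POSIXct("2019-09-09", tz = "UTC") + seq(0, 3600 * 400, by = 900)
  # steady emission, constant exchange, no deposition: C -> c_out + e/ER
  conc <- chamber_balance(tt, emission = 100, er_frac_h = 0.1, vd = 0,
                          c_out = 50, c0 = 0, substeps = 15)
  expect_equal(tail(conc, 1), 50 + 100 / 0.1, tolerance = 1e-6)

  # zero emission, zero inflow: decay to 0
  conc0 <- chamber_balance(tt, emission = 0, er_frac_h = 0.5, vd = 0.01,
                           c_out = 0, c0 = 500)
  expect_lt(tail(conc0, 1), 1e-6)
})

test_that("chamber mass balance closes over the integration", {
  tt <- as.POSIXct("2019-09-09", tz = "UTC") + seq(0, 3600 * 72, by = 900)
  hrs <- as.numeric(tt - tt[1]) / 3600
  e <- 50 * (1 + sin(2 * pi * hrs / 24))
  er <- 0.8 + 0.2 * cos(2 * pi * hrs / 24)
  conc <- chamber_balance(tt, e, er, vd = 0.01, c_out = 5, c0 = 30)
  dt_h <- 0.25
  rhs <- e - er * (conc - 5) - 0.01 * conc
  lhs <- tail(conc, 1) - conc[1]
  integral <- sum((head(rhs, -1) + tail(rhs, -1)) / 2) * dt_h
  expect_equal(integral, lhs, tolerance = 0.01)
})

test_that("campaign with zero emissions decays every compound to zero", {
  cmp <- default_compounds()
  cmp$epsilon <- 0
  cfg <- scenario_config(doy_start = 252, doy_end = 254, compounds = cmp,
                         vmr_noise_sd = 0)
  camp <- gen_campaign(cfg)
  for (v in camp$vmr) expect_true(all(v$vmr < 1e-8))
})

test_that("13CO2 pulses enrich de novo compounds only", {
  camp <- default_campaign()
  iso <- camp$isotope_samples
  eps_of <- function(cp, ctx) {
    sc <- iso[iso$compound == cp, ]
    ref <- mean(sc$ratio_13_12[sc$context == "ambient"])
    epsilon13c(sc$ratio_13_12[sc$context %in% ctx], ref)
  }
  # storage compound: pulse samples stay within the ambient scatter band
  for (cp in c("(+)-alpha-pinene", "(+)-limonene")) {
    amb_sd <- stats::sd(eps_of(cp, "ambient"))
    expect_lt(abs(mean(eps_of(cp, c("pulse1", "pulse2")))), 2 * amb_sd)
  }
  # de novo compound: every pulse sample clearly enriched
  expect_true(all(eps_of("(-)-alpha-pinene", c("pulse1", "pulse2")) > 0))
})
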