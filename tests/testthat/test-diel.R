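test_that("day/night split partitions the series at the strict threshold", {
  s <- data.frame(x = 1:6)
  out <- split_day_night(s, par = c(0, 0.05, 0.1, 0.1001, 50, NA))
  expect_equal(out$day$x, c(4, 5))           # strictly > 0.1
  expect_equal(out$night$x, c(1, 2, 3))      # PAR = 0.1 exactly is night
  expect_equal(out$n_excluded, 1)
  expect_equal(nrow(out$day) + nrow(out$night) + out$n_excluded, nrow(s))

  all_night <- split_day_night(s, par = rep(0, 6))
  expect_equal(nrow(all_night$day), 0)
  expect_equal(nrow(all_night$night), 6)
})

test_that("synthetic day fraction matches the photoperiod", {
  f <- gen_forcing(scenario_config())
  out <- split_day_night(f, f$par)
  expect_equal(nrow(out$day) / nrow(f), 12 / 24, tolerance = 1 / 24)
})

test_that("Savitzky-Golay smoothing is exact, linear and variance-correct", {
  # degree <= polyorder polynomials are reproduced exactly (everywhere:
  # edge rows of the projection matrix are exact for polynomials too)
  x <- seq(0, 5, length.out = 120)
  poly <- 2 - 3 * x + 0.5 * x^2 + 0.1 * x^3
  sm <- smooth_trend(poly, window = 25, polyorder = 3)
  expect_equal(sm$value, poly, tolerance = 1e-9)

  # constants unchanged
  expect_equal(smooth_trend(rep(4, 60))$value, rep(4, 60))

  # linearity: SG(a x + b y) = a SG(x) + b SG(y)
  withr::with_seed(3, {
    a <- rnorm(80); b <- rnorm(80)
  })
  expect_equal(smooth_trend(2 * a - 5 * b)$value,
               2 * smooth_trend(a)$value - 5 * smooth_trend(b)$value,
               tolerance = 1e-10)

  # values identical to the reference filter implementation
  sm2 <- smooth_trend(a, window = 11, polyorder = 2)
  expect_equal(sm2$value, as.numeric(signal::sgolayfilt(a, 2, 11)),
               tolerance = 1e-10)

  # white noise: interior output sd is sqrt(sum(w^2)) by propagation
  w <- unclass(signal::sgolay(3, 25))[13, ]
  sm3 <- smooth_trend(rnorm(500), sd = 1, window = 25, polyorder = 3)
  expect_equal(sm3$sd[250], sqrt(sum(w^2)), tolerance = 1e-12)

  expect_error(smooth_trend(rnorm(10), window = 25), "shorter")
  expect_error(smooth_trend(rnorm(50), window = 24), "odd")
})

test_that("diel cycles are normalized to a unit maximum across stages", {
  camp <- default_campaign()
  v <- camp$vmr[["(-)-beta-pinene"]]
  cyc <- diel_cycle(v$hour, v$vmr, stage_partition(v$doy),
                    compound = "(-)-beta-pinene")
  expect_equal(max(cyc$norm), 1)
  expect_true(all(cyc$norm >= 0 & cyc$norm <= 1))
  expect_equal(sort(unique(cyc$hour)), 0:23)

  # the across-stage normalization puts the global maximum in severe drought
  expect_equal(cyc$stage[which.max(cyc$norm)], "SD")
})

test_that("constant series yield a flat, unit-normalized cycle", {
  hrs <- rep(0:23, 10)
  cyc <- diel_cycle(hrs, rep(7, length(hrs)),
                    factor(rep("PD", length(hrs))))
  expect_true(all(cyc$norm == 1))
  pk <- peak_hour(cyc)
  expect_true(pk$degenerate)
})

test_that("the moving median suppresses an isolated spike", {
  hrs <- rep(0:23, 5)
  val <- rep(1, length(hrs))
  val[hrs == 7][1] <- 100                  # one contaminated sample
  cyc <- diel_cycle(hrs, val, factor(rep("PD", length(hrs))))
  spike_bin_mean <- max(cyc$mean)
  expect_gt(spike_bin_mean, 10)            # raw bin mean carries the spike
  expect_lt(max(cyc$smoothed), 2)          # the median removes it
})

test_that("peak hours are argmax bins with earliest-tie flagging", {
  cyc <- data.frame(hour = 10:14, norm = c(0.2, 0.5, 1, 0.9, 0.3))
  pk <- peak_hour(cyc)
  expect_equal(pk$hour, 12)
  expect_false(pk$tie)

  tied <- data.frame(hour = 10:13, norm = c(0.2, 1, 1, 0.3))
  pk2 <- peak_hour(tied)
  expect_equal(pk2$hour, 11)
  expect_true(pk2$tie)
  expect_error(peak_hour(cyc[0, ]), "empty")
})

test_that("group-2 cycles peak late morning pre-drought and shift later in drought", {
  camp <- default_campaign()
  v <- camp$vmr[["(-)-alpha-pinene"]]
  cyc <- diel_cycle(v$hour, v$vmr, stage_partition(v$doy))
  pk <- function(st) peak_hour(cyc[cyc$stage == st, ])$hour
  expect_true(pk("PD") %in% c(11, 12))
  expect_gt(pk("SD"), pk("PD"))
})

test_that("drought proxies behave on degenerate and synthetic inputs", {
  # equal constants across all compounds
  cmp <- default_compounds()$compound
  flat <- do.call(rbind, lapply(cmp, function(cp) {
    data.frame(compound = cp, stage = factor("PD"), hour = rep(0:23, 2),
               vmr = 5)
  }))
  px <- drought_proxies(flat)
  expect_equal(px$plus_a_over_minus_b, 1)
  expect_equal(px$beta_pinene_fraction, 1 / 8)   # 8 quantified monoterpenes
  expect_equal(px$afternoon_morning_ratio, 1)

  # generator campaign: the beta-pinene fraction roughly triples PD -> SD
  px2 <- drought_proxies(vmr_long(default_campaign()))
  ratio <- px2$beta_pinene_fraction[px2$stage == "SD"] /
    px2$beta_pinene_fraction[px2$stage == "PD"]
  expect_gt(ratio, 2)
  expect_lt(ratio, 4.5)
  # and the (+)-alpha / (-)-beta ratio falls with drought severity
  expect_lt(px2$plus_a_over_minus_b[px2$stage == "SD"],
            px2$plus_a_over_minus_b[px2$stage == "PD"])

  expect_error(drought_proxies(flat[flat$compound != "(-)-beta-pinene", ]),
               "missing")
})

test_that("correlation structure separates the enantiomer sources", {
  camp <- default_campaign()
  f <- camp$forcing
  v <- camp$vmr[["(-)-alpha-pinene"]]
  par_h <- approx(as.numeric(f$time), f$par, xout = as.numeric(v$time),
                  rule = 2)$y
  day_pd <- !is.na(par_h) & par_h > 0.1 & stage_partition(v$doy) == "PD"
  day_pd[is.na(day_pd)] <- FALSE
  w <- data.frame(
    minus_a = camp$vmr[["(-)-alpha-pinene"]]$vmr[day_pd],
    minus_b = camp$vmr[["(-)-beta-pinene"]]$vmr[day_pd],
    plus_a = camp$vmr[["(+)-alpha-pinene"]]$vmr[day_pd]
  )
  r <- correlation_matrix(w)
  expect_equal(diag(r), c(minus_a = 1, minus_b = 1, plus_a = 1))
  expect_equal(r, t(r))
  # co-produced (-) enantiomers correlate better than mirror forms
  expect_gt(r["minus_a", "minus_b"], r["minus_a", "plus_a"])

  # anti-correlated pair
  x <- sin(seq(0, 10, length.out = 50))
  r2 <- correlation_matrix(data.frame(x = x, y = -x + 0.001 * seq(50)))
  expect_lt(r2["x", "y"], 0)

  # insufficient overlap is flagged missing
  a <- c(1, 2, NA, NA, NA); b <- c(NA, NA, 1, 2, 3)
  r3 <- correlation_matrix(data.frame(a = a, b = b))
  expect_true(is.na(r3["a", "b"]))
})
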