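test_that("a pool-free group emits its synthesis instantaneously", {
  pd <- pd_forcing()
  p <- reservoir_params()[1, ]            # isoprene: phi = 0
  sim <- simulate_reservoir(p, pd$forcing, a = pd$truth$a)
  expect_true(all(sim$e_store == 0))
  expect_equal(sim$e_dn, sim$synthesis)
})

test_that("constant forcing drives the pool to its analytic fixed point", {
  tt <- as.POSIXct("2019-09-09", tz = "UTC") + seq(0, 3600 * 2000, 1800)
  f <- data.frame(time = tt, temp = 26, rh = 70, par = 400)
  p <- reservoir_params()[2, ]
  p$gamma_vpd <- 0                          # fixed point phi * P / k(T)
  sim <- simulate_reservoir(p, f, a = rep(1, nrow(f)), a_ref = 1, s0 = 0)
  k_t <- p$k0 * exp(p$beta * (26 - p$t_ref))
  expect_equal(tail(sim$s, 1), p$phi * p$epsilon / k_t, tolerance = 1e-6)
  # with the VPD release modifier the fixed point uses k_eff
  p2 <- reservoir_params()[2, ]
  sim2 <- simulate_reservoir(p2, f, a = rep(1, nrow(f)), a_ref = 1, s0 = 0)
  k_eff <- k_t * (1 + p2$gamma_vpd * vpd(26, 70))
  expect_equal(tail(sim2$s, 1), p2$phi * p2$epsilon / k_eff,
               tolerance = 1e-6)
})

test_that("mass is conserved per group: synthesis = emission + pool change", {
  pd <- pd_forcing()
  sim <- simulate_reservoir(reservoir_params(), pd$forcing, a = pd$truth$a)
  dt_h <- 0.25
  for (g in unique(sim$group)) {
    s <- sim[sim$group == g, ]
    trap <- function(x) sum((head(x, -1) + tail(x, -1)) / 2) * dt_h
    lhs <- trap(s$synthesis)
    rhs <- trap(s$e_dn) + trap(s$e_store) + (tail(s$s, 1) - s$s[1])
    expect_equal(rhs, lhs, tolerance = 1e-3)
  }
})

test_that("pre-drought peak timing separates the enzyme groups", {
  pd <- pd_forcing()
  sim <- simulate_reservoir(reservoir_params(), pd$forcing, a = pd$truth$a)
  hour <- floor(pd$forcing$hour)
  peak <- function(x) {
    b <- tapply(x, hour, mean)
    as.integer(names(b)[which.max(b)])
  }
  g2 <- sim[sim$group == 2, ]
  g3 <- sim[sim$group == 3, ]
  expect_lte(peak(g2$e_dn + g2$e_store), 12)  # light-driven: noon or before
  expect_gte(peak(g3$e_store), 14)            # storage release: mid-afternoon
})

test_that("slower pools peak later in the day", {
  pd <- pd_forcing()
  hour <- floor(pd$forcing$hour)
  peak <- function(k0) {
    p <- reservoir_params(k0 = k0)[3, ]
    sim <- simulate_reservoir(p, pd$forcing, a = pd$truth$a)
    b <- tapply(sim$e_store, hour, mean)
    as.integer(names(b)[which.max(b)])
  }
  expect_gte(peak(0.02), peak(0.5))
})

test_that("the two-reservoir model degenerates to the pure light model as phi -> 0", {
  pd <- pd_forcing()
  p0 <- reservoir_params()[2, ]; p0$phi <- 0; p0$phi_stress <- 0
  p_eps <- reservoir_params()[2, ]
  p_eps$phi <- 1e-6; p_eps$phi_stress <- 1e-6
  s0 <- simulate_reservoir(p0, pd$forcing, a = pd$truth$a)
  s1 <- simulate_reservoir(p_eps, pd$forcing, a = pd$truth$a)
  tot0 <- s0$e_dn + s0$e_store
  tot1 <- s1$e_dn + s1$e_store
  expect_lt(max(abs(tot1 - tot0)) / max(tot0), 1e-4)
})

test_that("the pooled light x temperature baseline behaves canonically", {
  p <- g93_params()
  expect_equal(g93_emission(0, 30, p), 0)

  # C_T at the standard temperature, hand-evaluated from the formula
  tk <- p$t_s - 273.15
  ct_hand <- 1 / (1 + exp(p$c_t2 * (p$t_s - p$t_m) / (8.314 * p$t_s^2)))
  cl_hand <- p$alpha * p$c_l1 * 1000 / sqrt(1 + p$alpha^2 * 1e6)
  expect_equal(g93_emission(1000, tk, p), ct_hand * cl_hand,
               tolerance = 1e-12)

  # light response is monotone in PAR
  act <- g93_emission(seq(0, 2000, by = 50), 30, p)
  expect_true(all(diff(act) > 0))
  expect_error(g93_emission(-5, 30, p), "par")
})

test_that("reservoir parameters are recovered from noise-free observations", {
  pd <- pd_forcing()
  true <- c(epsilon = 100, phi = 0.3, k0 = 0.04, beta = 0.09)
  p <- reservoir_params()[2, ]
  p$epsilon <- true[["epsilon"]]; p$phi <- true[["phi"]]
  p$phi_stress <- true[["phi"]]; p$k0 <- true[["k0"]]
  p$beta <- true[["beta"]]; p$gamma_vpd <- 0
  sim <- simulate_reservoir(p, pd$forcing, a = pd$truth$a,
                            a_ref = max(pd$truth$a))
  obs <- sim$e_dn + sim$e_store
  fit <- fit_reservoir(obs, pd$forcing, a = pd$truth$a,
                       a_ref = max(pd$truth$a), t_ref = 30,
                       start = list(epsilon = 70, phi = 0.5, k0 = 0.1,
                                    beta = 0.15), n_starts = 3)
  expect_true(fit$converged)
  expect_true(all(abs(fit$params - true) / true < 0.01))
})

test_that("unidentifiable fits are flagged, not silently returned", {
  pd <- pd_forcing()
  flat <- fit_reservoir(rep(5, nrow(pd$forcing)), pd$forcing,
                        a = pd$truth$a)
  expect_false(flat$converged)
  expect_match(flat$flags, "flat")

  p <- reservoir_params()[1, ]; p$epsilon <- 50
  sim <- simulate_reservoir(p, pd$forcing, a = pd$truth$a)
  fx <- fit_reservoir(sim$e_dn, pd$forcing, a = pd$truth$a, fix_phi = 0)
  expect_match(fx$flags, "k0/beta")
  expect_equal(fx$params[["epsilon"]], 50, tolerance = 1e-8)
  expect_true(is.na(fx$params[["k0"]]))
})

test_that("noisy observations still localize the fitted diel peak", {
  pd <- pd_forcing()
  p <- reservoir_params()[2, ]
  p$epsilon <- 100; p$phi <- 0.3; p$phi_stress <- 0.3
  p$k0 <- 0.04; p$gamma_vpd <- 0
  sim <- simulate_reservoir(p, pd$forcing, a = pd$truth$a,
                            a_ref = max(pd$truth$a))
  obs <- sim$e_dn + sim$e_store
  obs_noisy <- withr::with_seed(42, obs * exp(rnorm(length(obs), 0, 0.05)))
  fit <- fit_reservoir(obs_noisy, pd$forcing, a = pd$truth$a,
                       a_ref = max(pd$truth$a), t_ref = 30, n_starts = 3)
  pf <- p
  pf$epsilon <- fit$params[["epsilon"]]
  pf$phi <- fit$params[["phi"]]; pf$phi_stress <- pf$phi
  pf$k0 <- fit$params[["k0"]]; pf$beta <- fit$params[["beta"]]
  simf <- simulate_reservoir(pf, pd$forcing, a = pd$truth$a,
                             a_ref = max(pd$truth$a))
  hour <- floor(pd$forcing$hour)
  peak <- function(x) as.integer(names(which.max(tapply(x, hour, mean))))
  expect_lte(abs(peak(simf$e_dn + simf$e_store) - peak(obs)), 1)
})

test_that("baseline comparison summarizes ratio and peak offset by stage", {
  hrs <- rep(0:23, 20)
  stage <- factor(rep("PD", length(hrs)), levels = c("PD", "SD"))
  pred <- 1 + sin(2 * pi * (hrs - 6) / 24)

  same <- compare_to_baseline(pred, pred, stage, hrs)
  expect_equal(same$ratio[same$stage == "PD"], 1)
  expect_equal(same$peak_offset_h[same$stage == "PD"], 0)

  shifted <- c(tail(pred, 2), head(pred, -2))   # observed peak 2 h later
  cmp <- compare_to_baseline(shifted, pred, stage, hrs)
  expect_equal(cmp$peak_offset_h[cmp$stage == "PD"], 2)

  zero <- compare_to_baseline(pred, rep(0, length(hrs)), stage, hrs)
  expect_true(is.na(zero$ratio[zero$stage == "PD"]))
  expect_match(zero$flag[zero$stage == "PD"], "zero prediction")
})

test_that("severe-drought emissions exceed the pooled baseline prediction", {
  camp <- default_campaign()
  f <- camp$forcing
  v <- camp$vmr[["(-)-alpha-pinene"]]
  par_h <- approx(as.numeric(f$time), f$par, xout = as.numeric(v$time),
                  rule = 2)$y
  tmp_h <- approx(as.numeric(f$time), f$temp, xout = as.numeric(v$time),
                  rule = 2)$y
  stage <- stage_partition(v$doy)
  act <- g93_emission(par_h, tmp_h)
  basal <- mean(v$vmr[stage == "PD"], na.rm = TRUE) /
    mean(act[stage == "PD"], na.rm = TRUE)
  cmp <- compare_to_baseline(v$vmr, basal * act, stage, v$hour)
  expect_equal(cmp$ratio[cmp$stage == "PD"], 1, tolerance = 1e-6)
  expect_gt(cmp$ratio[cmp$stage == "SD"], 1)
})
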