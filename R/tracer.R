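#' Fit the air-exchange rate from SF6 tracer decay
#'
#' Ordinary least squares on `ln(sf6 - background)` versus time within a
#' decay window: the exchange rate is minus the slope, reported in % per
#' hour. The log-linear fit is the closed-form estimator for an exponential
#' decay with multiplicative noise. A negative fitted slope (apparent
#' growth) is physically impossible for a leaking enclosure and is clamped
#' to 0 %/h with a warning.
#'
#' @param tracer data.frame with `time` (POSIXct) and `sf6` (ppt).
#' @param window `c(t_start, t_end)` (POSIXct or coercible); default is the
#'   whole series.
#' @param background SF6 background to subtract, ppt (default 8).
#' @return one-row data.frame: `t_start, t_end, t_mid, er, stderr, r2, n`
#'   with `er` and `stderr` in %/h.
#' @export
fit_exchange_rate <- function(tracer, window = NULL, background = 8) {
  if (is.null(window)) window <- range(tracer$time)
  sel <- tracer$time >= window[1] & tracer$time <= window[2]
  tt <- tracer$time[sel]
  sf6 <- tracer$sf6[sel]
  if (length(sf6) < 5) {
    stop("insufficient data: need at least 5 points in the fit window")
  }
  if (any(sf6 <= background)) {
    stop("tracer concentration at or below background in window; ",
         "cannot take log of the excess")
  }
  hours <- as.numeric(difftime(tt, tt[1], units = "hours"))
  fit <- stats::lm(log(sf6 - background) ~ hours)
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  er <- -slope * 100
  if (er < 0) {
    warning("fitted exchange rate was negative; clamped to 0 %/h")
    er <- 0
  }
  data.frame(
    t_start = tt[1], t_end = tt[length(tt)],
    t_mid = tt[1] + as.numeric(difftime(tt[length(tt)], tt[1],
                                        units = "secs")) / 2,
    er = er, stderr = se * 100, r2 = summary(fit)$r.squared,
    n = length(sf6)
  )
}

#' Decay windows following each tracer injection
#'
#' Convenience for campaign processing: one fit window per injection,
#' starting one sample after the injection and extending `duration_h` hours
#' (truncated at the next injection).
#'
#' @param tracer tracer data.frame with `time` and logical `injection`.
#' @param duration_h window length in hours.
#' @return list of `c(t_start, t_end)` POSIXct pairs.
#' @export
er_windows_from_injections <- function(tracer, duration_h = 48) {
  idx <- which(tracer$injection)
  if (length(idx) == 0) stop("no injections flagged in tracer series")
  lapply(seq_along(idx), function(i) {
    start <- tracer$time[min(idx[i] + 1, nrow(tracer))]
    end <- start + duration_h * 3600
    if (i < length(idx)) end <- min(end, tracer$time[idx[i + 1] - 1])
    c(start, end)
  })
}

#' Interpolate window exchange-rate estimates onto a time grid
#'
#' Linear interpolation between window midpoints with constant extrapolation
#' beyond the first/last estimate.
#'
#' @param estimates data.frame of window fits ([fit_exchange_rate()] rows).
#' @param grid POSIXct timestamps.
#' @return numeric exchange-rate series (%/h) on `grid`.
#' @export
interpolate_er <- function(estimates, grid) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    stop("need at least one exchange-rate estimate")
  }
  if (nrow(estimates) == 1) {
    return(rep(estimates$er, length(grid)))
  }
  stats::approx(as.numeric(estimates$t_mid), estimates$er,
                xout = as.numeric(grid), rule = 2)$y
}

#' Apply the exchange-rate (leakage) correction to a VMR series
#'
#' `VMRc = VMRu * (1 + ER_frac)`, where `ER_frac` is the dimensionless
#' fraction of chamber air replaced during one sampling interval,
#' `ER[%/h] / 100 * dt[h]` (incoming VOC concentrations assumed negligible).
#' Uncertainties are scaled by the same factor. A series can only be
#' corrected once.
#'
#' @param series mixing-ratio data.frame with `time`, `vmr` and optionally
#'   `uncertainty`.
#' @param er_pct_per_h exchange rate in %/h, scalar or aligned vector.
#' @param dt_h sampling interval in hours; default inferred from `time`.
#' @return the series with corrected `vmr`/`uncertainty` and attribute
#'   `corrected = TRUE`.
#' @export
correct_vmr <- function(series, er_pct_per_h, dt_h = NULL) {
  if (isTRUE(attr(series, "corrected"))) {
    stop("series is already exchange-rate corrected; refusing to correct twice")
  }
  n <- nrow(series)
  er_pct_per_h <- rep_len(er_pct_per_h, n)
  if (any(er_pct_per_h < 0)) stop("exchange rate must be >= 0")
  if (is.null(dt_h)) {
    if (n < 2) stop("cannot infer sampling interval from one point")
    dt_h <- as.numeric(difftime(series$time[2], series$time[1],
                                units = "hours"))
  }
  fac <- 1 + er_pct_per_h / 100 * dt_h
  series$vmr <- series$vmr * fac
  if ("uncertainty" %in% names(series)) {
    series$uncertainty <- series$uncertainty * fac
  }
  attr(series, "corrected") <- TRUE
  series
}

#' Soil-chamber flux from inlet/outlet mixing ratios
#'
#' Flow-through chamber difference: the flux through the soil surface is the
#' mixing-ratio difference between the chamber outlet (soil side) and inlet
#' (atmosphere side) times the molar flow of air through the chamber,
#' normalized by the enclosed soil area. Air molar density comes from the
#' ideal gas law at the chamber temperature and pressure. Negative flux is
#' uptake by the soil.
#'
#' @param mr_atm inlet (atmosphere) mixing ratio, ppt.
#' @param mr_soil outlet (soil chamber) mixing ratio, ppt.
#' @param flow chamber flow, ml/min (> 0).
#' @param area enclosed soil area, m2 (> 0).
#' @param temp chamber air temperature, degrees C.
#' @param pressure air pressure, Pa.
#' @return flux in mol m-2 s-1 (negative = uptake).
#' @export
soil_chamber_flux <- function(mr_atm, mr_soil, flow, area,
                              temp = 25, pressure = 101325) {
  if (any(flow <= 0) || any(area <= 0)) {
    stop("`flow` and `area` must be positive")
  }
  flow_m3_s <- flow * 1e-6 / 60
  n_air <- pressure / (8.314 * (273.15 + temp))   # mol/m3
  (mr_soil - mr_atm) * 1e-12 * flow_m3_s * n_air / area
}
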