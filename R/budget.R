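#' Vapour pressure deficit from temperature and relative humidity
#'
#' Tetens-type formulation:
#' `VPD = 0.6108 * (1 - RH/100) * exp(17.27 * T / (237.3 + T))` in kPa.
#'
#' @param temp air temperature, degrees C.
#' @param rh relative humidity, percent (0--100).
#' @return VPD in kPa (non-negative).
#' @export
#' @examples
#' vpd(30, 100)  # saturated air: 0 kPa
#' vpd(25, 50)
vpd <- function(temp, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("`rh` must lie in [0, 100]")
  }
  0.6108 * (1 - rh / 100) * exp(17.27 * temp / (237.3 + temp))
}

#' Moles of CO2 in a volume of air
#'
#' Ideal-gas conversion of a CO2 mole fraction to moles:
#' `n = V * P / ((273.15 + T) * R) * co2_ppm / 1e6` with
#' R = 8.314 J mol-1 K-1. `co2_ppm` may be negative when the caller passes a
#' concentration *difference* (e.g. inside minus outside).
#'
#' @param volume representative air volume, m3 (> 0).
#' @param pressure air pressure, Pa (> 0).
#' @param temp_ave average air temperature of the volume, degrees C.
#' @param co2_ppm CO2 mole fraction, ppm.
#' @return moles of CO2.
#' @export
moles_co2 <- function(volume, pressure, temp_ave, co2_ppm) {
  if (any(volume <= 0) || any(pressure <= 0)) {
    stop("`volume` and `pressure` must be positive")
  }
  if (any(temp_ave <= -273.15)) stop("`temp_ave` below absolute zero")
  volume * pressure / ((273.15 + temp_ave) * 8.314) * co2_ppm / 1e6
}

#' Net ecosystem exchange from the semi-enclosed chamber CO2 balance
#'
#' Per time step the CO2 storage change inside the enclosure plus the net
#' CO2 imported by air exchange with the outside is attributed to the
#' ecosystem. The exchange term uses the trapezoidal mean of the inside
#' (outflow-level) and outside concentrations over the step. The sign
#' convention is uptake-positive: daytime photosynthetic drawdown gives
#' NEE > 0, so that assimilation `A = NEE - R` is positive by day.
#'
#' The enclosure is treated as a single well-mixed volume; pass
#' `co2_outflow` if the concentration at the outflow level differs from the
#' bulk series.
#'
#' @param time POSIXct timestamps, strictly increasing and equally spaced.
#' @param co2_inside CO2 inside the enclosure, ppm.
#' @param co2_outside CO2 of incoming outside air, ppm.
#' @param er_frac fractional air exchange per time step (dimensionless,
#'   e.g. ER of 10 %/h over a 15-min step is 0.025). Scalar or per-step.
#' @param volume enclosure air volume, m3.
#' @param area soil surface area, m2 (default 1950).
#' @param pressure air pressure, Pa.
#' @param temp_ave average air temperature, degrees C (scalar or series).
#' @param co2_outflow CO2 at the outflow level, ppm; defaults to
#'   `co2_inside` (well-mixed).
#' @return data.frame with `time` and `nee` (umol m-2 s-1, uptake-positive);
#'   first step is `NA` (no previous concentration).
#' @export
nee_series <- function(time, co2_inside, co2_outside, er_frac, volume,
                       area = 1950, pressure = 101325, temp_ave = 25,
                       co2_outflow = co2_inside) {
  n <- length(time)
  if (n < 2) stop("need at least 2 time steps")
  lens <- c(length(co2_inside), length(co2_outside), length(co2_outflow))
  if (any(lens != n)) stop("CO2 series must be aligned with `time`")
  dt_s <- as.numeric(diff(time), units = "secs")
  if (any(dt_s <= 0) || max(abs(dt_s - dt_s[1])) > 1e-6) {
    stop("`time` must be strictly increasing and equally spaced")
  }
  er_frac <- rep_len(er_frac, n)
  temp_ave <- rep_len(temp_ave, n)
  i <- 2:n
  storage <- moles_co2(volume, pressure, temp_ave[i],
                       co2_inside[i] - co2_inside[i - 1])
  dmix <- (co2_outflow[i] + co2_outflow[i - 1]) / 2 -
    (co2_outside[i] + co2_outside[i - 1]) / 2
  # exchanged-volume moles; linear in volume so the exchange fraction can
  # scale the bulk-volume conversion (and may be zero)
  exch <- moles_co2(volume, pressure, temp_ave[i], dmix) * er_frac[i]
  nee <- -(storage + exch) / area / dt_s[1] * 1e6
  data.frame(time = time, nee = c(NA_real_, nee))
}

#' Ecosystem assimilation from NEE and night-time respiration
#'
#' Night-time NEE (PAR <= `par_threshold`) is taken as representative of the
#' whole-day respiration, either per 24-h window (calendar day; tracks
#' drought-driven respiration change) or as one campaign-wide constant.
#' Assimilation `A = NEE - R` is reported at daytime steps and `NA` at night.
#' With the uptake-positive NEE convention, respiration is the (negative)
#' night mean and daytime A is positive.
#'
#' @param time POSIXct timestamps.
#' @param nee NEE series, umol m-2 s-1, uptake-positive.
#' @param par PAR series aligned with `nee`, umol m-2 s-1.
#' @param par_threshold day/night threshold; strictly greater is day.
#' @param window `"daily"` (R per calendar day) or `"campaign"` (single R).
#' @return data.frame `time, nee, resp, a` with `a = nee - resp` by day,
#'   `NA` at night.
#' @export
assimilation <- function(time, nee, par, par_threshold = 0.1,
                         window = c("daily", "campaign")) {
  window <- match.arg(window)
  if (length(nee) != length(par) || length(nee) != length(time)) {
    stop("`time`, `nee` and `par` must be aligned")
  }
  is_day <- !is.na(par) & par > par_threshold
  if (window == "campaign") {
    if (!any(!is_day)) stop("no night-time steps to estimate respiration")
    resp <- rep(mean(nee[!is_day], na.rm = TRUE), length(nee))
  } else {
    day_id <- format(time, "%Y-%m-%d")
    resp <- rep(NA_real_, length(nee))
    for (d in unique(day_id)) {
      sel <- day_id == d
      night <- sel & !is_day
      if (!any(night)) {
        stop("24-h window ", d, " has no night-time steps for respiration")
      }
      resp[sel] <- mean(nee[night], na.rm = TRUE)
    }
  }
  a <- ifelse(is_day, nee - resp, NA_real_)
  data.frame(time = time, nee = nee, resp = resp, a = a)
}

#' Normalize a flux to land surface area and biomass carbon
#'
#' @param flux flux in amount per time (e.g. umol s-1 for the whole
#'   enclosure).
#' @param area land surface area, m2 (> 0).
#' @param biomass_c tree biomass carbon, kgC (> 0).
#' @return list with `per_area` (flux / area) and `per_biomass_c`
#'   (flux / biomass_c).
#' @export
normalize_flux <- function(flux, area = 1950, biomass_c = NULL) {
  if (area <= 0) stop("`area` must be positive")
  out <- list(per_area = flux / area, per_biomass_c = NULL)
  if (!is.null(biomass_c)) {
    if (biomass_c <= 0) stop("`biomass_c` must be positive")
    out$per_biomass_c <- flux / biomass_c
  }
  out
}
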