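# Internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generator calls never leak randomness into the session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

# POSIXct (UTC) for a fractional day-of-year in the campaign year.
doy_to_time <- function(doy, year = 2019) {
  as.POSIXct(sprintf("%d-01-01", year), tz = "UTC") + (doy - 1) * 86400
}

# Mean of `x` within each integer hour bin of `time`; returns a data.frame
# with the bin-start time and the mean.
hourly_mean <- function(time, x) {
  bin <- floor(as.numeric(time) / 3600) * 3600
  agg <- tapply(x, bin, mean, na.rm = TRUE)
  sec <- as.numeric(names(agg))
  ord <- order(sec)
  data.frame(
    time = as.POSIXct(sec[ord], origin = "1970-01-01", tz = "UTC"),
    value = unname(agg)[ord]
  )
}

frac_doy <- function(time) {
  yr <- as.POSIXct(format(time, "%Y-01-01"), tz = "UTC")
  as.numeric(difftime(time, yr, units = "days")) + 1
}
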