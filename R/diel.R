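#' Split a series into daytime and night-time parts
#'
#' Daytime is strictly `PAR > threshold`; points with missing PAR are
#' excluded from both parts (and counted), so day + night + excluded
#' partition the input.
#'
#' @param series data.frame aligned with `par`.
#' @param par PAR series, umol m-2 s-1.
#' @param threshold day/night threshold (default 0.1 umol m-2 s-1).
#' @return list `day`, `night` (row subsets of `series`), `n_excluded`.
#' @export
split_day_night <- function(series, par, threshold = 0.1) {
  if (nrow(series) != length(par)) {
    stop("`series` and `par` must be aligned")
  }
  excluded <- is.na(par)
  if (any(excluded)) {
    message(sum(excluded), " point(s) excluded for missing PAR")
  }
  is_day <- !excluded & par > threshold
  is_night <- !excluded & !is_day
  list(day = series[is_day, , drop = FALSE],
       night = series[is_night, , drop = FALSE],
       n_excluded = sum(excluded))
}

#' Savitzky-Golay trend smoothing with uncertainty propagation
#'
#' Retains long-term trends while removing short-term fluctuations by local
#' polynomial (Savitzky-Golay) filtering. Uncertainties are propagated
#' through the same linear filter weights:
#' `sd_out[i] = sqrt(sum(w^2 * sd_in^2))` using the weight row actually
#' applied at each position (edge rows of the projection matrix near the
#' boundaries, the central row in the interior), so the smoothed values
#' match `signal::sgolayfilt()` exactly.
#'
#' @param x numeric series.
#' @param sd optional per-point standard uncertainties.
#' @param window odd filter window length (default 25 points).
#' @param polyorder polynomial order (default 3, must be < `window`).
#' @return data.frame `value` (smoothed) and `sd` (propagated, or `NA` when
#'   `sd` is not supplied).
#' @export
smooth_trend <- function(x, sd = NULL, window = 25, polyorder = 3) {
  n <- length(x)
  if (window %% 2 != 1) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (window >= n) stop("`window` must be shorter than the series")
  if (any(is.na(x))) stop("series contains NA; gap-fill or subset first")
  fm <- signal::sgolay(p = polyorder, n = window)
  fm <- unclass(fm)
  k <- (window - 1) / 2
  out <- numeric(n)
  w2 <- matrix(0, n, window)
  # leading edge: rows 1..k applied to the first `window` points
  for (i in seq_len(k)) {
    out[i] <- sum(fm[i, ] * x[1:window])
    w2[i, ] <- fm[i, ]
  }
  # interior: central row, symmetric window
  centre <- fm[k + 1, ]
  for (i in (k + 1):(n - k)) {
    out[i] <- sum(centre * x[(i - k):(i + k)])
    w2[i, ] <- centre
  }
  # trailing edge: rows k+2..window applied to the last `window` points
  for (j in seq_len(k)) {
    i <- n - k + j
    out[i] <- sum(fm[k + 1 + j, ] * x[(n - window + 1):n])
    w2[i, ] <- fm[k + 1 + j, ]
  }
  sd_out <- rep(NA_real_, n)
  if (!is.null(sd)) {
    sd <- rep_len(sd, n)
    for (i in seq_len(n)) {
      idx <- if (i <= k) {
        1:window
      } else if (i > n - k) {
        (n - window + 1):n
      } else {
        (i - k):(i + k)
      }
      sd_out[i] <- sqrt(sum(w2[i, ]^2 * sd[idx]^2))
    }
  }
  data.frame(value = out, sd = sd_out)
}

# Centered moving median with truncated (shrinking) windows at the edges.
moving_median <- function(x, window = 5) {
  if (window %% 2 != 1) stop("`window` must be odd")
  k <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - k):min(n, i + k)], na.rm = TRUE)
  }, numeric(1))
}

#' Stage-resolved average diel cycles
#'
#' Groups an hourly series by campaign stage, averages into 24 hour-of-day
#' bins, applies a centered moving median (window of five points, truncated
#' at the edges) to each stage's cycle, and normalizes by the maximum across
#' all stage bins for the compound -- so the global maximum bin is exactly 1
#' and stages are comparable on one axis.
#'
#' @param hour hour of day (0--23.99) per observation.
#' @param value observed values (e.g. hourly VMR).
#' @param stage stage factor aligned with `value`.
#' @param compound compound identifier stored in the output.
#' @param median_window moving-median window length (default 5).
#' @return data.frame `compound, stage, hour, mean, n, sd, smoothed, norm`.
#'   Stages with no data are dropped with a message.
#' @export
diel_cycle <- function(hour, value, stage, compound = "compound",
                       median_window = 5) {
  if (length(hour) != length(value) || length(value) != length(stage)) {
    stop("`hour`, `value` and `stage` must be aligned")
  }
  hbin <- floor(hour) %% 24
  out <- list()
  for (st in levels(factor(stage))) {
    sel <- !is.na(stage) & stage == st & !is.na(value)
    if (!any(sel)) {
      message("stage ", st, " has no data; skipped")
      next
    }
    m <- tapply(value[sel], hbin[sel], mean)
    nn <- tapply(value[sel], hbin[sel], length)
    s <- tapply(value[sel], hbin[sel], stats::sd)
    hrs <- as.integer(names(m))
    out[[st]] <- data.frame(
      compound = compound, stage = st, hour = hrs,
      mean = unname(m), n = unname(nn), sd = unname(s),
      smoothed = moving_median(unname(m), median_window),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) stop("no stage has data")
  res <- do.call(rbind, out)
  res$norm <- res$smoothed / max(res$smoothed)
  rownames(res) <- NULL
  res
}

#' Hour of the diel-cycle maximum
#'
#' Argmax hour bin of one stage's (normalized) diel cycle. Ties are broken
#' to the earliest hour and flagged; an all-equal cycle is flagged
#' degenerate.
#'
#' @param cycle data.frame with `hour` and a value column.
#' @param value_col column to maximize (default `"norm"`).
#' @return list `hour`, `tie` (logical), `degenerate` (logical).
#' @export
peak_hour <- function(cycle, value_col = "norm") {
  if (nrow(cycle) == 0) stop("empty diel cycle")
  v <- cycle[[value_col]]
  mx <- max(v)
  at <- cycle$hour[v == mx]
  list(hour = min(at), tie = length(at) > 1,
       degenerate = length(at) == nrow(cycle))
}

#' Stage-wise drought proxies from enantiomeric monoterpene mixing ratios
#'
#' Three air-measurable proxies of drought severity:
#' \describe{
#'   \item{plus_a_over_minus_b}{mean (+)-alpha-pinene / mean (-)-beta-pinene
#'     (falls as drought boosts (-)-beta-pinene).}
#'   \item{afternoon_morning_ratio}{afternoon (13:00--17:00) over morning
#'     (08:00--12:00) mean of (-)-alpha-pinene (rises as emission shifts
#'     from the light-driven noon peak to afternoon storage release).}
#'   \item{beta_pinene_fraction}{(-)-beta-pinene share of the summed
#'     quantified monoterpenes (isoprene excluded).}
#' }
#'
#' @param vmr long data.frame with columns `compound`, `stage`, `hour`,
#'   `vmr`.
#' @param afternoon,morning half-open hour windows `[from, to)` used for the
#'   afternoon/morning ratio.
#' @return data.frame, one row per stage; proxies with a zero denominator
#'   are `NA` and named in `flag`.
#' @export
drought_proxies <- function(vmr, afternoon = c(13, 17), morning = c(8, 12)) {
  need <- c("compound", "stage", "hour", "vmr")
  if (!all(need %in% names(vmr))) {
    stop("`vmr` must have columns: ", paste(need, collapse = ", "))
  }
  for (cp in c("(+)-alpha-pinene", "(-)-beta-pinene", "(-)-alpha-pinene")) {
    if (!cp %in% vmr$compound) stop("required compound missing: ", cp)
  }
  mono <- setdiff(unique(vmr$compound), "isoprene")
  out <- list()
  for (st in levels(factor(vmr$stage))) {
    sc <- vmr[!is.na(vmr$stage) & vmr$stage == st, ]
    if (nrow(sc) == 0) next
    m <- function(cp) mean(sc$vmr[sc$compound == cp], na.rm = TRUE)
    flag <- character(0)
    minus_b <- m("(-)-beta-pinene")
    ratio_ab <- if (isTRUE(minus_b > 0)) m("(+)-alpha-pinene") / minus_b else {
      flag <- c(flag, "plus_a_over_minus_b: zero denominator")
      NA_real_
    }
    am <- sc[sc$compound == "(-)-alpha-pinene", ]
    aft <- mean(am$vmr[am$hour >= afternoon[1] & am$hour < afternoon[2]],
                na.rm = TRUE)
    mor <- mean(am$vmr[am$hour >= morning[1] & am$hour < morning[2]],
                na.rm = TRUE)
    ratio_am <- if (isTRUE(mor > 0)) aft / mor else {
      flag <- c(flag, "afternoon_morning_ratio: zero denominator")
      NA_real_
    }
    total <- sum(vapply(mono, m, numeric(1)))
    frac_b <- if (isTRUE(total > 0)) minus_b / total else {
      flag <- c(flag, "beta_pinene_fraction: zero denominator")
      NA_real_
    }
    out[[st]] <- data.frame(
      stage = st, plus_a_over_minus_b = ratio_ab,
      afternoon_morning_ratio = ratio_am, beta_pinene_fraction = frac_b,
      flag = paste(flag, collapse = "; "), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise Pearson correlations between compound mixing ratios
#'
#' Pairwise-complete Pearson correlation matrix; entries with fewer than
#' `min_overlap` overlapping observations are set `NA`.
#'
#' @param vmr_wide data.frame or matrix, one column per compound, rows =
#'   common timestamps.
#' @param min_overlap minimum overlapping points per pair (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vmr_wide, min_overlap = 3) {
  m <- as.matrix(vmr_wide)
  r <- stats::cor(m, use = "pairwise.complete.obs", method = "pearson")
  cnt <- crossprod(!is.na(m))
  r[cnt < min_overlap] <- NA_real_
  diag(r) <- 1
  r
}
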