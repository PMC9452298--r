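#' Default campaign stage boundaries (day of year)
#'
#' The campaign is divided into five stages: pre-drought (PD), early drought
#' (ED), severe drought (SD), deep-water rewet (DRW) and rain rewet (RRW).
#' Boundaries are half-open intervals `[from, to)` in day-of-year units.
#' The ED/SD split within the drought window is not fixed by the experiment
#' design (it was identified from two relative-humidity minima) and defaults
#' to doy 306; it can be moved anywhere inside the drought window. The DRW
#' band is extended up to the start of RRW so that the five stages partition
#' the campaign window without gaps.
#'
#' @param ed_sd_split doy at which early drought becomes severe drought
#'   (must lie inside the drought window 281--337).
#' @return Named list of `c(from, to)` doy pairs with names
#'   `PD`, `ED`, `SD`, `DRW`, `RRW`.
#' @export
default_stage_boundaries <- function(ed_sd_split = 306) {
  if (ed_sd_split <= 281 || ed_sd_split >= 337) {
    stop("`ed_sd_split` must lie strictly inside the drought window (281, 337)")
  }
  list(
    PD  = c(252, 281),
    ED  = c(281, ed_sd_split),
    SD  = c(ed_sd_split, 337),
    DRW = c(337, 347),
    RRW = c(347, 357)
  )
}

#' Assign campaign stage labels from day of year
#'
#' Stage is a function of doy only. Timestamps outside the campaign window
#' are labelled `NA`.
#'
#' @param doy numeric vector of (possibly fractional) day-of-year values.
#' @param boundaries stage boundary list as returned by
#'   [default_stage_boundaries()].
#' @return factor with levels `PD, ED, SD, DRW, RRW`.
#' @export
stage_partition <- function(doy, boundaries = default_stage_boundaries()) {
  nm <- names(boundaries)
  from <- vapply(boundaries, `[`, numeric(1), 1L)
  to <- vapply(boundaries, `[`, numeric(1), 2L)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; nm <- nm[ord]
  if (any(diff(from) <= 0) || any(to <= from)) {
    stop("stage boundaries must be increasing and non-degenerate")
  }
  if (any(utils::head(to, -1) > utils::tail(from, -1))) {
    stop("stage boundaries overlap")
  }
  out <- rep(NA_character_, length(doy))
  for (i in seq_along(nm)) {
    out[doy >= from[i] & doy < to[i]] <- nm[i]
  }
  factor(out, levels = names(boundaries))
}
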