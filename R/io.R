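#' Write a time-series data.frame to a schema-tagged CSV
#'
#' Plain CSV with a small commented header carrying the schema version,
#' column units and any extra metadata, so files round-trip through
#' [read_series_csv()] with their units intact. Timestamps are written as
#' ISO-8601 UTC.
#'
#' @param df data.frame; a `time` column (POSIXct) is formatted ISO-8601.
#' @param path output file.
#' @param units named character vector of column units, e.g.
#'   `c(vmr = "ppt")`.
#' @param meta named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path, units = NULL, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chiraflux-schema: 1", con)
  if (!is.null(units)) {
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = "=", collapse = ";")),
               con)
  }
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  }
  if ("time" %in% names(df) && inherits(df$time, "POSIXct")) {
    df$time <- format(df$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a schema-tagged time-series CSV
#'
#' Reverses [write_series_csv()]: parses the commented header into `units` /
#' `meta` attributes, restores the `time` column to POSIXct (UTC) and
#' validates the series. Violations report the offending file (and column).
#'
#' @param path CSV file written by [write_series_csv()] (or any CSV with
#'   `#` comments).
#' @param check_time require a strictly increasing `time` column.
#' @return data.frame with attributes `units` and `meta`.
#' @export
read_series_csv <- function(path, check_time = TRUE) {
  if (!file.exists(path)) stop("schema error: file not found: ", path)
  head_lines <- readLines(path, n = 50)
  hdr <- grep("^#", head_lines, value = TRUE)
  units <- NULL
  meta <- list()
  for (line in hdr) {
    body <- sub("^#\\s*", "", line)
    key <- sub(":.*$", "", body)
    val <- sub("^[^:]*:\\s*", "", body)
    if (key == "units") {
      kv <- strsplit(strsplit(val, ";")[[1]], "=")
      units <- stats::setNames(vapply(kv, `[`, "", 2),
                               vapply(kv, `[`, "", 1))
    } else {
      meta[[key]] <- val
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("time" %in% names(df)) {
    df$time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    if (anyNA(df$time)) {
      stop("schema error in ", path, ", column `time`: unparseable timestamp")
    }
    if (check_time && any(diff(as.numeric(df$time)) <= 0)) {
      stop("schema error in ", path,
           ", column `time`: timestamps not strictly increasing")
    }
  }
  if ("unit" %in% names(df) && length(unique(df$unit)) > 1) {
    stop("schema error in ", path, ", column `unit`: mixed units (",
         paste(unique(df$unit), collapse = ", "), ")")
  }
  attr(df, "units") <- units
  attr(df, "meta") <- meta
  df
}

# File-name-safe token for a compound (enantiomer signs spelled out).
compound_token <- function(compound) {
  x <- gsub("^\\(-\\)-", "minus_", compound)
  x <- gsub("^\\(\\+\\)-", "plus_", x)
  gsub("[^A-Za-z0-9_]+", "_", x)
}

#' Write a generated campaign to a directory of CSV files
#'
#' Writes `forcing.csv`, `tracer.csv`, `co2.csv`, one `vmr_<compound>.csv`
#' per compound, `isotope_samples.csv` and `truth.json` (true exchange rate,
#' source classes, reference assimilation).
#'
#' @param campaign output of [gen_campaign()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(campaign$forcing, file.path(dir, "forcing.csv"),
                   units = c(par = "umol m-2 s-1", temp = "degC", rh = "%",
                             pressure = "Pa", soil_moisture = "%vol"))
  write_series_csv(campaign$tracer, file.path(dir, "tracer.csv"),
                   units = c(sf6 = "ppt"))
  write_series_csv(campaign$co2, file.path(dir, "co2.csv"),
                   units = c(co2_inside = "ppm", co2_outside = "ppm"))
  for (cp in names(campaign$vmr)) {
    write_series_csv(campaign$vmr[[cp]],
                     file.path(dir, paste0("vmr_", compound_token(cp), ".csv")),
                     units = c(vmr = "ppt", uncertainty = "ppt"),
                     meta = c(compound = cp, corrected = "false"))
  }
  iso <- campaign$isotope_samples
  iso <- iso[order(iso$time), ]
  write_series_csv(iso, file.path(dir, "isotope_samples.csv"))
  jsonlite::write_json(
    list(er_pct_per_h = campaign$truth$er_pct_per_h$er_pct_per_h,
         source_class = as.list(campaign$truth$source_class),
         a_ref = campaign$truth$a_ref),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
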