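#' Pipeline configuration
#'
#' Collects every threshold, window and seed the end-to-end pipeline uses,
#' so a run is fully reproducible from its config. Either a scenario is
#' simulated (`scenario` given) or an existing campaign directory of CSVs is
#' read (`input_dir`).
#'
#' @param out_dir output directory for the report bundle.
#' @param scenario a [scenario_config()] to simulate, or `NULL` to read
#'   `input_dir`.
#' @param input_dir directory with campaign CSVs (as written by
#'   [write_campaign()]); ignored when `scenario` is given.
#' @param par_threshold day/night PAR threshold, umol m-2 s-1.
#' @param alpha significance level for enrichment tests.
#' @param sg_window,sg_order Savitzky-Golay trend filter parameters.
#' @param er_window_h tracer decay-fit window length after each injection,
#'   hours.
#' @param tracer_background SF6 background subtracted before the log fit,
#'   ppt.
#' @param median_window diel-cycle moving-median window.
#' @param resp_window respiration window for [assimilation()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scenario = scenario_config(),
                            input_dir = NULL, par_threshold = 0.1,
                            alpha = 0.05, sg_window = 25, sg_order = 3,
                            er_window_h = 2, tracer_background = 8,
                            median_window = 5, resp_window = "daily") {
  cfg <- as.list(environment())
  if (is.null(scenario) && is.null(input_dir)) {
    stop("either `scenario` or `input_dir` must be given")
  }
  if (is.null(scenario) && !dir.exists(input_dir)) {
    stop("schema error: input directory not found: ", input_dir)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

read_campaign <- function(dir) {
  need <- c("forcing.csv", "tracer.csv", "co2.csv", "isotope_samples.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("schema error: missing campaign file: ", file.path(dir, f))
    }
  }
  vmr_files <- list.files(dir, pattern = "^vmr_.*\\.csv$", full.names = TRUE)
  if (length(vmr_files) == 0) {
    stop("schema error: no vmr_<compound>.csv files in ", dir)
  }
  vmr <- list()
  for (f in sort(vmr_files)) {
    df <- read_series_csv(f)
    vmr[[df$compound[1]]] <- df
  }
  forcing <- read_series_csv(file.path(dir, "forcing.csv"))
  forcing$stage <- factor(forcing$stage,
                          levels = names(default_stage_boundaries()))
  list(forcing = forcing,
       tracer = read_series_csv(file.path(dir, "tracer.csv")),
       co2 = read_series_csv(file.path(dir, "co2.csv")),
       vmr = vmr,
       isotope_samples = read_series_csv(file.path(dir,
                                                   "isotope_samples.csv"),
                                         check_time = FALSE),
       truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> exchange-rate fitting -> VMR correction
#' -> CO2 budget -> isotope source attribution -> diel analysis, writes the
#' report bundle (`er_estimates.csv`, `er_series.csv`, `flux.csv`,
#' `enrichment.csv`, `source_classes.csv`, `diel_cycles.csv`, `proxies.csv`,
#' `correlations_day.csv`, corrected VMR files and `summary.json` with
#' provenance metadata) under `config$out_dir`, and returns the bundle
#' invisibly.
#'
#' @param config a [pipeline_config()].
#' @return list with all intermediate tables plus `hash`, the md5 over the
#'   written outputs (identical configs give identical hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$scenario)) {
    campaign <- gen_campaign(config$scenario)
    write_campaign(campaign, file.path(out, "campaign"))
  } else {
    campaign <- read_campaign(config$input_dir)
  }
  forcing <- campaign$forcing

  # --- exchange rate from tracer decays ---------------------------------
  windows <- er_windows_from_injections(campaign$tracer,
                                        duration_h = config$er_window_h)
  fits <- lapply(windows, function(w) {
    tryCatch(fit_exchange_rate(campaign$tracer, w,
                               background = config$tracer_background),
             error = function(e) NULL)
  })
  er_est <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(er_est)) stop("no tracer window could be fitted")

  # --- correct VMRs ------------------------------------------------------
  vmr_corr <- lapply(campaign$vmr, function(v) {
    er <- interpolate_er(er_est, v$time)
    correct_vmr(v, er)
  })

  # --- CO2 budget --------------------------------------------------------
  co2 <- campaign$co2
  er15 <- interpolate_er(er_est, co2$time)
  dt_h <- as.numeric(difftime(co2$time[2], co2$time[1], units = "hours"))
  scen <- config$scenario
  vol <- if (!is.null(scen)) scen$volume else 27700
  area <- if (!is.null(scen)) scen$area else 1950
  pres <- if (!is.null(scen)) scen$pressure else forcing$pressure[1]
  t_air <- if (!is.null(scen)) scen$t_ref_air else mean(forcing$temp)
  nee <- nee_series(co2$time, co2$co2_inside, co2$co2_outside,
                    er_frac = er15 / 100 * dt_h, volume = vol, area = area,
                    pressure = pres, temp_ave = t_air)
  par_on_co2 <- stats::approx(as.numeric(forcing$time), forcing$par,
                              xout = as.numeric(co2$time), rule = 2)$y
  flux <- assimilation(nee$time, nee$nee, par_on_co2,
                       par_threshold = config$par_threshold,
                       window = config$resp_window)
  flux$vpd <- vpd(forcing$temp, forcing$rh)[seq_len(nrow(flux))]

  # --- isotope source attribution ---------------------------------------
  enrich <- enrichment_table(campaign$isotope_samples, alpha = config$alpha)
  classes <- classify_sources(enrich, alpha = config$alpha)

  # --- diel analysis -----------------------------------------------------
  cycles <- list()
  proxies_in <- list()
  wide_day <- NULL
  for (cp in names(vmr_corr)) {
    v <- vmr_corr[[cp]]
    stage <- stage_partition(v$doy)
    cycles[[cp]] <- diel_cycle(v$hour, v$vmr, stage, compound = cp,
                               median_window = config$median_window)
    proxies_in[[cp]] <- data.frame(compound = cp, stage = stage,
                                   hour = v$hour, vmr = v$vmr)
    par_hr <- stats::approx(as.numeric(forcing$time), forcing$par,
                            xout = as.numeric(v$time), rule = 2)$y
    day <- !is.na(par_hr) & par_hr > config$par_threshold
    col <- data.frame(v$vmr[day & stage == "PD"])
    names(col) <- cp
    wide_day <- if (is.null(wide_day)) col else cbind(wide_day, col)
  }
  cycles <- do.call(rbind, c(cycles, make.row.names = FALSE))
  proxies <- drought_proxies(do.call(rbind, proxies_in))
  cors <- correlation_matrix(wide_day)

  # --- write bundle ------------------------------------------------------
  utils::write.csv(er_est[, c("t_mid", "er", "stderr", "r2", "n")],
                   file.path(out, "er_estimates.csv"), row.names = FALSE)
  write_series_csv(data.frame(time = co2$time, er_pct_per_h = er15),
                   file.path(out, "er_series.csv"),
                   units = c(er_pct_per_h = "%/h"))
  write_series_csv(flux, file.path(out, "flux.csv"),
                   units = c(nee = "umol m-2 s-1", resp = "umol m-2 s-1",
                             a = "umol m-2 s-1", vpd = "kPa"))
  utils::write.csv(enrich, file.path(out, "enrichment.csv"),
                   row.names = FALSE)
  utils::write.csv(classes, file.path(out, "source_classes.csv"),
                   row.names = FALSE)
  utils::write.csv(cycles, file.path(out, "diel_cycles.csv"),
                   row.names = FALSE)
  utils::write.csv(proxies, file.path(out, "proxies.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cors), file.path(out,
                                                  "correlations_day.csv"))

  cfg_for_hash <- config
  cfg_for_hash$scenario$compounds <-
    lapply(as.list(cfg_for_hash$scenario$compounds), unname)
  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(rapply(unclass(cfg_for_hash), as.vector, how = "replace"),
                   cfg_file)
  files <- c("er_estimates.csv", "er_series.csv", "flux.csv",
             "enrichment.csv", "source_classes.csv", "diel_cycles.csv",
             "proxies.csv", "correlations_day.csv")
  hash <- unname(tools::md5sum(file.path(out, files)))
  bundle_hash <- unname(tools::md5sum(
    write_lines_tmp(paste(hash, collapse = ""))))
  summary <- list(
    package_version = as.character(utils::packageVersion("chiraflux")),
    seed = if (!is.null(scen)) scen$seed else NA,
    config_md5 = unname(tools::md5sum(cfg_file)),
    thresholds = list(par_day_night = config$par_threshold,
                      alpha = config$alpha,
                      sg_window = config$sg_window,
                      sg_order = config$sg_order,
                      er_window_h = config$er_window_h,
                      tracer_background = config$tracer_background,
                      median_window = config$median_window),
    er_mean_pct_per_h = mean(er_est$er),
    source_classes = stats::setNames(as.list(classes$source_class),
                                     classes$compound),
    report_hash = bundle_hash
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(er_estimates = er_est, er_series = er15, vmr = vmr_corr,
                 flux = flux, enrichment = enrich, source_classes = classes,
                 diel_cycles = cycles, proxies = proxies,
                 correlations_day = cors, summary = summary,
                 hash = bundle_hash))
}

write_lines_tmp <- function(x) {
  f <- tempfile(fileext = ".txt")
  writeLines(x, f)
  f
}
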