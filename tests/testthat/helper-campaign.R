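# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default campaign (instrument-like noise, seed 1)
default_campaign <- function() {
  cached_fixture("default", gen_campaign(scenario_config()))
}

# noise-free campaign for closure/recovery oracles
clean_campaign <- function() {
  cached_fixture("clean", gen_campaign(scenario_config(
    co2_noise_sd = 0, vmr_noise_sd = 0, tracer_noise_sd = 0, cloud_sd = 0
  )))
}

# ten pre-drought days of deterministic forcing + ecosystem truth
pd_forcing <- function() {
  cached_fixture("pd", {
    cfg <- scenario_config(doy_start = 252, doy_end = 261, cloud_sd = 0)
    f <- gen_forcing(cfg)
    list(config = cfg, forcing = f, truth = ecosystem_truth(cfg, f))
  })
}

# long VMR data.frame (compound, stage, hour, vmr) from a campaign
vmr_long <- function(campaign) {
  do.call(rbind, lapply(campaign$vmr, function(v) {
    data.frame(compound = v$compound, stage = stage_partition(v$doy),
               hour = v$hour, vmr = v$vmr)
  }))
}

# independent Welch one-tailed oracle, written from the textbook formula
welch_one_tailed <- function(x, y) {
  sx <- stats::var(x) / length(x)
  sy <- stats::var(y) / length(y)
  tval <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  stats::pt(tval, df, lower.tail = FALSE)
}
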