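# Shared fixtures: the five-expert elicited example and the four
# hypothetical historical-data configurations with robust weight sets I/II.

expert5_sources <- function() {
  as_historical_summaries(data.frame(
    label = paste0("expert", 1:5),
    mean = c(-0.26, -0.24, -0.37, -0.34, -0.32),
    variance = c(0.25, 0.23, 0.22, 0.36, 0.26),
    w = c(0.15, 0.20, 0.17, 0.13, 0.20)))
}

# raw configuration table (means, variances, two weight sets per config)
config_table <- function() {
  m12 <- c(-0.260, -0.240, -0.370, -0.340, -0.320)
  m34 <- c(-0.260, -0.170, -0.440, -0.150, 0.120)
  list(
    config1 = list(m = m12, s2 = c(0.250, 0.230, 0.220, 0.360, 0.260),
                   wI = c(0.103, 0.175, 0.081, 0.143, 0.077),
                   wII = c(0.252, 0.319, 0.140, 0.306, 0.149)),
    config2 = list(m = m12, s2 = rep(0.100, 5),
                   wI = c(0.103, 0.175, 0.081, 0.143, 0.077),
                   wII = c(0.252, 0.319, 0.140, 0.306, 0.149)),
    config3 = list(m = m34, s2 = c(0.250, 0.640, 0.970, 1.540, 0.590),
                   wI = c(0.101, 0.219, 0.385, 0.385, 0.304),
                   wII = c(0.325, 0.203, 0.171, 0.180, 0.272)),
    config4 = list(m = m34, s2 = c(0.250, 0.150, 0.400, 0.890, 0.220),
                   wI = c(0.066, 0.303, 0.459, 0.355, 0.115),
                   wII = c(0.537, 0.306, 0.054, 0.220, 0.350))
  )
}

sources_from <- function(m, s2, w) {
  as_historical_summaries(data.frame(mean = m, variance = s2, w = w))
}

# all eight (configuration x weight-set) fixture priors
all_config_priors <- function(spec = commensurate_spec()) {
  tab <- config_table()
  out <- list()
  for (cf in names(tab)) {
    for (ws in c("wI", "wII")) {
      nm <- paste0(cf, "_", sub("w", "RW", ws))
      out[[nm]] <- collective_prior(
        sources_from(tab[[cf]]$m, tab[[cf]]$s2, tab[[cf]][[ws]]), spec)
    }
  }
  out
}
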