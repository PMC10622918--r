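# shared fixtures: small configs and hand-built bottle pairs

noise_free_cfg <- function(...) {
  sim_config(count_cv = 0, d_jitter_sd = 0, pp_depth_jitter_sd = 0,
             abundance_jitter_sd = 0, ...)
}

# one noise-free bottle pair with known rates, bypassing the simulator
make_pair <- function(mu, m, d = 0.33, n0 = 1e4, duration = 1,
                      population = "SYN", station_id = "S001", depth = 5) {
  tibble::tibble(
    station_id = station_id, depth = depth, population = population,
    d_measured = d,
    n0_undiluted = n0,
    nf_undiluted = n0 * exp((mu - m) * duration),
    n0_diluted = n0 * d,
    nf_diluted = n0 * d * exp((mu - m * d) * duration),
    duration = duration
  )
}

# full simulate -> estimate -> aggregate chain for station-level fixtures
simulate_and_aggregate <- function(seed, n_stations = 50, ...) {
  cruise <- simulate_cruise(sim_config(n_stations = n_stations,
                                       seed = seed, ...))
  suppressMessages(aggregate_stations(estimate_rates(cruise$bottles),
                                      cruise$environment))
}

# truth table for direct calls to simulate_bottles()
make_truth <- function(mu, m, abundance = 1e4, population = "SYN",
                       station_id = "S001", depth = 5) {
  tibble::tibble(
    station_id = station_id, depth = depth, population = population,
    abundance = abundance, mu_true = mu, m_true = m
  )
}
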