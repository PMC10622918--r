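#' Generate a synthetic environmental gradient
#'
#' Draws per-station, per-depth environmental profiles (temperature,
#' nitrate, chlorophyll a, primary production) with the covariance
#' structure of a wind-driven upwelling ecosystem: station-level log10
#' primary production (PP) is uniform over `cfg$pp_log10_range` and shared
#' (up to a small jitter) by the station's depths; temperature decreases
#' with PP (upwelled water is cold); nitrate increases with PP and hence
#' decreases with temperature; chlorophyll a follows a positive power law
#' of PP with lognormal scatter. All values are clamped to the envelope
#' observed across the CCE process cruises (temperature 11--19.5 degC,
#' nitrate 0--14 uM, Chl a 0.05--14 mg m-3, PP 1.8--367 mg C m-3 d-1).
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `station_id`, `depth` (m), `temperature`
#'   (degC), `nitrate` (uM), `chla` (mg m-3), `pp` (mg C m-3 d-1).
#' @export
generate_environment <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(as.integer(cfg$seed), generate_environment_impl(cfg))
}

generate_environment_impl <- function(cfg) {
  env <- cce_envelope()
  n <- cfg$n_stations
  k <- cfg$depths_per_station
  depths <- 5 + 10 * (seq_len(k) - 1)          # 5, 15, 25, ... m

  l10_station <- runif(n, cfg$pp_log10_range[1], cfg$pp_log10_range[2])
  # cold upwelled water fuels production: temperature declines along the
  # gradient and crosses the 14 degC Prochlorococcus limit near PP ~ 80
  t_station <- 19.3 - 3.2 * (l10_station - cfg$pp_log10_range[1]) +
    rnorm(n, sd = 0.3)

  grid <- tidyr::expand_grid(
    station = seq_len(n),
    depth = depths
  )
  l10pp <- l10_station[grid$station] +
    rnorm(nrow(grid), sd = cfg$pp_depth_jitter_sd)
  l10pp <- clamp(l10pp, log10(env$pp[1]), log10(env$pp[2]))
  pp <- 10^l10pp

  temperature <- t_station[grid$station] - 0.02 * (grid$depth - depths[1]) +
    rnorm(nrow(grid), sd = 0.1)
  temperature <- clamp(temperature, env$temperature[1], env$temperature[2])

  nitrate <- 14 * ((l10pp - cfg$pp_log10_range[1]) /
                     diff(cfg$pp_log10_range))^2 *
    rlnorm(nrow(grid), meanlog = 0, sdlog = 0.2)
  nitrate <- clamp(nitrate, env$nitrate[1], env$nitrate[2])

  chla <- 0.06 * pp^0.72 *
    rlnorm(nrow(grid), meanlog = 0, sdlog = cfg$chla_scatter_sd * log(10))
  chla <- clamp(chla, env$chla[1], env$chla[2])

  tibble::tibble(
    station_id = sprintf("S%03d", grid$station),
    depth = grid$depth,
    temperature = temperature,
    nitrate = nitrate,
    chla = chla,
    pp = pp
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' True rates and abundances along the productivity gradient
#'
#' Piecewise-linear interpolation in log10(PP) through the published
#' bin-mean abundances and rates ([cce_picoplankton_rates()]), with
#' anchors placed at the log10 PP bin centers 0.5, 1.5, and 2.5 and
#' clamped beyond the end bins. Abundance is interpolated on the log10
#' scale (it spans orders of magnitude); rates are interpolated linearly.
#' *Prochlorococcus* has no high-production anchor (it is absent from
#' cold high-PP water), so its trend is clamped above the middle bin; its
#' structural absence is imposed by the simulator's temperature rule, not
#' here.
#'
#' @param pp Primary production, mg C m-3 d-1 (vectorized).
#' @param population One of `"HBAC"`, `"PRO"`, `"SYN"`, `"PEUK"`.
#' @return A tibble with columns `abundance` (cells mL-1), `mu_true`,
#'   `m_true` (d-1), recycled to `length(pp)`.
#' @export
#' @examples
#' true_rates_from_pp(10^1.5, "HBAC")
true_rates_from_pp <- function(pp, population) {
  if (length(population) != 1L || !population %in% POPULATIONS) {
    abort(sprintf("unknown population label: %s",
                  paste(format(population), collapse = ", ")))
  }
  stopifnot(is.numeric(pp), all(is.finite(pp)), all(pp > 0))
  anchors <- dplyr::filter(cce_picoplankton_rates(),
                           .data$population == !!population,
                           !is.na(.data$mu))
  centers <- c("PP<10" = 0.5, "10<PP<100" = 1.5, "PP>100" = 2.5)
  xa <- unname(centers[anchors$pp_bin])
  l10 <- log10(pp)
  interp <- function(ya) {
    if (length(xa) == 1L) return(rep(ya, length(l10)))
    stats::approx(xa, ya, xout = clamp(l10, min(xa), max(xa)),
                  method = "linear", rule = 2)$y
  }
  tibble::tibble(
    abundance = 10^interp(log10(anchors$abundance)),
    mu_true = interp(anchors$mu),
    m_true = interp(anchors$m)
  )
}

# truth table for a generated environment; applies the cold-water
# Prochlorococcus cutoff and lognormal depth scatter on abundance
simulate_truth_impl <- function(environment, cfg) {
  truth <- tidyr::expand_grid(
    environment,
    population = cfg$populations
  ) |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(true_rates_from_pp(.data$pp, .data$population[1])) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      abundance = .data$abundance *
        10^rnorm(dplyr::n(), sd = cfg$abundance_jitter_sd)
    )
  # PRO cannot sustain populations below 14 degC (cold productive water)
  pro_absent <- truth$population == "PRO" & truth$temperature < 14
  truth$abundance[pro_absent] <- 0
  truth$mu_true[pro_absent] <- NA_real_
  truth$m_true[pro_absent] <- NA_real_
  dplyr::select(truth, "station_id", "depth", "population",
                "abundance", "mu_true", "m_true")
}

#' Simulate dilution-bottle pairs from true rates
#'
#' Forward model of the two-treatment dilution experiment. For each truth
#' record a realized dilution factor D is drawn near
#' `cfg$dilution_target`; the undiluted bottle then changes exponentially
#' at net rate (mu - m) and the diluted bottle at (mu - m D) -- grazing
#' encounter rates scale linearly with the fraction of whole seawater,
#' the assumption under which the two-bottle estimator is exact. All four
#' cell counts are finally perturbed by independent multiplicative
#' lognormal noise with coefficient of variation `cfg$count_cv` (unit
#' mean). With `count_cv = 0` and `d_jitter_sd = 0` the forward model is
#' deterministic and [estimate_rates()] inverts it exactly.
#'
#' Rows with zero abundance or undefined rates are rejected: callers must
#' emit absent-population records themselves (as [simulate_cruise()]
#' does, writing zero counts).
#'
#' @param truth A tibble with columns `station_id`, `depth`, `population`,
#'   `abundance` (cells mL-1), `mu_true`, `m_true` (d-1).
#' @param cfg A [sim_config()].
#' @return A tibble of bottle pairs: `station_id`, `depth`, `population`,
#'   `d_measured`, `n0_undiluted`, `nf_undiluted`, `n0_diluted`,
#'   `nf_diluted` (cells mL-1), `duration` (days).
#' @export
simulate_bottles <- function(truth, cfg) {
  validate_sim_config(cfg)
  if (any(truth$abundance <= 0 | !is.finite(truth$mu_true) |
            !is.finite(truth$m_true))) {
    abort(paste("cannot simulate bottles for absent populations",
                "(zero abundance or undefined rates)"),
          class = "picograze_sim_error")
  }
  simulate_bottles_impl(truth, cfg)
}

simulate_bottles_impl <- function(truth, cfg) {
  nr <- nrow(truth)
  t_inc <- cfg$incubation_days

  d <- rnorm(nr, mean = cfg$dilution_target, sd = cfg$d_jitter_sd)
  d <- clamp(d, 0.01, 0.99)

  n0_u <- truth$abundance
  n0_d <- truth$abundance * d
  nf_u <- n0_u * exp((truth$mu_true - truth$m_true) * t_inc)
  nf_d <- n0_d * exp((truth$mu_true - truth$m_true * d) * t_inc)

  counts <- cbind(n0_u, nf_u, n0_d, nf_d)
  if (cfg$count_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$count_cv^2))
    noise <- matrix(rlnorm(4 * nr, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nr)
    counts <- counts * noise
  }

  tibble::tibble(
    station_id = truth$station_id,
    depth = truth$depth,
    population = truth$population,
    d_measured = d,
    n0_undiluted = unname(counts[, 1]),
    nf_undiluted = unname(counts[, 2]),
    n0_diluted = unname(counts[, 3]),
    nf_diluted = unname(counts[, 4]),
    duration = t_inc
  )
}

#' Simulate a full synthetic cruise
#'
#' Runs the whole forward model under one seed: environmental gradient
#' ([generate_environment()]), true abundances and rates along it
#' ([true_rates_from_pp()] plus the cold-water *Prochlorococcus* cutoff),
#' and noisy dilution-bottle observations ([simulate_bottles()]).
#' Populations absent at a depth appear in `bottles` with all counts 0,
#' so the estimation stage sees and propagates them as undefined.
#'
#' @param cfg A [sim_config()]; `cfg$seed` governs every draw, so equal
#'   configs give bit-identical cruises.
#' @return A list with elements `config`, `environment`, `truth`, and
#'   `bottles` (tibbles as documented in the respective generators).
#' @export
#' @examples
#' cruise <- simulate_cruise(sim_config(n_stations = 5, seed = 42))
#' head(cruise$bottles)
simulate_cruise <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(as.integer(cfg$seed), {
    environment <- generate_environment_impl(cfg)
    truth <- simulate_truth_impl(environment, cfg)
    present <- truth$abundance > 0 & is.finite(truth$mu_true)
    bottles <- simulate_bottles_impl(truth[present, ], cfg)
    if (any(!present)) {
      absent <- truth[!present, c("station_id", "depth", "population")]
      absent <- dplyr::mutate(absent,
        d_measured = cfg$dilution_target,
        n0_undiluted = 0, nf_undiluted = 0,
        n0_diluted = 0, nf_diluted = 0,
        duration = cfg$incubation_days
      )
      bottles <- dplyr::bind_rows(bottles, absent)
    }
    bottles <- dplyr::arrange(bottles, .data$station_id, .data$depth,
                              factor(.data$population, levels = POPULATIONS))
    list(config = cfg, environment = environment, truth = truth,
         bottles = bottles)
  })
}
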