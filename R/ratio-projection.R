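#' Grazing mortality ratio between two populations
#'
#' `m_pop / m_ref`, the dimensionless mortality of a population relative
#' to a reference (conventionally heterotrophic bacteria, the population
#' whose grazing losses track productivity most strongly). Undefined
#' (`NA`) when the reference mortality is not positive.
#'
#' @param m_pop,m_ref Grazing mortality rates, d-1 (vectorized).
#' @return Numeric vector of ratios; `NA` where `m_ref <= 0`.
#' @export
#' @examples
#' mortality_ratio(0.57, 0.21)
mortality_ratio <- function(m_pop, m_ref) {
  ifelse(is.finite(m_ref) & m_ref > 0, m_pop / m_ref, NA_real_)
}

#' Counterfactual mortality under shared predation
#'
#' If predators consumed a population in the same proportion to the
#' reference everywhere, its mortality in rich waters would be the
#' low-production mortality ratio times the reference's high-production
#' mortality. The product of those two inputs is the "scaled mortality".
#'
#' @param ratio_low_pp Mean mortality ratio (population : reference) at
#'   the low-production end of the gradient, dimensionless.
#' @param m_ref_high_pp Reference mortality at the high-production end,
#'   d-1.
#' @return Scaled mortality, d-1.
#' @export
#' @examples
#' scaled_mortality(3.9, 0.61)
scaled_mortality <- function(ratio_low_pp, m_ref_high_pp) {
  stopifnot(all(ratio_low_pp >= 0, na.rm = TRUE),
            all(m_ref_high_pp >= 0, na.rm = TRUE))
  ratio_low_pp * m_ref_high_pp
}

#' Daily percent decline implied by a net decline rate
#'
#' Converts a continuous net decline rate r (d-1) to the percentage of
#' the population lost per day, `100 (1 - exp(-r))`. Negative rates
#' (net growth) return negative percentages.
#'
#' @param net_decline_rate Net decline rate, d-1 (vectorized).
#' @return Percent of the population lost per day.
#' @export
#' @examples
#' daily_decline_pct(2.0)
daily_decline_pct <- function(net_decline_rate) {
  stopifnot(all(is.finite(net_decline_rate)))
  100 * (1 - exp(-net_decline_rate))
}

#' Days until a declining population reaches a threshold
#'
#' Time for exponential decline at rate r from `n0` to `threshold`:
#' `ln(n0 / threshold) / r`. Returns 0 when the population is already at
#' or below the threshold.
#'
#' @param n0 Initial abundance, cells mL-1.
#' @param threshold Abundance defining nominal local extinction,
#'   cells mL-1 (must be positive).
#' @param net_decline_rate Net decline rate, d-1 (must be positive).
#' @return Days to reach the threshold.
#' @export
#' @examples
#' days_to_threshold(1e4, 1, 2.0)
days_to_threshold <- function(n0, threshold, net_decline_rate) {
  if (any(threshold <= 0)) {
    abort("`threshold` must be positive", class = "picograze_projection_error")
  }
  if (any(!is.finite(net_decline_rate) | net_decline_rate <= 0)) {
    abort("population not declining (rate must be positive)",
          class = "picograze_projection_error")
  }
  n <- max(length(n0), length(threshold), length(net_decline_rate))
  n0 <- rep_len(n0, n)
  threshold <- rep_len(threshold, n)
  rate <- rep_len(net_decline_rate, n)
  ifelse(n0 <= threshold, 0, log(n0 / threshold) / rate)
}

#' Percent of production consumed by grazers
#'
#' `100 m / mu`, the share of a population's growth removed by grazing;
#' 100% indicates growth-grazing balance. Undefined (`NA`) when growth is
#' not positive (e.g. populations too scarce to assess).
#'
#' @param m Grazing mortality, d-1 (vectorized).
#' @param mu Instantaneous growth, d-1.
#' @return Percent of production consumed; `NA` where `mu <= 0`.
#' @export
#' @examples
#' production_consumed_pct(0.3, 0.6)
production_consumed_pct <- function(m, mu) {
  ifelse(is.finite(mu) & mu > 0, 100 * m / mu, NA_real_)
}

#' Per-station mortality ratios relative to a reference population
#'
#' Joins each population's station-mean mortality to the reference
#' population's at the same station and forms the ratio. Stations where
#' the reference mortality is not positive, or either rate is undefined,
#' yield `NA`. The result feeds segmented gradient regressions of
#' mortality ratio against production.
#'
#' @param stations Station table from [aggregate_stations()].
#' @param reference Reference population label (default `"HBAC"`).
#' @return A tibble: `station_id`, `population`, `pp_mean`, `ratio`
#'   (named `ratio` so it can be passed as a response to
#'   [segment_regressions()]).
#' @export
station_mortality_ratios <- function(stations, reference = "HBAC") {
  ref <- stations |>
    dplyr::filter(.data$population == reference) |>
    dplyr::select("station_id", m_ref = "m_mean")
  stations |>
    dplyr::filter(.data$population != reference) |>
    dplyr::left_join(ref, by = "station_id") |>
    dplyr::mutate(ratio = mortality_ratio(.data$m_mean, .data$m_ref)) |>
    dplyr::select("station_id", "population", "pp_mean", "ratio")
}

#' Assemble shared-predation projection inputs from station data
#'
#' For each non-reference population: the mean of its per-station
#' mortality ratios in low-production water (`pp_mean < low_max`), the
#' reference's mean mortality in high-production water
#' (`pp_mean > high_min`), and the population's own mean growth rate
#' there. Ratios are averaged per station (not formed from bin means),
#' matching how mean mortality ratios are reported in the field.
#'
#' @param stations Station table from [aggregate_stations()].
#' @param reference Reference population label.
#' @param low_max,high_min Production bounds (mg C m-3 d-1) defining the
#'   low- and high-production ends of the gradient.
#' @return A tibble: `population`, `ratio_low`, `m_ref_high`, `mu_high`,
#'   ready for [project_shared_predation()].
#' @export
shared_predation_inputs <- function(stations, reference = "HBAC",
                                    low_max = 10, high_min = 100) {
  ratios <- station_mortality_ratios(stations, reference)
  ratio_low <- ratios |>
    dplyr::filter(.data$pp_mean < low_max, is.finite(.data$ratio)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(ratio_low = mean(.data$ratio), .groups = "drop")
  high <- stations |>
    dplyr::filter(.data$pp_mean > high_min, .data$defined)
  m_ref_high <- high |>
    dplyr::filter(.data$population == reference) |>
    dplyr::summarise(m_ref_high = mean(.data$m_mean)) |>
    dplyr::pull("m_ref_high")
  mu_high <- high |>
    dplyr::filter(.data$population != reference) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mu_high = mean(.data$mu_mean), .groups = "drop")
  dplyr::inner_join(ratio_low, mu_high, by = "population") |>
    dplyr::mutate(m_ref_high = m_ref_high, .after = "ratio_low")
}

#' Shared-predation projection inputs from the published summaries
#'
#' Combines [cce_mortality_ratios()] (mean low-production mortality
#' ratios) with [cce_picoplankton_rates()] (high-production reference
#' mortality and population growth rates) into the input table for
#' [project_shared_predation()], reproducing the published projection
#' arithmetic.
#'
#' @param reference Reference population label.
#' @return A tibble: `population`, `ratio_low`, `m_ref_high`, `mu_high`.
#' @export
#' @examples
#' project_shared_predation(cce_projection_inputs())
cce_projection_inputs <- function(reference = "HBAC") {
  rates <- dplyr::filter(cce_picoplankton_rates(), .data$pp_bin == "PP>100")
  m_ref_high <- rates$m[rates$population == reference]
  cce_mortality_ratios() |>
    dplyr::select("population", "ratio_low") |>
    dplyr::left_join(dplyr::select(rates, "population", mu_high = "mu"),
                     by = "population") |>
    dplyr::mutate(m_ref_high = m_ref_high, .after = "ratio_low")
}

#' Project population decline under shared predation
#'
#' The shared-predation counterfactual asks what would happen to a
#' population in high-production water if grazers consumed it in the
#' same proportion to the reference population as they do in poor water.
#' Scaled mortality is `ratio_low x m_ref_high`
#' ([scaled_mortality()]); the net decline rate is scaled mortality
#' minus the population's own measured growth there; that rate implies a
#' daily percent decline ([daily_decline_pct()]) and a time to nominal
#' local extinction ([days_to_threshold()]).
#'
#' @param inputs A tibble with columns `population`, `ratio_low`,
#'   `m_ref_high`, `mu_high` ([shared_predation_inputs()] or
#'   [cce_projection_inputs()]).
#' @param n0 Initial abundance for the extinction clock, cells mL-1
#'   (default 1e4, the order of magnitude of picophytoplankton standing
#'   stocks in rich water).
#' @param threshold Abundance defining nominal local extinction,
#'   cells mL-1.
#' @return A tibble: `population`, `ratio_low`, `m_ref_high`, `m_scaled`,
#'   `mu_reference`, `net_rate`, `fold_excess` (scaled mortality over own
#'   growth), `daily_decline_pct`, `days_to_threshold`, `n0`,
#'   `threshold`. `days_to_threshold` is `NA` when the population is not
#'   declining.
#' @export
project_shared_predation <- function(inputs, n0 = 1e4, threshold = 1) {
  required <- c("population", "ratio_low", "m_ref_high", "mu_high")
  missing_cols <- setdiff(required, names(inputs))
  if (length(missing_cols) > 0) {
    abort(sprintf("`inputs` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "picograze_schema_error")
  }
  inputs |>
    dplyr::mutate(
      m_scaled = scaled_mortality(.data$ratio_low, .data$m_ref_high),
      mu_reference = .data$mu_high,
      net_rate = .data$m_scaled - .data$mu_reference,
      fold_excess = .data$m_scaled / .data$mu_reference,
      daily_decline_pct = daily_decline_pct(.data$net_rate),
      days_to_threshold = ifelse(
        .data$net_rate > 0,
        days_to_threshold(n0, threshold, pmax(.data$net_rate, 1e-12)),
        NA_real_
      ),
      n0 = n0,
      threshold = threshold
    ) |>
    dplyr::select("population", "ratio_low", "m_ref_high", "m_scaled",
                  "mu_reference", "net_rate", "fold_excess",
                  "daily_decline_pct", "days_to_threshold",
                  "n0", "threshold")
}
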