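#' Net exponential growth rate from initial and final counts
#'
#' `ln(nf / n0) / duration`, the apparent (net) rate of exponential change
#' over an incubation, in d-1. Nonpositive counts yield `NA` rather than
#' an error, so absent populations (zero flow-cytometry counts) propagate
#' as undefined records through the pipeline.
#'
#' @param n0,nf Initial and final cell counts (cells mL-1), vectorized.
#' @param duration Incubation duration, days.
#' @return Numeric vector of rates (d-1); `NA` where either count is not
#'   positive.
#' @export
#' @examples
#' net_rate(1000, 2718.28, 1)   # ~1 d-1
net_rate <- function(n0, nf, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    abort("`duration` must be positive", class = "picograze_rate_error")
  }
  ok <- is.finite(n0) & is.finite(nf) & n0 > 0 & nf > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log(nf[ok] / n0[ok]) / rep_len(duration, length(ok))[ok]
  out
}

#' Estimate growth and grazing rates from two-treatment dilution pairs
#'
#' For each bottle pair, the apparent rates in the undiluted (`k`) and
#' diluted (`k_d`) treatments give grazing mortality
#' `m = (k_d - k) / (1 - D)` and instantaneous growth `mu = k + m`, where
#' `D` is the measured dilution factor. Net growth equals `k` (and
#' `mu - m`) exactly. Negative `m` or `mu` are returned as-is; any
#' transformation (e.g. the 0.01 d-1 floor for log-scale regression) is
#' deferred to [floor_for_log()].
#'
#' If `d_measured` is missing for a pair, `D` is taken from the initial
#' counts as `n0_diluted / n0_undiluted` (the dilution factor as measured
#' from initial flow-cytometry subsamples). Pairs with nonpositive counts
#' are returned with `defined = FALSE` and `NA` rates.
#'
#' @param bottles A tibble of bottle pairs as produced by
#'   [simulate_cruise()] or read from a `bottles` table: columns
#'   `station_id`, `depth`, `population`, `d_measured`, `n0_undiluted`,
#'   `nf_undiluted`, `n0_diluted`, `nf_diluted`, `duration`.
#' @return A tibble of per-depth rate estimates: `station_id`, `depth`,
#'   `population`, `abundance` (initial undiluted count, cells mL-1),
#'   `d` (dilution factor used), `k`, `k_d`, `m`, `mu`, `net` (d-1), and
#'   logical `defined`.
#' @export
#' @examples
#' pair <- tibble::tibble(
#'   station_id = "S001", depth = 5, population = "SYN",
#'   d_measured = 0.33, n0_undiluted = 1e4, nf_undiluted = 1e4 * exp(0.2),
#'   n0_diluted = 3.3e3, nf_diluted = 3.3e3 * exp(0.5), duration = 1
#' )
#' estimate_rates(pair)
estimate_rates <- function(bottles) {
  required <- c("station_id", "depth", "population", "n0_undiluted",
                "nf_undiluted", "n0_diluted", "nf_diluted", "duration")
  missing_cols <- setdiff(required, names(bottles))
  if (length(missing_cols) > 0) {
    abort(sprintf("`bottles` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "picograze_schema_error")
  }
  d_measured <- bottles$d_measured %||% rep(NA_real_, nrow(bottles))
  d_from_counts <- ifelse(bottles$n0_undiluted > 0,
                          bottles$n0_diluted / bottles$n0_undiluted,
                          NA_real_)
  d <- ifelse(is.finite(d_measured), d_measured, d_from_counts)

  k <- net_rate(bottles$n0_undiluted, bottles$nf_undiluted, bottles$duration)
  k_d <- net_rate(bottles$n0_diluted, bottles$nf_diluted, bottles$duration)
  defined <- is.finite(k) & is.finite(k_d) & is.finite(d)
  if (any(defined & d >= 1)) {
    abort("undiluted treatment cannot resolve grazing (dilution factor >= 1)",
          class = "picograze_rate_error")
  }

  m <- ifelse(defined, (k_d - k) / (1 - d), NA_real_)
  tibble::tibble(
    station_id = bottles$station_id,
    depth = bottles$depth,
    population = bottles$population,
    abundance = bottles$n0_undiluted,
    d = d,
    k = ifelse(defined, k, NA_real_),
    k_d = ifelse(defined, k_d, NA_real_),
    m = m,
    mu = ifelse(defined, k + m, NA_real_),
    net = ifelse(defined, k, NA_real_),
    defined = defined
  )
}

sem <- function(x) {
  n <- sum(is.finite(x))
  if (n <= 1L) return(0)
  sd(x[is.finite(x)]) / sqrt(n)
}

#' Aggregate depth-level rates to station means
#'
#' Depth-level estimates within the upper euphotic zone are treated as
#' independent assessments of the same station-level rates, so each
#' station x population is summarised as an arithmetic mean +/- SEM
#' (sd / sqrt(n)) over the selected depths. The default `depth_rule`
#' keeps the shallowest half (ceiling) of each station's sampled depths,
#' where rates are not light-limited; `"all"` keeps every depth (use it
#' when the input already contains only upper-euphotic incubations).
#'
#' Abundance is averaged over all selected depths (zeros from absent
#' populations included, so an absent population reports `0 +/- 0`);
#' rates are averaged over the defined depths only, and a population
#' with no defined depth at a station is reported with `defined = FALSE`
#' and `NA` rates. Stations with a single contributing depth report
#' SEM = 0; a message counts them so users can filter.
#'
#' @param rates Depth-level estimates from [estimate_rates()].
#' @param environment Environmental profiles carrying `station_id`,
#'   `depth`, `pp` (from [generate_environment()] or a read table).
#' @param depth_rule `"upper-half"` (default) or `"all"`.
#' @return A tibble with one row per station x population: `station_id`,
#'   `population`, `n_depths` (defined depths), `abundance_mean/_sem`,
#'   `mu_mean/_sem`, `m_mean/_sem`, `net_mean/_sem`, `pp_mean/_sem`, and
#'   `defined`.
#' @export
aggregate_stations <- function(rates, environment,
                               depth_rule = c("upper-half", "all")) {
  depth_rule <- match.arg(depth_rule)
  if (nrow(rates) == 0) {
    abort("no rate estimates to aggregate", class = "picograze_agg_error")
  }
  keep <- environment |>
    dplyr::distinct(.data$station_id, .data$depth) |>
    dplyr::group_by(.data$station_id) |>
    dplyr::arrange(.data$depth, .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number(), .n = dplyr::n()) |>
    dplyr::ungroup()
  if (depth_rule == "upper-half") {
    keep <- dplyr::filter(keep, .data$.rank <= ceiling(.data$.n / 2))
  }
  keep <- dplyr::select(keep, "station_id", "depth")

  env_sel <- dplyr::inner_join(environment, keep,
                               by = c("station_id", "depth"))
  pp_by_station <- env_sel |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(pp_mean = mean(.data$pp), pp_sem = sem(.data$pp),
                     .groups = "drop")

  out <- rates |>
    dplyr::inner_join(keep, by = c("station_id", "depth")) |>
    dplyr::group_by(.data$station_id, .data$population) |>
    dplyr::summarise(
      n_depths = sum(.data$defined),
      abundance_mean = mean(.data$abundance),
      abundance_sem = sem(.data$abundance),
      mu_mean = mean(.data$mu[.data$defined]),
      mu_sem = sem(.data$mu[.data$defined]),
      m_mean = mean(.data$m[.data$defined]),
      m_sem = sem(.data$m[.data$defined]),
      net_mean = mean(.data$net[.data$defined]),
      net_sem = sem(.data$net[.data$defined]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      defined = .data$n_depths >= 1L,
      dplyr::across(c("mu_mean", "mu_sem", "m_mean", "m_sem",
                      "net_mean", "net_sem"),
                    ~ ifelse(.data$n_depths >= 1L, .x, NA_real_))
    ) |>
    dplyr::left_join(pp_by_station, by = "station_id") |>
    dplyr::arrange(.data$station_id,
                   factor(.data$population, levels = POPULATIONS))

  n1 <- sum(out$n_depths == 1L)
  if (n1 > 0) {
    inform(sprintf(
      "%d station x population mean(s) based on a single depth; SEM reported as 0",
      n1))
  }
  out
}
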