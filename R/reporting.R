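#' Assign stations to productivity classes
#'
#' @param pp Primary production, mg C m-3 d-1 (vectorized).
#' @param edges Two bin edges. Membership is `[0, e1)`, `[e1, e2]`,
#'   `(e2, Inf)`: the middle class is closed so the three labels
#'   partition the gradient (edge values are measure-zero in practice).
#' @return Factor with levels `"PP<10"`, `"10<PP<100"`, `"PP>100"` (for
#'   the default edges).
#' @export
pp_bin <- function(pp, edges = c(10, 100)) {
  stopifnot(length(edges) == 2, edges[1] < edges[2])
  labels <- if (identical(edges, c(10, 100))) PP_BINS else {
    c(sprintf("PP<%g", edges[1]),
      sprintf("%g<PP<%g", edges[1], edges[2]),
      sprintf("PP>%g", edges[2]))
  }
  out <- ifelse(pp < edges[1], labels[1],
                ifelse(pp <= edges[2], labels[2], labels[3]))
  factor(out, levels = labels)
}

#' Bin-level summary of station rates
#'
#' Assigns each station to one productivity class by its mean primary
#' production and summarises abundance, growth, grazing mortality, and
#' net growth per class x population as mean +/- SEM across stations.
#' Abundance averages over all stations in the class (absent populations
#' contribute zeros); rates average over stations where the population
#' was present ("nd" propagates when it never was). Empty combinations
#' are emitted with `n_stations = 0` and `NA` values so the table is
#' always rectangular.
#'
#' @param stations Station table from [aggregate_stations()].
#' @param edges Productivity class edges, mg C m-3 d-1.
#' @return A tibble: `pp_bin`, `population`, `n_stations`,
#'   `abundance_mean/_sem`, `mu_mean/_sem`, `m_mean/_sem`,
#'   `net_mean/_sem`.
#' @export
bin_stations <- function(stations, edges = c(10, 100)) {
  binned <- dplyr::mutate(stations, pp_bin = pp_bin(.data$pp_mean, edges))
  pops <- unique(stations$population)
  full <- tidyr::expand_grid(pp_bin = levels(binned$pp_bin),
                             population = pops)
  mean_or_na <- function(x) if (sum(is.finite(x)) == 0) NA_real_ else {
    mean(x[is.finite(x)])
  }
  sem_or_na <- function(x) if (sum(is.finite(x)) == 0) NA_real_ else {
    sem(x[is.finite(x)])
  }
  binned |>
    dplyr::group_by(pp_bin = as.character(.data$pp_bin), .data$population) |>
    # sem before mean within each pair: summarise evaluates sequentially and
    # the mean would otherwise mask the station-level column of the same name
    dplyr::summarise(
      n_stations = dplyr::n(),
      abundance_sem = sem(.data$abundance_mean),
      abundance_mean = mean(.data$abundance_mean),
      mu_sem = sem_or_na(.data$mu_mean),
      mu_mean = mean_or_na(.data$mu_mean),
      m_sem = sem_or_na(.data$m_mean),
      m_mean = mean_or_na(.data$m_mean),
      net_sem = sem_or_na(.data$net_mean),
      net_mean = mean_or_na(.data$net_mean),
      .groups = "drop"
    ) |>
    dplyr::select("pp_bin", "population", "n_stations",
                  "abundance_mean", "abundance_sem", "mu_mean", "mu_sem",
                  "m_mean", "m_sem", "net_mean", "net_sem") |>
    dplyr::right_join(full, by = c("pp_bin", "population")) |>
    dplyr::mutate(n_stations = dplyr::coalesce(.data$n_stations, 0L)) |>
    dplyr::arrange(factor(.data$pp_bin, levels = levels(binned$pp_bin)),
                   factor(.data$population, levels = POPULATIONS))
}

# ---- table IO ---------------------------------------------------------

table_units <- c(
  environment = "# station_id; depth m; temperature degC; nitrate uM; chla mg m-3; pp mg C m-3 d-1",
  bottles = "# station_id; depth m; population; d_measured fraction; counts cells mL-1; duration days",
  rates_by_depth = "# station_id; depth m; population; abundance cells mL-1; d fraction; k, k_d, m, mu, net d-1",
  station_rates = "# station_id; population; abundance cells mL-1; mu, m, net d-1; pp mg C m-3 d-1; mean +/- SEM",
  regression_fits = "# slope/intercept on the recorded transforms; p_perm two-sided permutation p",
  bin_summary = "# pp_bin classes of pp mg C m-3 d-1; abundance cells mL-1; mu, m, net d-1; mean +/- SEM",
  projections = "# rates d-1; daily_decline_pct percent; days_to_threshold days; n0, threshold cells mL-1"
)

#' Write a pipeline table with a units header
#'
#' Tab-separated, preceded by a `#` comment line naming the units, so the
#' files round-trip through [read_table()].
#'
#' @param x Tibble to write.
#' @param path Output file.
#' @param what Table name (one of the pipeline's table kinds) selecting
#'   the units header; `NULL` writes no header.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, what = NULL) {
  header <- if (!is.null(what) && what %in% names(table_units)) {
    table_units[[what]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  cat(readr::format_tsv(x), file = con, sep = "")
  invisible(path)
}

#' Read a pipeline table
#'
#' Reads the TSV tables written by [write_table()] (or equivalently
#' formatted field data), skipping `#` comment lines.
#'
#' @param path Input file.
#' @return A tibble.
#' @export
read_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

# ---- pipeline ---------------------------------------------------------

default_pipeline_config <- function() {
  list(
    simulation = list(n_stations = 100, depths_per_station = 3, seed = 1),
    depth_rule = "upper-half",
    regression = list(
      method = "SMA", n_perm = 999, log_x = TRUE, log_y = TRUE,
      responses = list(
        list(population = "HBAC", response = "m_mean"),
        list(population = "SYN", response = "m_mean"),
        list(population = "HBAC", response = "mu_mean")
      )
    ),
    projection = list(reference = "HBAC", low_max = 10, high_min = 100,
                      n0 = 1e4, threshold = 1),
    bin_edges = c(10, 100)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
                        !is.null(names(override[[nm]]))) {
      merge_config(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> estimate -> aggregate -> regress -> project ->
#' summarise end to end from a single configuration, optionally writing
#' every table (plus a provenance report) to `out_dir`. Rerunning with
#' the same configuration and seed reproduces the outputs byte for byte.
#'
#' The configuration is a nested list (or the path to a YAML file with
#' the same shape); omitted entries take documented defaults: a
#' `simulation` block ([sim_config()] arguments), `depth_rule`
#' ([aggregate_stations()]), a `regression` block (`method`, `n_perm`,
#' `log_x`, `log_y`, and `responses`, a list of
#' `list(population=, response=)` pairs fitted over [default_segments()];
#' the mortality-ratio regressions relative to the projection reference
#' are always added), a `projection` block
#' ([shared_predation_inputs()] / [project_shared_predation()]
#' arguments), and `bin_edges` ([bin_stations()]). Instead of simulating,
#' set `config$input$environment` and `config$input$bottles` to file
#' paths to analyse existing tables.
#'
#' @param config Nested list or path to a YAML file; see Details.
#' @param out_dir Optional output directory (created if needed).
#' @return A list with the `config` used and tibbles `environment`,
#'   `bottles`, `rates_by_depth`, `station_rates`, `regression_fits`,
#'   `projections`, `bin_summary`, plus a `report` list (seed, row
#'   counts, package version).
#' @export
#' @examples
#' res <- run_pipeline(list(simulation = list(n_stations = 12, seed = 3)))
#' res$bin_summary
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)

  if (!is.null(cfg$input)) {
    for (f in c("environment", "bottles")) {
      if (is.null(cfg$input[[f]]) || !file.exists(cfg$input[[f]])) {
        abort(sprintf("input file for `%s` not found: %s", f,
                      cfg$input[[f]] %||% "<missing>"),
              class = "picograze_config_error")
      }
    }
    environment <- read_table(cfg$input$environment)
    bottles <- read_table(cfg$input$bottles)
    sim_seed <- cfg$simulation$seed
  } else {
    sim <- do.call(sim_config, cfg$simulation)
    cruise <- simulate_cruise(sim)
    environment <- cruise$environment
    bottles <- cruise$bottles
    sim_seed <- sim$seed
  }

  rates <- estimate_rates(bottles)
  stations <- aggregate_stations(rates, environment,
                                 depth_rule = cfg$depth_rule)

  reg <- cfg$regression
  ratio_stations <- station_mortality_ratios(
    stations, reference = cfg$projection$reference)
  fit_specs <- reg$responses
  fits <- purrr::imap(fit_specs, function(sp, i) {
    segment_regressions(
      stations, response = sp$response, population = sp$population,
      method = reg$method, log_x = reg$log_x, log_y = reg$log_y,
      n_perm = reg$n_perm, seed = sim_seed * 1000L + i * 10L
    )
  })
  ratio_pops <- setdiff(unique(ratio_stations$population),
                        cfg$projection$reference)
  ratio_fits <- purrr::imap(setNames(ratio_pops, ratio_pops), function(p, i) {
    segment_regressions(
      ratio_stations, response = "ratio", population = p,
      method = reg$method, log_x = reg$log_x, log_y = reg$log_y,
      n_perm = reg$n_perm,
      seed = sim_seed * 1000L + 900L + match(p, ratio_pops) * 10L
    )
  })
  regression_fits <- dplyr::bind_rows(c(fits, ratio_fits))

  proj_in <- shared_predation_inputs(
    stations, reference = cfg$projection$reference,
    low_max = cfg$projection$low_max, high_min = cfg$projection$high_min)
  projections <- project_shared_predation(
    proj_in, n0 = cfg$projection$n0, threshold = cfg$projection$threshold)

  bin_summary <- bin_stations(stations, edges = cfg$bin_edges)

  report <- list(
    seed = sim_seed,
    package_version = as.character(utils::packageVersion("picograze")),
    config = cfg,
    rows = list(
      environment = nrow(environment), bottles = nrow(bottles),
      rates_by_depth = nrow(rates), station_rates = nrow(stations),
      regression_fits = nrow(regression_fits),
      projections = nrow(projections), bin_summary = nrow(bin_summary)
    ),
    undefined_estimates = sum(!rates$defined)
  )

  out <- list(config = cfg, environment = environment, bottles = bottles,
              rates_by_depth = rates, station_rates = stations,
              regression_fits = regression_fits, projections = projections,
              bin_summary = bin_summary, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("environment", "bottles", "rates_by_depth", "station_rates",
                 "regression_fits", "projections", "bin_summary")) {
      write_table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")), nm)
    }
    yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  }
  out
}
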