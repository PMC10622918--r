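test_that("productivity classes partition the gradient", {
  pp <- c(0.5, 5, 9.999, 10, 50, 100, 100.01, 250)
  b <- pp_bin(pp)
  expect_equal(as.character(b),
               c("PP<10", "PP<10", "PP<10", "10<PP<100", "10<PP<100",
                 "10<PP<100", "PP>100", "PP>100"))
  expect_false(anyNA(b))
  custom <- pp_bin(c(1, 3, 8), edges = c(2, 5))
  expect_equal(levels(custom), c("PP<2", "2<PP<5", "PP>5"))
})

test_that("bin summary counts every station exactly once", {
  stations <- simulate_and_aggregate(seed = 17, n_stations = 40)
  bins <- bin_stations(stations)
  per_pop <- dplyr::count(bins, population, wt = n_stations)
  expect_true(all(per_pop$n == 40L))
  expect_equal(nrow(bins), 3 * 4)
})

test_that("bin means and SEMs agree with direct computation", {
  stations <- tibble::tibble(
    station_id = sprintf("S%02d", 1:4),
    population = "SYN",
    pp_mean = c(3, 5, 40, 300),
    abundance_mean = c(1e4, 2e4, 5e4, 1.5e4),
    mu_mean = c(0.5, 0.4, 0.4, 0.35),
    m_mean = c(0.6, 0.5, 0.3, 0.2),
    net_mean = c(-0.1, -0.1, 0.1, 0.15),
    defined = TRUE
  )
  bins <- bin_stations(stations)
  low <- dplyr::filter(bins, pp_bin == "PP<10")
  expect_equal(low$n_stations, 2L)
  expect_equal(low$mu_mean, 0.45)
  expect_equal(low$mu_sem, sd(c(0.5, 0.4)) / sqrt(2))
  expect_equal(low$net_mean, low$mu_mean - low$m_mean)
  # singleton and empty-for-population cells still appear
  expect_equal(dplyr::filter(bins, pp_bin == "PP>100")$n_stations, 1L)
  mid <- dplyr::filter(bins, pp_bin == "10<PP<100")
  expect_equal(mid$m_sem, 0)

  two <- bin_stations(dplyr::mutate(stations,
                                    net_mean = c(0.1, 0.3, NA, NA)))
  expect_equal(dplyr::filter(two, pp_bin == "PP<10")$net_mean, 0.2)
  expect_equal(dplyr::filter(two, pp_bin == "PP<10")$net_sem, 0.1)
})

test_that("nd propagates when a population is absent from a whole class", {
  stations <- simulate_and_aggregate(seed = 23, n_stations = 60)
  bins <- bin_stations(stations)
  pro_high <- dplyr::filter(bins, pp_bin == "PP>100", population == "PRO")
  expect_true(is.na(pro_high$mu_mean))
  expect_equal(pro_high$abundance_mean, 0)
})

test_that("noise-free class means sit on the published anchors", {
  cruise <- simulate_cruise(noise_free_cfg(n_stations = 150, seed = 29))
  stations <- suppressMessages(aggregate_stations(
    estimate_rates(cruise$bottles), cruise$environment))
  bins <- bin_stations(stations)
  anchors <- cce_picoplankton_rates()
  joined <- dplyr::inner_join(
    bins, anchors, by = c("pp_bin", "population"),
    suffix = c("", "_anchor"))
  joined <- dplyr::filter(joined, !is.na(mu))
  # interpolation across each class biases the class mean away from the
  # center anchor by design; the published 2-SEM band must still hold
  expect_true(all(abs(joined$mu_mean - joined$mu) <= 2 * joined$mu_sem_anchor))
  expect_true(all(abs(joined$m_mean - joined$m) <= 2 * joined$m_sem_anchor))
  syn_high <- dplyr::filter(joined, pp_bin == "PP>100", population == "SYN")
  expect_equal(syn_high$net_mean, 0.19, tolerance = 2 * 0.03 / 0.19)
})

test_that("station-level and depth-level averaging agree on balanced data", {
  cruise <- simulate_cruise(noise_free_cfg(n_stations = 12, seed = 37))
  rates <- estimate_rates(cruise$bottles)
  stations <- suppressMessages(aggregate_stations(rates, cruise$environment))
  hbac <- dplyr::filter(stations, population == "HBAC")
  # every station contributes the same number of depths, so the mean of
  # station means equals the pooled depth-level mean
  keep <- dplyr::semi_join(
    rates,
    dplyr::distinct(
      dplyr::filter(
        dplyr::mutate(
          dplyr::group_by(cruise$environment, station_id),
          rank = rank(depth), nd = dplyr::n()),
        rank <= ceiling(nd / 2)),
      station_id, depth),
    by = c("station_id", "depth"))
  pooled <- mean(dplyr::filter(keep, population == "HBAC")$mu)
  expect_equal(mean(hbac$mu_mean), pooled, tolerance = 1e-12)
})

test_that("tables round-trip through the units-commented TSV format", {
  dir <- withr::local_tempdir()
  cruise <- simulate_cruise(sim_config(n_stations = 3, seed = 2))
  path <- file.path(dir, "bottles.tsv")
  write_table(cruise$bottles, path, "bottles")
  expect_match(readLines(path, n = 1), "^# station_id")
  back <- read_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cruise$bottles),
               tolerance = 1e-12)
})

test_that("pipeline runs end to end, writes all tables, and is deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- list(simulation = list(n_stations = 16, seed = 8),
              regression = list(n_perm = 99))
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg, out_dir = dir1)))
  expect_named(
    res,
    c("config", "environment", "bottles", "rates_by_depth", "station_rates",
      "regression_fits", "projections", "bin_summary", "report"))
  tables <- c("environment.tsv", "bottles.tsv", "rates_by_depth.tsv",
              "station_rates.tsv", "regression_fits.tsv", "projections.tsv",
              "bin_summary.tsv")
  expect_true(all(file.exists(file.path(dir1, tables))))
  expect_gt(nrow(res$regression_fits), 0)
  expect_equal(nrow(res$bin_summary), 12)

  suppressMessages(suppressWarnings(run_pipeline(cfg, out_dir = dir2)))
  for (tb in tables) {
    expect_identical(readLines(file.path(dir1, tb)),
                     readLines(file.path(dir2, tb)),
                     label = sprintf("%s bytes", tb))
  }
})

test_that("the bundled demo configuration runs the whole pipeline", {
  demo <- system.file("extdata", "cruise-demo.yaml", package = "picograze")
  expect_true(nzchar(demo))
  cfg <- yaml::read_yaml(demo)
  cfg$simulation$n_stations <- 15   # keep the smoke run quick
  cfg$regression$n_perm <- 49
  dir <- withr::local_tempdir()
  res <- suppressMessages(suppressWarnings(run_pipeline(cfg, out_dir = dir)))
  expect_gte(length(list.files(dir, pattern = "\\.tsv$")), 6)
  expect_true(file.exists(file.path(dir, "report.yaml")))
  expect_equal(res$report$seed, 1)
})

test_that("pipeline analyses existing tables and fails fast on missing input", {
  dir <- withr::local_tempdir()
  cruise <- simulate_cruise(sim_config(n_stations = 10, seed = 4))
  write_table(cruise$environment, file.path(dir, "environment.tsv"),
              "environment")
  write_table(cruise$bottles, file.path(dir, "bottles.tsv"), "bottles")
  res <- suppressMessages(suppressWarnings(run_pipeline(list(
    input = list(environment = file.path(dir, "environment.tsv"),
                 bottles = file.path(dir, "bottles.tsv")),
    regression = list(n_perm = 49)
  ))))
  expect_equal(nrow(res$station_rates), 10 * 4)
  expect_error(
    run_pipeline(list(input = list(environment = "does-not-exist.tsv"))),
    "environment", class = "picograze_config_error")
})
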