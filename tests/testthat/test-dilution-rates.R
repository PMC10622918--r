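test_that("net rate is the exponential rate over the incubation", {
  expect_equal(net_rate(1000, 1000, 1), 0)
  expect_equal(net_rate(1000, 2718.28, 1), 1, tolerance = 1e-5)
  expect_equal(net_rate(500, 250, 0.5), log(0.5) / 0.5)
  # nonpositive counts signal an undefined rate, not an error
  expect_true(is.na(net_rate(0, 100, 1)))
  expect_true(is.na(net_rate(100, 0, 1)))
  expect_error(net_rate(100, 100, 0), class = "picograze_rate_error")
})

test_that("two-treatment estimator recovers the defining arithmetic", {
  # k = 0.2, k_d = 0.5, D = 0.33: m = 0.3/0.67, mu = k + m
  pair <- tibble::tibble(
    station_id = "S001", depth = 5, population = "HBAC", d_measured = 0.33,
    n0_undiluted = 1000, nf_undiluted = 1000 * exp(0.2),
    n0_diluted = 330, nf_diluted = 330 * exp(0.5), duration = 1
  )
  est <- estimate_rates(pair)
  expect_equal(est$k, 0.2)
  expect_equal(est$k_d, 0.5)
  expect_equal(est$m, 0.3 / 0.67)
  expect_equal(est$mu, 0.2 + 0.3 / 0.67)
  expect_equal(est$net, est$k)

  # equal apparent rates in both treatments: no grazing
  same <- make_pair(mu = 0.4, m = 0)
  est0 <- estimate_rates(same)
  expect_equal(est0$m, 0)
  expect_equal(est0$mu, est0$k)
})

test_that("estimator is the exact inverse of the forward model at published rates", {
  pair <- make_pair(mu = 0.79, m = 0.61, population = "HBAC")
  est <- estimate_rates(pair)
  expect_equal(est$mu, 0.79)
  expect_equal(est$m, 0.61)
  expect_equal(est$net, 0.18)

  syn <- estimate_rates(make_pair(mu = 0.48, m = 0.57))
  expect_equal(syn$net, -0.09)
})

test_that("identities, unit invariance, and monotonicity hold", {
  cfg <- sim_config(n_stations = 5, seed = 9)
  cruise <- simulate_cruise(cfg)
  est <- dplyr::filter(estimate_rates(cruise$bottles), defined)
  expect_equal(est$mu, est$k + est$m)
  expect_equal(est$net, est$k)
  expect_equal(est$mu - est$m, est$k)

  # common rescaling of all four counts leaves every rate unchanged
  scaled <- dplyr::mutate(
    cruise$bottles,
    dplyr::across(dplyr::starts_with("n"), ~ .x * 7.3))
  est2 <- dplyr::filter(estimate_rates(scaled), defined)
  expect_equal(est2$m, est$m)
  expect_equal(est2$mu, est$mu)

  # m strictly increases with k_d at fixed k, and with D at fixed k_d - k > 0
  m_of <- function(k_d, d) {
    estimate_rates(tibble::tibble(
      station_id = "s", depth = 5, population = "SYN", d_measured = d,
      n0_undiluted = 1000, nf_undiluted = 1000 * exp(0.1),
      n0_diluted = 1000 * d, nf_diluted = 1000 * d * exp(k_d), duration = 1
    ))$m
  }
  kds <- seq(0.1, 0.8, by = 0.1)
  expect_true(all(diff(vapply(kds, m_of, numeric(1), d = 0.33)) > 0))
  ds <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(ds, m_of, numeric(1), k_d = 0.5)) > 0))
})

test_that("degenerate pairs are signalled, not silently estimated", {
  bad_d <- make_pair(mu = 0.5, m = 0.2, d = 1.0)
  expect_error(estimate_rates(bad_d), "cannot resolve grazing",
               class = "picograze_rate_error")
  zero <- make_pair(mu = 0.5, m = 0.2)
  zero$nf_undiluted <- 0
  est <- estimate_rates(zero)
  expect_false(est$defined)
  expect_true(is.na(est$m) && is.na(est$mu))
  expect_error(estimate_rates(dplyr::select(zero, -n0_diluted)),
               "n0_diluted", class = "picograze_schema_error")
})

test_that("missing dilution factor falls back to the initial-count ratio", {
  pair <- make_pair(mu = 0.6, m = 0.3, d = 0.4)
  pair$d_measured <- NA_real_
  est <- estimate_rates(pair)
  expect_equal(est$d, 0.4)
  expect_equal(est$mu, 0.6)
  expect_equal(est$m, 0.3)
})

test_that("station aggregation averages the upper-euphotic depths", {
  env <- tibble::tibble(
    station_id = "S001", depth = c(5, 15, 25),
    temperature = 15, nitrate = 1, chla = 0.5, pp = c(20, 22, 24)
  )
  rates <- dplyr::bind_rows(
    make_pair(mu = 0.4, m = 0.2, depth = 5),
    make_pair(mu = 0.6, m = 0.4, depth = 15),
    make_pair(mu = 5.0, m = 5.0, depth = 25)  # deep depth must be excluded
  ) |> estimate_rates()
  st <- suppressMessages(aggregate_stations(rates, env,
                                            depth_rule = "upper-half"))
  expect_equal(nrow(st), 1)
  expect_equal(st$n_depths, 2L)
  expect_equal(st$mu_mean, 0.5)
  expect_equal(st$mu_sem, sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(st$mu_sem, 0.1, tolerance = 1e-6)
  expect_equal(st$pp_mean, mean(c(20, 22)))

  all_depths <- suppressMessages(aggregate_stations(rates, env,
                                                    depth_rule = "all"))
  expect_equal(all_depths$n_depths, 3L)
})

test_that("single-depth stations report SEM 0 with a message", {
  env <- tibble::tibble(station_id = "S001", depth = 5,
                        temperature = 15, nitrate = 1, chla = 0.5, pp = 20)
  rates <- estimate_rates(make_pair(mu = 0.4, m = 0.2))
  expect_message(st <- aggregate_stations(rates, env, depth_rule = "all"),
                 "single depth")
  expect_equal(st$mu_mean, 0.4)
  expect_equal(st$mu_sem, 0)
})

test_that("populations absent at every depth aggregate to an nd record", {
  env <- tibble::tibble(station_id = "S001", depth = c(5, 15),
                        temperature = 12, nitrate = 5, chla = 2, pp = c(150, 160))
  pro <- tibble::tibble(
    station_id = "S001", depth = c(5, 15), population = "PRO",
    d_measured = 0.33, n0_undiluted = 0, nf_undiluted = 0,
    n0_diluted = 0, nf_diluted = 0, duration = 1
  )
  rates <- estimate_rates(dplyr::bind_rows(
    make_pair(mu = 0.7, m = 0.6, population = "HBAC", depth = 5),
    make_pair(mu = 0.8, m = 0.5, population = "HBAC", depth = 15),
    pro
  ))
  st <- aggregate_stations(rates, env, depth_rule = "all")
  pro_row <- dplyr::filter(st, population == "PRO")
  expect_false(pro_row$defined)
  expect_equal(pro_row$n_depths, 0L)
  expect_equal(pro_row$abundance_mean, 0)
  expect_true(is.na(pro_row$mu_mean) && is.na(pro_row$m_mean))
  expect_true(dplyr::filter(st, population == "HBAC")$defined)
  expect_error(aggregate_stations(rates[0, ], env), class = "picograze_agg_error")
})
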