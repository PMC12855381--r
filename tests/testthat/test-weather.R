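make_obs <- function(n_years, tmax = 20, tmin = 10, precip_fun = NULL,
                     rad = 15) {
  doy <- rep(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365)
  precip <- if (is.null(precip_fun)) rep(0, length(doy)) else
    precip_fun(length(doy))
  data.frame(year = year, doy = doy, tmin_c = tmin, tmax_c = tmax,
             precip_mm = precip, rad_mj_m2 = rad)
}

test_that("parameter estimation recovers degenerate series exactly", {
  p <- estimate_params(make_obs(3, tmax = 20, tmin = 12))
  expect_equal(p$monthly_mean_tmax, rep(20, 12))
  expect_equal(p$monthly_sd_tmax, rep(0, 12))
  expect_equal(p$p_wet_given_dry, rep(0, 12))
  expect_equal(p$p_wet_given_wet, rep(0, 12))
  expect_true(all(is.na(p$wet_amount_shape)))
})

test_that("estimation reports missing days by name", {
  obs <- make_obs(3)
  obs <- obs[!(obs$year == 2 & obs$doy == 100), ]
  expect_error(estimate_params(obs), "year 2 is missing day.*100")
  expect_error(estimate_params(make_obs(2)), "at least 3")
})

test_that("generated series re-estimate to the generating parameters", {
  site <- make_site_params(site_fixture_spec("rt", "wet_temperate", seed = 1))
  ser <- generate_series(site, 10, seed = 42)
  est <- estimate_params(ser, latitude = site$latitude)
  # autocorrelation-deflated effective sample size; 3 standard errors so
  # that 24 simultaneous month-level comparisons rarely trip by chance
  rho <- site$temp_autocorr
  n_eff <- 10 * 30 * (1 - rho) / (1 + rho)
  tol <- 3 * site$monthly_sd_tmax / sqrt(n_eff)
  expect_true(all(abs(est$monthly_mean_tmax - site$monthly_mean_tmax) < tol))
  expect_true(all(abs(est$monthly_mean_tmin - site$monthly_mean_tmin) < tol))
})

test_that("generation honours the dry chain, series length and moments", {
  site <- benign_site_params()
  dry <- site
  dry$p_wet_given_dry <- rep(0, 12)
  dry$p_wet_given_wet <- rep(0, 12)
  ser_dry <- generate_series(dry, 3, seed = 9)
  expect_true(all(ser_dry$precip_mm == 0))

  ser <- generate_series(site, 100, seed = 9)
  expect_equal(nrow(ser), 36500)
  expect_true(all(ser$tmax_c >= ser$tmin_c))
  expect_true(all(ser$precip_mm >= 0))
  expect_true(all(ser$rad_mj_m2 >= 0))

  # January tmax mean within 3 autocorrelation-adjusted standard errors
  jan <- ser$tmax_c[ser$doy <= 31]
  rho <- site$temp_autocorr
  se <- site$monthly_sd_tmax[1] /
    sqrt(length(jan) * (1 - rho) / (1 + rho))
  expect_lt(abs(mean(jan) - site$monthly_mean_tmax[1]), 3 * se)

  # wet-day frequency close to the chain's stationary value
  p_wd <- site$p_wet_given_dry[1]
  p_ww <- site$p_wet_given_wet[1]
  pi_wet <- p_wd / (1 + p_wd - p_ww)
  expect_lt(abs(mean(ser$precip_mm[ser$doy <= 31] > 0) - pi_wet), 0.06)
})

test_that("byte-identical series under an identical seed", {
  site <- benign_site_params()
  expect_identical(generate_series(site, 5, seed = 77),
                   generate_series(site, 5, seed = 77))
  expect_false(identical(generate_series(site, 5, seed = 77),
                         generate_series(site, 5, seed = 78)))
})

test_that("delta-change algebra is exact", {
  site <- benign_site_params()
  zero <- climate_delta(rep(0, 12), rep(0, 12), rep(1, 12), rep(1, 12),
                        co2 = 363.8)
  expect_equal(unclass(apply_delta(site, zero))[names(site)],
               unclass(site)[names(site)])

  annihilate <- climate_delta(rep(0, 12), rep(0, 12), rep(0, 12), rep(1, 12),
                              co2 = 363.8)
  expect_equal(apply_delta(site, annihilate)$wet_amount_mean, rep(0, 12))

  d1 <- climate_delta(rep(1.5, 12), rep(1, 12), rep(0.9, 12), rep(1.01, 12),
                      co2 = 500)
  d2 <- climate_delta(rep(2, 12), rep(2.5, 12), rep(1.2, 12), rep(0.99, 12),
                      co2 = 700)
  composed <- apply_delta(apply_delta(site, d1), d2)
  expect_equal(composed$monthly_mean_tmax,
               site$monthly_mean_tmax + d1$d_tmax + d2$d_tmax)
  expect_equal(composed$wet_amount_mean,
               site$wet_amount_mean * d1$precip_factor * d2$precip_factor)
  # second moments and occurrence untouched
  expect_equal(composed$monthly_sd_tmax, site$monthly_sd_tmax)
  expect_equal(composed$p_wet_given_wet, site$p_wet_given_wet)
  expect_equal(composed$wet_amount_shape, site$wet_amount_shape)
})

test_that("a shared seed turns a temperature delta into an exact shift", {
  site <- benign_site_params()
  d <- climate_delta(c(0, 0, 0, 0, 0, 3, 0, 0, 0, 0, 0, 0), rep(0, 12),
                     rep(1, 12), rep(1, 12), co2 = 363.8)
  base <- generate_series(site, 200, seed = 5)
  warm <- generate_series(apply_delta(site, d), 200, seed = 5)
  jun <- month_of_doy(base$doy) == 6
  expect_equal(warm$tmax_c[jun] - base$tmax_c[jun], rep(3, sum(jun)))
  expect_equal(warm$tmax_c[!jun], base$tmax_c[!jun])
})
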