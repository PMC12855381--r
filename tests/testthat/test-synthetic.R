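test_that("site parameter expansion follows the seasonal sinusoid", {
  flat <- site_fixture_spec("flat", "hot_narrow", seasonal_amplitude = 0,
                            mean_annual_tmax = 20)
  p <- make_site_params(flat)
  expect_equal(p$monthly_mean_tmax, rep(20, 12))

  south <- make_site_params(site_fixture_spec("s", "cool_variable",
                                              latitude = -35))
  expect_true(which.max(south$monthly_mean_tmax) %in% c(12, 1, 2))
  north <- make_site_params(site_fixture_spec("n", "cool_variable",
                                              latitude = 52))
  expect_equal(which.max(north$monthly_mean_tmax), 7)
})

test_that("archetype sd vectors pass through verbatim and expansion is pure", {
  cool <- site_fixture_spec("c", "cool_variable", tmax_sd_by_month = 6)
  hot <- site_fixture_spec("h", "hot_narrow", tmax_sd_by_month = 2)
  expect_equal(make_site_params(cool)$monthly_sd_tmax, rep(6, 12))
  expect_equal(make_site_params(hot)$monthly_sd_tmax, rep(2, 12))
  expect_identical(make_site_params(cool), make_site_params(cool))
})

test_that("invalid archetypes and invalid descriptors are rejected", {
  expect_error(site_fixture_spec("x", "mediterranean"), "archetype")
  expect_error(site_fixture_spec("x", "hot_narrow",
                                 wet_day_prob_by_month = 1.2),
               "probabilities")
})

test_that("delta ensembles honour spread, range, and the seed contract", {
  degenerate <- make_delta_ensemble(1, warming_mean = 2, warming_spread = 0,
                                    precip_factor_range = c(1, 1),
                                    co2 = 500, seed = 7)
  expect_equal(degenerate[[1]]$d_tmax, rep(2, 12))
  expect_equal(degenerate[[1]]$d_tmin, rep(2, 12))

  e1 <- make_delta_ensemble(15, 4.8, 1.0, c(0.8, 1.2), co2 = 1001.8, seed = 3)
  e2 <- make_delta_ensemble(15, 4.8, 1.0, c(0.8, 1.2), co2 = 1001.8, seed = 3)
  expect_identical(e1, e2)
  expect_true(all(sapply(e1, function(d) all(d$precip_factor >= 0.8 &
                                               d$precip_factor <= 1.2))))

  # Monte-Carlo: mean monthly offset over 200 members within 4.8 +/- 0.2
  big <- make_delta_ensemble(200, 4.8, 1.0, c(0.9, 1.1), co2 = 1001.8,
                             seed = 5)
  offsets <- unlist(lapply(big, `[[`, "d_tmax"))
  expect_lt(abs(mean(offsets) - 4.8), 0.2)
})

test_that("cultivar profiles set only the mechanism switches", {
  base <- cultivar_params(n_pot = 123, w_pot = 0.05)
  tol <- make_cultivar("tolerant", base)
  expect_false(tol$drought_mech_on)
  expect_false(tol$heat_mech_on)

  heat_only <- make_cultivar("heat_sensitive_only", base)
  expect_false(heat_only$drought_mech_on)
  expect_true(heat_only$heat_mech_on)

  both <- make_cultivar("sensitive_both", base)
  expect_identical(both, base)

  non_switch <- setdiff(names(base), c("drought_mech_on", "heat_mech_on"))
  expect_identical(tol[non_switch], base[non_switch])
  expect_error(make_cultivar("mystery", base))
})

test_that("hot-narrow vs cool-variable archetypes contrast as designed", {
  # hot_narrow: warmer growing season, but smaller across-year variability
  # of the flowering-window temperature maximum
  cool <- make_site_params(site_fixture_spec("c", "cool_variable"))
  hot <- make_site_params(site_fixture_spec("h", "hot_narrow"))
  ser_c <- generate_series(cool, 60, seed = 21)
  ser_h <- generate_series(hot, 60, seed = 22)

  # growing seasons: spring sowing doy 75 (cool), autumn doy 320 (hot)
  season_mean <- function(ser, sow, len) {
    idx <- rep((0:58) * 365, each = len) + sow + 0:(len - 1)
    mean(ser$tmax_c[idx])
  }
  expect_gt(season_mean(ser_h, 320, 120), season_mean(ser_c, 75, 120))

  # 11-day window maxima around each archetype's typical anthesis doy
  window_max_sd <- function(ser, center) {
    sd(vapply(0:58, function(y) {
      max(ser$tmax_c[y * 365 + center + (-10:0)])
    }, numeric(1)))
  }
  expect_lt(window_max_sd(ser_h, 389), window_max_sd(ser_c, 181))
})
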