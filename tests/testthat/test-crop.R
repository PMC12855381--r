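test_that("RUE responds linearly to CO2", {
  expect_identical(rue_co2_multiplier(363.8, 363.8), 1)
  expect_identical(rue_co2_multiplier(2 * 363.8, 363.8), 1.3)
  expect_equal(rue_co2_multiplier(562.8, 363.8),
               1 + 0.3 * (562.8 / 363.8 - 1))
  expect_equal(rue_co2_multiplier(562.8, 363.8), 1.16409, tolerance = 1e-5)
  expect_error(rue_co2_multiplier(-1), "> 0")
})

test_that("anthesis day matches thermal-time accumulation", {
  cv <- cultivar_params(tt_sowing_to_anthesis = 1000, base_temp = 0)
  w <- const_weather(200, tmin = 20, tmax = 20)
  expect_identical(anthesis_day(w, cv), 50L)

  set.seed(4)
  w2 <- const_weather(250, tmin = 5, tmax = 15)
  w2$tmax_c <- w2$tmax_c + rnorm(250, 0, 3)
  w2$tmin_c <- w2$tmax_c - 10
  # independent day-by-day accumulation oracle
  tmean <- (w2$tmax_c + w2$tmin_c) / 2
  acc <- 0
  das_oracle <- NA
  for (i in seq_len(250)) {
    acc <- acc + max(0, tmean[i] - cv$base_temp)
    if (acc >= 1000) { das_oracle <- i; break }
  }
  expect_identical(anthesis_day(w2, cv), das_oracle)

  warmer <- w2
  warmer$tmax_c <- warmer$tmax_c + 2
  warmer$tmin_c <- warmer$tmin_c + 2
  expect_lt(anthesis_day(warmer, cv), anthesis_day(w2, cv))

  cold <- const_weather(100, tmin = -5, tmax = 1)
  expect_error(anthesis_day(cold, cv), class = "season_failure")
})

test_that("canopy temperature interpolates between air and air + dmax", {
  cfg <- crop_model_config(canopy_dmax = 5, canopy_rad_ref = 25)
  expect_equal(canopy_tmax(30, 1, 20, cfg), 30)
  expect_equal(canopy_tmax(30, 0, 25, cfg), 35)
  expect_equal(canopy_tmax(30, 0.5, 25, cfg), 32.5)
  expect_equal(canopy_tmax(30, 0.25, 12.5, cfg), 30 + 5 * 0.75 * 0.5)
  expect_error(canopy_tmax(30, 1.2, 20, cfg), "supply_ratio")
})

test_that("the daily water balance conserves water and respects limits", {
  soil <- soil_params(sawc = 100, initial_smd = 20)
  cfg <- crop_model_config()

  # ample water: transpiration meets demand
  wb <- water_balance_step(100, das = 80, precip = 0, tmean = 18,
                           radiation = 20, f_int = 0.8, soil = soil,
                           config = cfg)
  expect_equal(wb$supply, 1)
  expect_equal(wb$ta, wb$tp)

  # 30-day ledger: initial + sum(precip) = final + sum(ETa) + sum(drainage)
  set.seed(11)
  precip <- rgamma(30, 0.8, scale = 8) * rbinom(30, 1, 0.4)
  store <- soil$sawc - soil$initial_smd
  eta_sum <- 0
  drain_sum <- 0
  for (i in 1:30) {
    wb <- water_balance_step(store, i, precip[i], 16, 18, 0.5, soil, cfg)
    eta_sum <- eta_sum + wb$eta
    drain_sum <- drain_sum + wb$drainage
    expect_gte(wb$store, 0)
    expect_lte(wb$store, soil$sawc)
    expect_lte(wb$ta, wb$tp + 1e-12)
    expect_lte(wb$eta, wb$etp + 1e-12)
    store <- wb$store
  }
  expect_equal((soil$sawc - soil$initial_smd) + sum(precip),
               store + eta_sum + drain_sum)

  # exhaustion: no rain drives root-available water and transpiration to 0
  store <- 40
  for (i in 1:200) {
    wb <- water_balance_step(store, i, 0, 25, 22, 0.7, soil, cfg)
    store <- wb$store
  }
  expect_lt(wb$raw, 1e-3)
  expect_lt(wb$ta, 1e-4)
})

test_that("a tolerant cultivar is untouched by flowering-window extremes", {
  # hot, bone-dry season: heavy stress for a sensitive cultivar
  w <- const_weather(250, tmin = 22, tmax = 34, precip = 0, rad = 22)
  soil <- soil_params(sawc = 120, initial_smd = 0)
  tol <- make_cultivar("tolerant")
  sens <- make_cultivar("sensitive_both")
  r_tol <- run_season(w, tol, soil)
  r_sens <- run_season(w, sens, soil)
  expect_season_ok(r_tol)
  expect_identical(c(r_tol$r_d, r_tol$r_h, r_tol$r_w), c(1, 1, 1))
  expect_lt(r_sens$r_d, 1)
  expect_lt(r_sens$yield, r_tol$yield)
  expect_equal(r_sens$anthesis_das, r_tol$anthesis_das)
})

test_that("doubling CO2 scales biomass by exactly 1.30 when water is ample", {
  w <- const_weather(250, tmin = 12, tmax = 22, precip = 8, rad = 16)
  soil <- soil_params(sawc = 300, initial_smd = 0)
  cv <- make_cultivar("tolerant")
  r1 <- run_season(w, cv, soil, co2 = 363.8, co2_ref = 363.8)
  r2 <- run_season(w, cv, soil, co2 = 727.6, co2_ref = 363.8)
  expect_true(all(r1$daily$supply == 1))
  expect_equal(r2$biomass / r1$biomass, 1.3)
})

test_that("a benign season yields identically for all profiles", {
  w <- const_weather(250, tmin = 10, tmax = 20, precip = 6, rad = 15)
  soil <- soil_params(sawc = 250, initial_smd = 0)
  yields <- sapply(c("tolerant", "sensitive_both", "drought_sensitive_only",
                     "heat_sensitive_only"), function(p) {
    run_season(w, make_cultivar(p), soil)$yield
  })
  expect_true(all(abs(yields - yields[1]) < 1e-12))
})

test_that("sensitive yield never exceeds tolerant yield (30 random years)", {
  site <- water_limited_site()
  ser <- generate_series(site$params, 31, seed = 31)
  tol <- make_cultivar("tolerant", site$cultivar)
  sens <- make_cultivar("sensitive_both", site$cultivar)
  for (y in 1:30) {
    w <- season_slice(ser, y, 70)
    r_t <- run_season(w, tol, site$soil)
    r_s <- run_season(w, sens, site$soil)
    expect_lte(r_s$yield, r_t$yield + 1e-12)
    expect_lte(max(r_t$daily$eta - r_t$daily$etp), 1e-12)
  }
})

test_that("uniform warming advances anthesis and trims pre-anthesis ETp", {
  site <- water_limited_site()
  d <- climate_delta(rep(2, 12), rep(2, 12), rep(1, 12), rep(1, 12),
                     co2 = 363.8, label = "warm2")
  base <- run_paired_protocol(site$params, site$cultivar, site$soil, 70,
                              n_years = 40, seed = 13)
  warm <- run_paired_protocol(site$params, site$cultivar, site$soil, 70,
                              delta = d, n_years = 40, seed = 13)
  expect_lt(mean(warm$seasons$anthesis_das), mean(base$seasons$anthesis_das))
  expect_lt(mean(warm$seasons$etp_at_flowering),
            mean(base$seasons$etp_at_flowering))
})
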