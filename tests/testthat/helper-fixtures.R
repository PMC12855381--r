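# Shared builders for small deterministic fixtures.

# one season of constant weather starting at sowing
const_weather <- function(n, tmin = 10, tmax = 20, precip = 0, rad = 15,
                          start_doy = 75) {
  doy <- ((start_doy - 1 + seq_len(n) - 1) %% 365) + 1
  data.frame(year = 1L, doy = doy, tmin_c = tmin, tmax_c = tmax,
             precip_mm = precip, rad_mj_m2 = rad)
}

# a mild, wet site where no flowering-window stress ever triggers
benign_site_params <- function() {
  make_site_params(site_fixture_spec(
    "benign", "wet_temperate",
    mean_annual_tmax = 14, seasonal_amplitude = 6,
    tmax_sd_by_month = 2, wet_day_prob_by_month = 0.6,
    mean_wet_amount_by_month = 6, sowing_doy = 75L, seed = 1
  ))
}

# the moderately water-limited continental fixture used for the warming
# directional checks: drought stress present at baseline, flowering-window
# canopy temperatures in the low 30s C
water_limited_site <- function() {
  spec <- site_fixture_spec("contdry", "dry_continental",
                            mean_annual_tmax = 13, seasonal_amplitude = 12,
                            wet_day_prob_by_month = 0.22,
                            sowing_doy = 70L, seed = 1)
  list(spec = spec,
       params = make_site_params(spec),
       soil = soil_params(sawc = 150, initial_smd = 30),
       cultivar = cultivar_params())
}

expect_season_ok <- function(res) {
  expect_s3_class(res, "season_result")
  expect_gt(res$maturity_das, res$anthesis_das)
  expect_true(all(c(res$r_d, res$r_h, res$r_w) >= 0))
  expect_true(all(c(res$r_d, res$r_h, res$r_w) <= 1))
}
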