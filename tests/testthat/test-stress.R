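test_that("the drought response reproduces its hand-computed branches", {
  p <- stress_params(dsgnt = 0.5, dsgns = 0.1, dsgnr_max = 0.2)
  expect_equal(drought_reduction_factor(0.9, p), 1)
  expect_equal(drought_reduction_factor(0.05, p), 0.2)
  # linear segment: S = (1 - 0.2) / (0.5 - 0.1) = 2; 0.2 + 2 * (0.3 - 0.1)
  expect_equal(drought_reduction_factor(0.3, p), 0.6)
  expect_error(drought_reduction_factor(1.2, p), "\\[0, 1\\]")
})

test_that("heat responses are the double-clamped linear forms", {
  p <- stress_params(t_n = 27, s_n = 0.1, t_w = 30, s_w = 0.08)
  expect_equal(heat_grain_number_factor(20, p), 1)
  expect_equal(heat_grain_number_factor(27, p), 1)
  expect_equal(heat_grain_number_factor(32, p), 0.5)
  expect_equal(heat_grain_number_factor(40, p), 0)

  expect_equal(heat_grain_weight_factor(25, p), 1)
  expect_equal(heat_grain_weight_factor(35, p), 1 - 5 * 0.08)
  p0 <- stress_params(t_w = 30, s_w = 0)
  expect_equal(heat_grain_weight_factor(60, p0), 1)
})

test_that("responses are monotone, continuous, and bounded", {
  p <- stress_params(dsgnt = 0.7, dsgns = 0.15, dsgnr_max = 0.3,
                     t_n = 28, s_n = 0.07, t_w = 33, s_w = 0.05)
  dsf_grid <- seq(0, 1, by = 1e-3)
  rd <- drought_reduction_factor(dsf_grid, p)
  expect_true(all(diff(rd) >= 0))
  expect_true(all(rd >= p$dsgnr_max & rd <= 1))
  # continuity at the saturation and threshold knots
  eps <- 1e-9
  expect_equal(drought_reduction_factor(p$dsgns + eps, p),
               drought_reduction_factor(p$dsgns, p), tolerance = 1e-6)
  expect_equal(drought_reduction_factor(p$dsgnt + eps, p),
               drought_reduction_factor(p$dsgnt - eps, p), tolerance = 1e-6)

  t_grid <- seq(10, 60, by = 0.01)
  rh <- heat_grain_number_factor(t_grid, p)
  rw <- heat_grain_weight_factor(t_grid, p)
  expect_true(all(diff(rh) <= 0))
  expect_true(all(diff(rw) <= 0))
  expect_true(all(rh >= 0 & rh <= 1 & rw >= 0 & rw <= 1))
})

test_that("window diagnostics match hand sums and day counts", {
  # inclusive windows: 16, 11, and 8 days
  w <- stress_windows("inclusive")
  expect_length(w$drought, 16)
  expect_length(w$heat_number, 11)
  expect_length(w$heat_weight, 8)
  expect_length(stress_windows("exclusive_anthesis")$drought, 15)

  n <- 80
  ta <- rep(2, n)
  tp <- rep(4, n)
  tcan <- rep(20, n)
  anth <- 40L
  # plant a hot spike in each heat window and a dry spell in the drought one
  tcan[anth - 3] <- 33       # pre-anthesis window [-10, 0]
  tcan[anth + 8] <- 31       # post-anthesis window [+5, +12]
  tcan[anth + 20] <- 45      # outside every window: must be ignored
  ta[(anth - 10):(anth + 5)] <- c(rep(0, 8), rep(2, 8))
  d <- window_diagnostics(ta, tp, tcan, anth, w)
  expect_equal(d$dsf, (8 * 0 + 8 * 2) / (16 * 4))   # hand sums: 16/64
  expect_equal(d$tcan_max_pre, 33)
  expect_equal(d$tcan_max_post, 31)

  # unstressed and fully stressed limits
  expect_equal(window_diagnostics(tp, tp, tcan, anth, w)$dsf, 1)
  expect_equal(window_diagnostics(rep(0, n), tp, tcan, anth, w)$dsf, 0)
  # zero demand means no stress by convention
  expect_equal(window_diagnostics(rep(0, n), rep(0, n), tcan, anth, w)$dsf, 1)

  expect_error(window_diagnostics(ta, tp, tcan, 5L, w), "season edge")
  expect_error(window_diagnostics(ta, tp, tcan, 75L, w), "season edge")
})

test_that("a switched-off mechanism leaves its factor at 1 regardless", {
  w <- const_weather(250, tmin = 24, tmax = 36, precip = 0, rad = 24)
  soil <- soil_params(sawc = 100, initial_smd = 60)
  r_no_heat <- run_season(w, make_cultivar("drought_sensitive_only"), soil)
  expect_identical(r_no_heat$r_h, 1)
  expect_identical(r_no_heat$r_w, 1)
  expect_lt(r_no_heat$r_d, 1)

  r_no_drought <- run_season(w, make_cultivar("heat_sensitive_only"), soil)
  expect_identical(r_no_drought$r_d, 1)
  expect_lt(r_no_drought$r_h, 1)

  # switching off suppresses the yield response, not the shared diagnostics
  expect_equal(r_no_heat$dsf, r_no_drought$dsf)
  expect_equal(r_no_heat$tcan_max_pre, r_no_drought$tcan_max_pre)
})
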