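# Simplified process-based wheat season model.
#
# One season = one weather-year slice starting at sowing.  Thermal-time
# phenology; LAI ramps with thermal time to a maximum at anthesis, then
# senesces linearly to maturity; biomass accumulates as RUE x intercepted
# radiation, scaled by the CO2 response and by the daily water supply
# ratio; Priestley-Taylor potential evapotranspiration is split into
# canopy transpiration and soil evaporation by light interception; actual
# transpiration is limited by root-available water through a critical
# fraction rule; canopy maximum temperature is air tmax plus an empirical
# water- and radiation-dependent elevation.  Grain yield is sink-limited
# through grain number x grain weight with an assimilate cap.
#
# Host-model constants that are not cultivar or soil properties live in
# `crop_model_config()` so they are configuration, not code.

#' Host-model configuration constants
#'
#' @param pt_alpha Priestley-Taylor coefficient (dimensionless).
#' @param psychrometric_kpa_per_c psychrometric constant, kPa per deg C.
#' @param net_radiation_fraction fraction of global radiation that is net
#'   radiation at the surface.
#' @param latent_heat_mj_per_mm latent heat of vaporisation expressed as
#'   MJ m-2 per mm of water.
#' @param f_crit critical fraction of root-accessible capacity below which
#'   transpiration is supply-limited.
#' @param canopy_dmax maximum canopy-minus-air temperature elevation under
#'   a fully stressed, non-transpiring canopy, degrees C.
#' @param canopy_rad_ref radiation at which the canopy elevation reaches
#'   its maximum, MJ m-2 d-1.
#' @return A named list of constants.
#' @export
crop_model_config <- function(pt_alpha = 1.26,
                              psychrometric_kpa_per_c = 0.066,
                              net_radiation_fraction = 0.6,
                              latent_heat_mj_per_mm = 2.45,
                              f_crit = 0.5,
                              canopy_dmax = 5,
                              canopy_rad_ref = 25) {
  list(pt_alpha = pt_alpha,
       psychrometric_kpa_per_c = psychrometric_kpa_per_c,
       net_radiation_fraction = net_radiation_fraction,
       latent_heat_mj_per_mm = latent_heat_mj_per_mm,
       f_crit = f_crit,
       canopy_dmax = canopy_dmax,
       canopy_rad_ref = canopy_rad_ref)
}

#' CO2 multiplier on radiation-use efficiency
#'
#' RUE scales linearly with atmospheric CO2, increasing by 30% for a
#' doubling of the concentration relative to the reference:
#' `1 + 0.30 * (co2 / co2_ref - 1)`.
#'
#' @param co2 atmospheric CO2 concentration, ppm (> 0).
#' @param co2_ref reference concentration, ppm (> 0).
#' @return Dimensionless multiplier on RUE.
#' @export
rue_co2_multiplier <- function(co2, co2_ref = 363.8) {
  if (any(co2 <= 0) || any(co2_ref <= 0)) {
    stop("co2 and co2_ref must be > 0", call. = FALSE)
  }
  1 + 0.30 * (co2 / co2_ref - 1)
}

#' Anthesis date by thermal-time accumulation
#'
#' The smallest day after sowing at which cumulative
#' `max(0, T_mean - base_temp)` reaches the cultivar's sowing-to-anthesis
#' requirement, with `T_mean = (tmax + tmin) / 2`.
#'
#' @param weather one season of daily weather (rows from sowing onwards),
#'   needing columns `tmin_c`, `tmax_c`.
#' @param cultivar a [cultivar_params()] object.
#' @return Integer days after sowing.  Errors with condition class
#'   `season_failure` if the requirement is not met within the series.
#' @export
anthesis_day <- function(weather, cultivar) {
  tmean <- (weather$tmax_c + weather$tmin_c) / 2
  tt <- cumsum(pmax(0, tmean - cultivar$base_temp))
  das <- match(TRUE, tt >= cultivar$tt_sowing_to_anthesis)
  if (is.na(das)) {
    stop(season_failure("thermal-time requirement for anthesis not met"))
  }
  das
}

season_failure <- function(msg) {
  structure(class = c("season_failure", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Daily canopy maximum temperature
#'
#' Empirical surrogate for a canopy energy balance: the canopy warms above
#' air temperature when transpiration is supply-limited, by up to
#' `canopy_dmax` degrees under high radiation:
#' `tcan = tmax_air + canopy_dmax * (1 - supply_ratio) * min(1, rad / canopy_rad_ref)`.
#' A fully transpiring canopy (`supply_ratio = 1`) sits at air temperature.
#'
#' @param tmax_air daily maximum air temperature, deg C.
#' @param supply_ratio actual / potential transpiration in \[0, 1\].
#' @param radiation daily global radiation, MJ m-2 d-1.
#' @param config a [crop_model_config()] list.
#' @return Canopy maximum temperature, deg C; vectorised.
#' @export
canopy_tmax <- function(tmax_air, supply_ratio, radiation,
                        config = crop_model_config()) {
  if (any(supply_ratio < 0 | supply_ratio > 1)) {
    stop("supply_ratio must be in [0, 1]", call. = FALSE)
  }
  tmax_air + config$canopy_dmax * (1 - supply_ratio) *
    pmin(1, pmax(0, radiation) / config$canopy_rad_ref)
}

# Priestley-Taylor potential evapotranspiration (mm/day)
priestley_taylor_etp <- function(tmean, radiation, config) {
  es_slope <- 4098 * 0.6108 * exp(17.27 * tmean / (tmean + 237.3)) /
    (tmean + 237.3)^2
  config$pt_alpha * es_slope / (es_slope + config$psychrometric_kpa_per_c) *
    config$net_radiation_fraction * radiation / config$latent_heat_mj_per_mm
}

#' One day of the soil water balance
#'
#' Rain enters the store first (overflow beyond capacity drains), then
#' Priestley-Taylor potential evapotranspiration is split into canopy
#' transpiration demand (`f_int * ETp`) and soil evaporation demand.
#' Actual transpiration is `Tp * min(1, RAW / (f_crit * cap))` where RAW
#' is root-available water (the root-accessible share of the store) and
#' `cap` the root-accessible capacity; the accessible fraction grows
#' linearly with days after sowing.  Soil evaporation is limited by
#' profile wetness.  Extraction can never exceed the store, so the store
#' stays in `[0, sawc]` and water is conserved exactly:
#' store_in + precip = store_out + ETa + drainage.
#'
#' @param store profile water store at the start of the day, mm.
#' @param das day after sowing (drives root-accessible fraction).
#' @param precip,tmean,radiation the day's rain (mm), mean temperature
#'   (deg C) and global radiation (MJ m-2 d-1).
#' @param f_int fraction of radiation intercepted by the canopy.
#' @param soil a [soil_params()] object.
#' @param config a [crop_model_config()] list.
#' @return List with `store`, `ta`, `tp`, `ea`, `eta`, `etp`, `raw`,
#'   `supply` (actual/potential transpiration ratio) and `drainage`.
#' @export
water_balance_step <- function(store, das, precip, tmean, radiation,
                               f_int, soil, config = crop_model_config()) {
  if (store < -1e-9 || store > soil$sawc + 1e-9) {
    stop("internal invariant violated: store outside [0, sawc]", call. = FALSE)
  }
  root_frac <- min(1, das * soil$max_root_depth_fraction_per_day)
  store <- store + precip
  drainage <- max(0, store - soil$sawc)
  store <- store - drainage
  cap <- root_frac * soil$sawc
  raw <- root_frac * store

  etp <- priestley_taylor_etp(tmean, radiation, config)
  tp <- f_int * etp
  ep <- (1 - f_int) * etp
  supply <- if (tp > 0 && cap > 0) min(1, raw / (config$f_crit * cap)) else 1
  ta <- tp * supply
  ea <- ep * min(1, store / soil$sawc)
  extract <- ta + ea
  if (extract > store) {                 # cannot extract more than stored
    scale <- if (extract > 0) store / extract else 0
    ta <- ta * scale
    ea <- ea * scale
    supply <- if (tp > 0) ta / tp else 1
    extract <- ta + ea
  }
  store <- store - extract
  list(store = store, ta = ta, tp = tp, ea = ea, eta = ta + ea, etp = etp,
       raw = raw, supply = supply, drainage = drainage)
}

#' Simulate one wheat season
#'
#' Integrates phenology, leaf area, light interception, biomass, the soil
#' water balance and canopy temperature day by day from sowing, then
#' applies the flowering-window stress mechanisms (per the cultivar's
#' switches) to grain number and grain weight.
#'
#' Grain set: ear mass at anthesis is `ear_mass_fraction` of anthesis
#' biomass; grain number is `n_pot * ear_mass * R_D * R_H`.  Grain weight
#' is `w_pot * R_W`, capped by the assimilate available for grain fill
#' (post-anthesis growth plus a retranslocatable share of anthesis
#' biomass) divided by grain number, so grain-number losses are only
#' partially compensated.  Yield is `grain_number * grain_weight` in
#' t ha-1.
#'
#' @param weather one season of daily weather (row 1 = sowing day),
#'   columns `doy`, `tmin_c`, `tmax_c`, `precip_mm`, `rad_mj_m2`.
#' @param cultivar a [cultivar_params()] object.
#' @param soil a [soil_params()] object.
#' @param co2 atmospheric CO2, ppm.
#' @param co2_ref reference CO2 for the RUE response, ppm.
#' @param windows a [stress_windows()] object.
#' @param config a [crop_model_config()] list.
#' @return A list of class `season_result` with elements `anthesis_das`,
#'   `maturity_das`, `yield` (t ha-1), `grain_number` (grains m-2),
#'   `grain_weight` (g), `biomass` (g m-2, at maturity),
#'   `biomass_anthesis`, `eta_at_flowering`, `etp_at_flowering`,
#'   `raw_at_flowering` (mm), `dsf`, `r_d`, `r_h`, `r_w`,
#'   `tcan_max_pre`, `tcan_max_post`, and a `daily` data frame
#'   (das, ta, tp, eta, etp, tcan, store, drainage).
#' @export
run_season <- function(weather, cultivar, soil, co2 = 363.8,
                       co2_ref = 363.8, windows = stress_windows(),
                       config = crop_model_config()) {
  stopifnot(inherits(cultivar, "cultivar_params"), inherits(soil, "soil_params"))
  n <- nrow(weather)
  tmean <- (weather$tmax_c + weather$tmin_c) / 2
  tt <- cumsum(pmax(0, tmean - cultivar$base_temp))
  tt_anth <- cultivar$tt_sowing_to_anthesis
  tt_mat <- tt_anth + cultivar$tt_anthesis_to_maturity

  anthesis_das <- match(TRUE, tt >= tt_anth)
  maturity_das <- match(TRUE, tt >= tt_mat)
  if (is.na(anthesis_das) || is.na(maturity_das)) {
    stop(season_failure(
      "thermal-time requirement not met within the season's weather"))
  }

  # green-area and interception profile (thermal-time driven, so identical
  # across cultivar profiles differing only in stress switches)
  lai <- ifelse(tt < tt_anth,
                cultivar$max_lai * tt / tt_anth,
                cultivar$max_lai * pmax(0, 1 - (tt - tt_anth) /
                                          cultivar$tt_anthesis_to_maturity))
  f_int <- 1 - exp(-cultivar$k_light * lai)

  etp_all <- priestley_taylor_etp(tmean, weather$rad_mj_m2, config)
  co2_mult <- rue_co2_multiplier(co2, co2_ref)

  store <- soil$sawc - soil$initial_smd
  ta_d <- tp_d <- eta_d <- tcan_d <- store_d <- drain_d <- numeric(n)
  supply_d <- numeric(n)
  biomass <- 0
  biomass_anth <- NA_real_
  eta_cum <- 0
  etp_cum <- 0
  eta_flower <- etp_flower <- raw_flower <- NA_real_

  last <- maturity_das
  for (i in seq_len(last)) {
    wb <- water_balance_step(store, i, weather$precip_mm[i], tmean[i],
                             weather$rad_mj_m2[i], f_int[i], soil, config)
    store <- wb$store

    tcan <- canopy_tmax(weather$tmax_c[i], wb$supply, weather$rad_mj_m2[i],
                        config)
    biomass <- biomass + cultivar$rue_ref * co2_mult * f_int[i] *
      weather$rad_mj_m2[i] * wb$supply

    eta_cum <- eta_cum + wb$eta
    etp_cum <- etp_cum + wb$etp
    ta_d[i] <- wb$ta; tp_d[i] <- wb$tp; eta_d[i] <- wb$eta
    tcan_d[i] <- tcan; store_d[i] <- store; drain_d[i] <- wb$drainage
    supply_d[i] <- wb$supply

    if (i == anthesis_das) {
      biomass_anth <- biomass
      eta_flower <- eta_cum
      etp_flower <- etp_cum
      raw_flower <- min(1, i * soil$max_root_depth_fraction_per_day) * store
    }
  }

  diag <- window_diagnostics(ta_d, tp_d, tcan_d, anthesis_das, windows)
  sp <- cultivar$stress
  r_d <- if (cultivar$drought_mech_on) {
    drought_reduction_factor(min(1, max(0, diag$dsf)), sp)
  } else 1
  r_h <- if (cultivar$heat_mech_on) {
    heat_grain_number_factor(diag$tcan_max_pre, sp)
  } else 1
  r_w <- if (cultivar$heat_mech_on) {
    heat_grain_weight_factor(diag$tcan_max_post, sp)
  } else 1

  ear_mass <- cultivar$ear_mass_fraction * biomass_anth
  grain_number <- cultivar$n_pot * ear_mass * r_d * r_h
  assimilate <- (biomass - biomass_anth) +
    cultivar$retrans_fraction * biomass_anth
  grain_weight <- if (grain_number > 0) {
    min(cultivar$w_pot * r_w, assimilate / grain_number)
  } else 0
  yield <- grain_number * grain_weight * 0.01   # g m-2 -> t ha-1

  structure(list(
    anthesis_das = anthesis_das,
    maturity_das = maturity_das,
    yield = yield,
    grain_number = grain_number,
    grain_weight = grain_weight,
    biomass = biomass,
    biomass_anthesis = biomass_anth,
    eta_at_flowering = eta_flower,
    etp_at_flowering = etp_flower,
    raw_at_flowering = raw_flower,
    dsf = min(1, max(0, diag$dsf)),
    r_d = r_d, r_h = r_h, r_w = r_w,
    tcan_max_pre = diag$tcan_max_pre,
    tcan_max_post = diag$tcan_max_post,
    daily = data.frame(das = seq_len(last), ta = ta_d[seq_len(last)],
                       tp = tp_d[seq_len(last)], eta = eta_d[seq_len(last)],
                       etp = etp_all[seq_len(last)],
                       tcan = tcan_d[seq_len(last)],
                       supply = supply_d[seq_len(last)],
                       store = store_d[seq_len(last)],
                       drainage = drain_d[seq_len(last)])
  ), class = "season_result")
}

#' Slice one season of weather starting at a sowing date
#'
#' Season `i` starts on `sowing_doy` of series-year `i` and may run into
#' year `i + 1`; a series of `n + 1` years therefore supports `n` seasons.
#'
#' @param series multi-year daily series from [generate_series()].
#' @param season_index season number (1-based).
#' @param sowing_doy sowing day of year.
#' @return Data frame of up to 365 daily rows, row 1 = sowing day.
#' @export
season_slice <- function(series, season_index, sowing_doy) {
  start <- (season_index - 1L) * DAYS_PER_YEAR + as.integer(sowing_doy)
  stop_at <- min(start + DAYS_PER_YEAR - 1L, nrow(series))
  if (start > nrow(series)) {
    stop("season_index is beyond the end of the series", call. = FALSE)
  }
  series[start:stop_at, , drop = FALSE]
}

#' Run one season per weather-year over a multi-year series
#'
#' @inheritParams season_slice
#' @inheritParams run_season
#' @param n_seasons number of seasons; the series must hold one extra year
#'   so late seasons can run across the year boundary.
#' @return List with `results` (per-season `season_result` or a
#'   `season_failure` condition) and `failed` (logical vector).
#' @export
run_seasons <- function(series, n_seasons, sowing_doy, cultivar, soil,
                        co2 = 363.8, co2_ref = 363.8,
                        windows = stress_windows(),
                        config = crop_model_config()) {
  results <- vector("list", n_seasons)
  failed <- logical(n_seasons)
  for (i in seq_len(n_seasons)) {
    w <- season_slice(series, i, sowing_doy)
    results[[i]] <- tryCatch(
      run_season(w, cultivar, soil, co2 = co2, co2_ref = co2_ref,
                 windows = windows, config = config),
      season_failure = function(e) e,
      error = function(e) {
        if (grepl("season edge", conditionMessage(e))) {
          season_failure(conditionMessage(e))
        } else {
          stop(e)
        }
      }
    )
    failed[i] <- inherits(results[[i]], "season_failure")
  }
  list(results = results, failed = failed)
}
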