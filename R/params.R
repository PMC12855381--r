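#' @keywords internal
"_PACKAGE"

# month lengths of the fixed 365-day model year (no leap days)
MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_STARTS <- cumsum(c(0L, MONTH_LENGTHS[-12])) + 1L
DAYS_PER_YEAR <- 365L

#' Month index for a day-of-year in the 365-day model calendar
#'
#' @param doy integer day of year in 1..365.
#' @return integer month in 1..12.
#' @export
month_of_doy <- function(doy) {
  if (any(doy < 1L | doy > DAYS_PER_YEAR)) {
    stop("doy must be in 1..365", call. = FALSE)
  }
  findInterval(doy, MONTH_STARTS)
}

check_monthly <- function(x, name, allow_na = FALSE) {
  if (length(x) != 12L) {
    stop(sprintf("'%s' must have 12 monthly values, got %d", name, length(x)),
         call. = FALSE)
  }
  if (!allow_na && anyNA(x)) stop(sprintf("'%s' contains NA", name), call. = FALSE)
  as.numeric(x)
}

#' Site climate parameters for the stochastic weather generator
#'
#' Bundles the per-month statistics that drive [generate_series()]:
#' Gaussian temperature means and standard deviations, a first-order
#' wet/dry occurrence chain, gamma-distributed wet-day amounts, and
#' lognormal daily radiation around a monthly mean.
#'
#' @param monthly_mean_tmax,monthly_mean_tmin monthly mean daily maximum and
#'   minimum air temperature, degrees C (12 values each).
#' @param monthly_sd_tmax,monthly_sd_tmin monthly standard deviation of daily
#'   maximum / minimum temperature, degrees C (12 values each).
#' @param temp_autocorr lag-1 autocorrelation of the daily temperature
#'   anomaly, in (-1, 1).
#' @param p_wet_given_dry,p_wet_given_wet monthly probabilities that a day is
#'   wet given the previous day was dry / wet (12 values each).
#' @param wet_amount_shape gamma shape of wet-day precipitation per month
#'   (12 values, > 0; NA allowed for all-dry months).
#' @param wet_amount_mean mean wet-day precipitation per month, mm
#'   (12 values, >= 0).
#' @param monthly_mean_radiation monthly mean daily global radiation,
#'   MJ m-2 d-1 (12 values).
#' @param radiation_cv coefficient of variation of daily radiation around its
#'   monthly mean (dimensionless, >= 0).
#' @param latitude site latitude, degrees (negative = southern hemisphere).
#' @param site_id optional short identifier.
#' @return An object of class `site_climate_params` (a named list).
#' @seealso [generate_series()], [apply_delta()], [estimate_params()]
#' @export
site_climate_params <- function(monthly_mean_tmax, monthly_mean_tmin,
                                monthly_sd_tmax, monthly_sd_tmin,
                                temp_autocorr,
                                p_wet_given_dry, p_wet_given_wet,
                                wet_amount_shape, wet_amount_mean,
                                monthly_mean_radiation, radiation_cv,
                                latitude, site_id = "site") {
  p <- list(
    site_id = as.character(site_id),
    monthly_mean_tmax = check_monthly(monthly_mean_tmax, "monthly_mean_tmax"),
    monthly_mean_tmin = check_monthly(monthly_mean_tmin, "monthly_mean_tmin"),
    monthly_sd_tmax = check_monthly(monthly_sd_tmax, "monthly_sd_tmax"),
    monthly_sd_tmin = check_monthly(monthly_sd_tmin, "monthly_sd_tmin"),
    temp_autocorr = as.numeric(temp_autocorr),
    p_wet_given_dry = check_monthly(p_wet_given_dry, "p_wet_given_dry"),
    p_wet_given_wet = check_monthly(p_wet_given_wet, "p_wet_given_wet"),
    wet_amount_shape = check_monthly(wet_amount_shape, "wet_amount_shape",
                                     allow_na = TRUE),
    wet_amount_mean = check_monthly(wet_amount_mean, "wet_amount_mean"),
    monthly_mean_radiation = check_monthly(monthly_mean_radiation,
                                           "monthly_mean_radiation"),
    radiation_cv = as.numeric(radiation_cv),
    latitude = as.numeric(latitude)
  )
  validate_site_climate_params(p)
  structure(p, class = "site_climate_params")
}

validate_site_climate_params <- function(p) {
  if (any(p$monthly_mean_tmax < p$monthly_mean_tmin)) {
    stop("monthly mean tmax must be >= monthly mean tmin in every month",
         call. = FALSE)
  }
  if (any(p$monthly_sd_tmax < 0) || any(p$monthly_sd_tmin < 0)) {
    stop("temperature standard deviations must be >= 0", call. = FALSE)
  }
  if (abs(p$temp_autocorr) >= 1) {
    stop("temp_autocorr must be in (-1, 1)", call. = FALSE)
  }
  probs <- c(p$p_wet_given_dry, p$p_wet_given_wet)
  if (any(probs < 0 | probs > 1)) {
    stop("wet/dry transition probabilities must be in [0, 1]", call. = FALSE)
  }
  shp <- p$wet_amount_shape
  if (any(!is.na(shp) & shp <= 0)) {
    stop("wet_amount_shape must be > 0 where defined", call. = FALSE)
  }
  if (any(p$wet_amount_mean < 0)) {
    stop("wet_amount_mean must be >= 0", call. = FALSE)
  }
  if (any(p$monthly_mean_radiation < 0) || p$radiation_cv < 0) {
    stop("radiation parameters must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' One delta-change climate scenario (a single GCM x period)
#'
#' Additive monthly offsets for temperature and multiplicative monthly
#' factors for precipitation and radiation, plus the scenario CO2
#' concentration.  Applied to baseline site parameters by [apply_delta()].
#'
#' @param d_tmax,d_tmin additive monthly changes in mean daily maximum /
#'   minimum temperature, degrees C (12 values each).
#' @param precip_factor,radiation_factor multiplicative monthly changes in
#'   mean precipitation / radiation (12 values each, >= 0).
#' @param co2 scenario atmospheric CO2 concentration, ppm (> 0).
#' @param label scenario identifier, conventionally "gcm x period".
#' @param scenario scenario period grouping (e.g. "2050"); defaults to
#'   `label`.  Used when aggregating over a GCM ensemble.
#' @param gcm GCM identifier within the ensemble; defaults to `label`.
#' @return An object of class `climate_delta`.
#' @export
climate_delta <- function(d_tmax, d_tmin, precip_factor, radiation_factor,
                          co2, label = "delta", scenario = label, gcm = label) {
  d <- list(
    label = as.character(label),
    scenario = as.character(scenario),
    gcm = as.character(gcm),
    d_tmax = check_monthly(d_tmax, "d_tmax"),
    d_tmin = check_monthly(d_tmin, "d_tmin"),
    precip_factor = check_monthly(precip_factor, "precip_factor"),
    radiation_factor = check_monthly(radiation_factor, "radiation_factor"),
    co2 = as.numeric(co2)
  )
  if (any(d$precip_factor < 0) || any(d$radiation_factor < 0)) {
    stop("precipitation and radiation factors must be >= 0", call. = FALSE)
  }
  if (d$co2 <= 0) stop("co2 must be > 0", call. = FALSE)
  structure(d, class = "climate_delta")
}

#' Soil parameters
#'
#' @param sawc soil available water capacity over the full profile, mm (> 0).
#' @param initial_smd soil moisture deficit at sowing, mm
#'   (0 <= initial_smd <= sawc); the profile starts at `sawc - initial_smd`.
#' @param max_root_depth_fraction_per_day daily linear growth of the
#'   root-accessible fraction of the profile (dimensionless per day); the
#'   accessible fraction is `min(1, das * rate)`.
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(sawc = 150, initial_smd = 0,
                        max_root_depth_fraction_per_day = 0.015) {
  if (sawc <= 0) stop("sawc must be > 0", call. = FALSE)
  if (initial_smd < 0 || initial_smd > sawc) {
    stop("initial_smd must satisfy 0 <= initial_smd <= sawc", call. = FALSE)
  }
  if (max_root_depth_fraction_per_day <= 0) {
    stop("max_root_depth_fraction_per_day must be > 0", call. = FALSE)
  }
  structure(list(sawc = as.numeric(sawc),
                 initial_smd = as.numeric(initial_smd),
                 max_root_depth_fraction_per_day =
                   as.numeric(max_root_depth_fraction_per_day)),
            class = "soil_params")
}

#' Flowering-window stress response parameters
#'
#' Parameters of the piecewise drought response on grain set and the
#' clamped linear heat responses on grain set and grain weight.  The slope
#' of the drought response, `S = (1 - dsgnr_max) / (dsgnt - dsgns)`, is
#' derived, never stored.
#'
#' The shipped defaults are documented, non-calibrated placeholders of
#' realistic magnitude; site- or cultivar-specific use requires calibration
#' against field or controlled-environment data.
#'
#' @param dsgnt drought stress grain number reduction threshold on the
#'   drought stress factor scale (dimensionless; no reduction above it).
#' @param dsgns drought stress grain number reduction saturation
#'   (dimensionless; full reduction at or below it); `0 <= dsgns < dsgnt <= 1`.
#' @param dsgnr_max maximum drought stress grain number reduction, the floor
#'   of the reduction factor (dimensionless in \[0, 1\]).
#' @param t_n canopy temperature threshold for grain-number loss, degrees C.
#' @param s_n slope of grain-number reduction per degree of canopy
#'   temperature above `t_n` (per degree C, >= 0).
#' @param t_w canopy temperature threshold for grain-weight loss, degrees C.
#' @param s_w slope of potential grain-weight reduction per degree above
#'   `t_w` (per degree C, >= 0).
#' @return An object of class `stress_params`.
#' @seealso [drought_reduction_factor()], [heat_grain_number_factor()],
#'   [heat_grain_weight_factor()]
#' @export
stress_params <- function(dsgnt = 0.6, dsgns = 0.2, dsgnr_max = 0.25,
                          t_n = 30, s_n = 0.08, t_w = 35, s_w = 0.06) {
  if (!(dsgns >= 0 && dsgns < dsgnt && dsgnt <= 1)) {
    stop("require 0 <= dsgns < dsgnt <= 1", call. = FALSE)
  }
  if (dsgnr_max < 0 || dsgnr_max > 1) {
    stop("dsgnr_max must be in [0, 1]", call. = FALSE)
  }
  if (s_n < 0 || s_w < 0) stop("slopes must be >= 0", call. = FALSE)
  structure(list(dsgnt = as.numeric(dsgnt), dsgns = as.numeric(dsgns),
                 dsgnr_max = as.numeric(dsgnr_max),
                 t_n = as.numeric(t_n), s_n = as.numeric(s_n),
                 t_w = as.numeric(t_w), s_w = as.numeric(s_w)),
            class = "stress_params")
}

#' Cultivar parameters
#'
#' Phenology, growth, and sink parameters of the simplified wheat season
#' model, plus the stress-response block and the two mechanism switches
#' that define sensitive vs tolerant profiles.
#'
#' @param tt_sowing_to_anthesis thermal time from sowing to anthesis,
#'   degree C days (> 0).
#' @param tt_anthesis_to_maturity thermal time from anthesis to maturity,
#'   degree C days (> 0).
#' @param base_temp base temperature for thermal-time accumulation, deg C.
#' @param rue_ref radiation-use efficiency at the reference CO2
#'   concentration, g biomass per MJ intercepted global radiation.
#' @param k_light canopy light extinction coefficient (dimensionless).
#' @param max_lai maximum leaf area index (dimensionless).
#' @param n_pot potential primary grain setting number per unit ear dry
#'   mass, grains per g (> 0).
#' @param ear_mass_fraction fraction of anthesis biomass in ears
#'   (0 < x < 1).
#' @param w_pot potential weight of a single grain, g per grain (> 0).
#' @param retrans_fraction fraction of anthesis biomass retranslocatable to
#'   grain during grain fill (dimensionless in \[0, 1\]).
#' @param stress a [stress_params()] block.
#' @param drought_mech_on,heat_mech_on logical switches for the
#'   flowering-window drought / heat mechanisms; a cultivar with both off
#'   is the tolerant profile.
#' @return An object of class `cultivar_params`.
#' @export
cultivar_params <- function(tt_sowing_to_anthesis = 1100,
                            tt_anthesis_to_maturity = 750,
                            base_temp = 0,
                            rue_ref = 1.1,
                            k_light = 0.6,
                            max_lai = 6,
                            n_pot = 100,
                            ear_mass_fraction = 0.3,
                            w_pot = 0.045,
                            retrans_fraction = 0.25,
                            stress = stress_params(),
                            drought_mech_on = TRUE,
                            heat_mech_on = TRUE) {
  if (tt_sowing_to_anthesis <= 0 || tt_anthesis_to_maturity <= 0) {
    stop("thermal-time requirements must be > 0", call. = FALSE)
  }
  if (ear_mass_fraction <= 0 || ear_mass_fraction >= 1) {
    stop("ear_mass_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_pot <= 0 || w_pot <= 0) stop("n_pot and w_pot must be > 0", call. = FALSE)
  if (retrans_fraction < 0 || retrans_fraction > 1) {
    stop("retrans_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!inherits(stress, "stress_params")) {
    stop("stress must be a stress_params object", call. = FALSE)
  }
  structure(list(tt_sowing_to_anthesis = as.numeric(tt_sowing_to_anthesis),
                 tt_anthesis_to_maturity = as.numeric(tt_anthesis_to_maturity),
                 base_temp = as.numeric(base_temp),
                 rue_ref = as.numeric(rue_ref),
                 k_light = as.numeric(k_light),
                 max_lai = as.numeric(max_lai),
                 n_pot = as.numeric(n_pot),
                 ear_mass_fraction = as.numeric(ear_mass_fraction),
                 w_pot = as.numeric(w_pot),
                 retrans_fraction = as.numeric(retrans_fraction),
                 stress = stress,
                 drought_mech_on = isTRUE(drought_mech_on),
                 heat_mech_on = isTRUE(heat_mech_on)),
            class = "cultivar_params")
}

#' Stress windows around anthesis
#'
#' Day-offset intervals, inclusive of both endpoints, anchored on the
#' anthesis date (offset 0).  The drought window spans 10 days before to
#' 5 days after anthesis; the heat window for grain number spans 10 days
#' before anthesis to anthesis (meiosis and fertilisation); the heat window
#' for grain weight spans 5 to 12 days after anthesis (early endosperm
#' development).
#'
#' Under the default `"inclusive"` convention the drought window counts 16
#' calendar days.  The `"exclusive_anthesis"` convention drops the anthesis
#' day itself, giving the 15-day count sometimes quoted for a window
#' running from 10 days before to 5 days after flowering.
#'
#' @param window_convention `"inclusive"` (default) or
#'   `"exclusive_anthesis"`.
#' @return An object of class `stress_windows` with integer offset vectors
#'   `drought`, `heat_number`, `heat_weight`.
#' @export
stress_windows <- function(window_convention = c("inclusive",
                                                 "exclusive_anthesis")) {
  window_convention <- match.arg(window_convention)
  drought <- if (window_convention == "inclusive") {
    -10L:5L
  } else {
    setdiff(-10L:5L, 0L)
  }
  structure(list(drought = drought,
                 heat_number = -10L:0L,
                 heat_weight = 5L:12L,
                 convention = window_convention),
            class = "stress_windows")
}
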