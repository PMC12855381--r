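# Synthetic fixtures: contrasting site climates, soils, cultivars and
# GCM-like delta ensembles.  Everything here is a pure function of its
# arguments (plus an explicit seed), so fixtures are reproducible and the
# whole pipeline is testable without external data.

ARCHETYPES <- c("cool_variable", "hot_narrow", "wet_temperate",
                "dry_continental")

archetype_defaults <- function(archetype) {
  switch(archetype,
    cool_variable = list(mean_annual_tmax = 12, seasonal_amplitude = 10,
                         tmax_sd = 6, wet_day_prob = 0.35, mean_wet_amount = 5,
                         radiation_annual_mean = 14, latitude = 52,
                         sowing_doy = 75L),
    hot_narrow = list(mean_annual_tmax = 26, seasonal_amplitude = 6,
                      tmax_sd = 2, wet_day_prob = 0.25, mean_wet_amount = 6,
                      radiation_annual_mean = 20, latitude = 28,
                      sowing_doy = 320L),
    wet_temperate = list(mean_annual_tmax = 15, seasonal_amplitude = 8,
                         tmax_sd = 4, wet_day_prob = 0.50, mean_wet_amount = 6,
                         radiation_annual_mean = 13, latitude = 50,
                         sowing_doy = 285L),
    dry_continental = list(mean_annual_tmax = 15, seasonal_amplitude = 13,
                           tmax_sd = 5, wet_day_prob = 0.12, mean_wet_amount = 4,
                           radiation_annual_mean = 17, latitude = 48,
                           sowing_doy = 75L),
    stop(sprintf("unknown climate archetype '%s'", archetype), call. = FALSE)
  )
}

#' Specification of a synthetic site fixture
#'
#' Describes a synthetic site in terms of a small number of climate
#' descriptors; [make_site_params()] expands it into the full
#' [site_climate_params()] block.  The four archetypes span the contrasts
#' that matter for flowering-window stress: a cool climate with wide
#' temperature variability vs a hot climate with a narrow distribution,
#' and wet vs dry growing seasons.  Omitted descriptors are filled from
#' the archetype.
#'
#' @param site_id short identifier.
#' @param climate_archetype one of `"cool_variable"`, `"hot_narrow"`,
#'   `"wet_temperate"`, `"dry_continental"`.
#' @param latitude degrees; sign selects the hemisphere phase of the
#'   seasonal cycle (warmest month July if >= 0, January otherwise).
#' @param seasonal_amplitude half-range of the monthly mean tmax sinusoid,
#'   degrees C.
#' @param mean_annual_tmax annual mean of daily maximum temperature, deg C.
#' @param tmax_sd_by_month within-month sd of daily tmax, deg C; scalar or
#'   12 values.
#' @param wet_day_prob_by_month unconditional wet-day probability; scalar
#'   or 12 values in \[0, 1\].
#' @param mean_wet_amount_by_month mean wet-day precipitation, mm; scalar
#'   or 12 values (> 0).
#' @param radiation_annual_mean annual mean daily radiation, MJ m-2 d-1.
#' @param diurnal_range monthly mean tmax minus tmin, deg C.
#' @param temp_autocorr lag-1 daily temperature autocorrelation (free
#'   parameter of the generator; default 0.6).
#' @param occurrence_persistence lag-1 persistence of the wet/dry chain in
#'   \[0, 1); converts the unconditional wet-day probability into the two
#'   conditional transition probabilities.
#' @param sowing_doy sowing day of year; default per archetype (autumn
#'   sowing for the temperate archetypes, spring for the continental ones).
#' @param seed integer seed associated with the fixture.
#' @return An object of class `site_fixture_spec`.
#' @export
site_fixture_spec <- function(site_id,
                              climate_archetype,
                              latitude = NULL,
                              seasonal_amplitude = NULL,
                              mean_annual_tmax = NULL,
                              tmax_sd_by_month = NULL,
                              wet_day_prob_by_month = NULL,
                              mean_wet_amount_by_month = NULL,
                              radiation_annual_mean = NULL,
                              diurnal_range = 10,
                              temp_autocorr = 0.6,
                              occurrence_persistence = 0.3,
                              sowing_doy = NULL,
                              seed = 1L) {
  if (!climate_archetype %in% ARCHETYPES) {
    stop(sprintf("unknown climate archetype '%s'", climate_archetype),
         call. = FALSE)
  }
  def <- archetype_defaults(climate_archetype)
  pick <- function(x, d) if (is.null(x)) d else x
  rep12 <- function(x) if (length(x) == 1L) rep(as.numeric(x), 12L) else
    check_monthly(x, "monthly vector")

  spec <- list(
    site_id = as.character(site_id),
    climate_archetype = climate_archetype,
    latitude = as.numeric(pick(latitude, def$latitude)),
    seasonal_amplitude = as.numeric(pick(seasonal_amplitude,
                                         def$seasonal_amplitude)),
    mean_annual_tmax = as.numeric(pick(mean_annual_tmax, def$mean_annual_tmax)),
    tmax_sd_by_month = rep12(pick(tmax_sd_by_month, def$tmax_sd)),
    wet_day_prob_by_month = rep12(pick(wet_day_prob_by_month,
                                       def$wet_day_prob)),
    mean_wet_amount_by_month = rep12(pick(mean_wet_amount_by_month,
                                          def$mean_wet_amount)),
    radiation_annual_mean = as.numeric(pick(radiation_annual_mean,
                                            def$radiation_annual_mean)),
    diurnal_range = as.numeric(diurnal_range),
    temp_autocorr = as.numeric(temp_autocorr),
    occurrence_persistence = as.numeric(occurrence_persistence),
    sowing_doy = as.integer(pick(sowing_doy, def$sowing_doy)),
    seed = as.integer(seed)
  )
  if (any(spec$wet_day_prob_by_month < 0 | spec$wet_day_prob_by_month > 1)) {
    stop("wet-day probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(spec$tmax_sd_by_month < 0)) stop("tmax sd must be >= 0", call. = FALSE)
  if (any(spec$mean_wet_amount_by_month <= 0)) {
    stop("mean wet amounts must be > 0", call. = FALSE)
  }
  if (spec$occurrence_persistence < 0 || spec$occurrence_persistence >= 1) {
    stop("occurrence_persistence must be in [0, 1)", call. = FALSE)
  }
  structure(spec, class = "site_fixture_spec")
}

#' Expand a site fixture spec into full weather-generator parameters
#'
#' Monthly mean tmax follows a sinusoid of the stated amplitude around the
#' annual mean, with the warmest month set by hemisphere (July for
#' latitude >= 0, January otherwise); tmin sits a fixed diurnal range
#' below tmax.  Monthly radiation follows the same phase with a relative
#' amplitude of 0.45.  The unconditional wet-day probability and the
#' occurrence persistence are converted into the conditional transition
#' probabilities of the two-state chain so that the chain's stationary
#' wet-day frequency equals the stated probability.
#'
#' Deterministic: the same spec always yields the same parameters.
#'
#' @param spec a [site_fixture_spec()].
#' @return A [site_climate_params()] object.
#' @export
make_site_params <- function(spec) {
  if (!inherits(spec, "site_fixture_spec")) {
    stop("spec must be a site_fixture_spec", call. = FALSE)
  }
  m <- 1:12
  peak <- if (spec$latitude >= 0) 7 else 1
  phase <- cos(2 * pi * (m - peak) / 12)
  tmax <- spec$mean_annual_tmax + spec$seasonal_amplitude * phase
  tmin <- tmax - spec$diurnal_range
  rad <- spec$radiation_annual_mean * (1 + 0.45 * phase)

  pi_wet <- spec$wet_day_prob_by_month
  r <- spec$occurrence_persistence
  p_wd <- pi_wet * (1 - r)
  p_ww <- pi_wet * (1 - r) + r

  site_climate_params(
    monthly_mean_tmax = tmax,
    monthly_mean_tmin = tmin,
    monthly_sd_tmax = spec$tmax_sd_by_month,
    monthly_sd_tmin = spec$tmax_sd_by_month,
    temp_autocorr = spec$temp_autocorr,
    p_wet_given_dry = p_wd,
    p_wet_given_wet = p_ww,
    wet_amount_shape = rep(0.8, 12),
    wet_amount_mean = spec$mean_wet_amount_by_month,
    monthly_mean_radiation = rad,
    radiation_cv = 0.25,
    latitude = spec$latitude,
    site_id = spec$site_id
  )
}

#' Generate a GCM-like ensemble of delta-change scenarios
#'
#' Each ensemble member draws a GCM-level warming from
#' `Normal(warming_mean, warming_spread)`, adds small monthly jitter
#' (sd `warming_spread / 4`) independently to the tmax and tmin offsets,
#' draws monthly precipitation factors uniformly in `precip_factor_range`
#' and monthly radiation factors uniformly in \[0.98, 1.02\].  All members
#' share the scenario CO2.  Reproducible under `seed`.
#'
#' @param n_gcms number of ensemble members (>= 1).
#' @param warming_mean ensemble-mean warming, degrees C.
#' @param warming_spread between-GCM sd of warming, degrees C (>= 0).
#' @param precip_factor_range length-2 numeric, bounds of the monthly
#'   precipitation factor (both > 0).
#' @param co2 scenario CO2, ppm.
#' @param seed integer seed.
#' @param scenario scenario period label shared by the ensemble.
#' @return A list of [climate_delta()] objects labelled
#'   `"<scenario>@gcm01"`, `"<scenario>@gcm02"`, ...
#' @export
make_delta_ensemble <- function(n_gcms, warming_mean, warming_spread,
                                precip_factor_range, co2, seed,
                                scenario = "future") {
  if (n_gcms < 1) stop("n_gcms must be >= 1", call. = FALSE)
  if (warming_spread < 0) stop("warming_spread must be >= 0", call. = FALSE)
  if (length(precip_factor_range) != 2L || any(precip_factor_range <= 0)) {
    stop("precip_factor_range must be two positive numbers", call. = FALSE)
  }
  lo <- min(precip_factor_range)
  hi <- max(precip_factor_range)
  set.seed(as.integer(seed))
  lapply(seq_len(n_gcms), function(i) {
    base <- rnorm(1, warming_mean, warming_spread)
    jitter_sd <- warming_spread / 4
    gcm <- sprintf("gcm%02d", i)
    climate_delta(
      d_tmax = base + rnorm(12, 0, jitter_sd),
      d_tmin = base + rnorm(12, 0, jitter_sd),
      precip_factor = runif(12, lo, hi),
      radiation_factor = runif(12, 0.98, 1.02),
      co2 = co2,
      label = paste0(scenario, "@", gcm),
      scenario = scenario,
      gcm = gcm
    )
  })
}

#' Derive a cultivar profile by setting the stress mechanism switches
#'
#' Returns a copy of `base` whose drought / heat mechanism switches are
#' set according to the profile; no other field is altered.  The tolerant
#' profile (both mechanisms off) is the reference cultivar of the paired
#' simulation protocol, whose yield is unaffected by flowering-window
#' extremes.
#'
#' @param profile one of `"sensitive_both"`, `"drought_sensitive_only"`,
#'   `"heat_sensitive_only"`, `"tolerant"`.
#' @param base a [cultivar_params()] object.
#' @return A `cultivar_params` object.
#' @export
make_cultivar <- function(profile = c("sensitive_both",
                                      "drought_sensitive_only",
                                      "heat_sensitive_only",
                                      "tolerant"),
                          base = cultivar_params()) {
  profile <- match.arg(profile)
  if (!inherits(base, "cultivar_params")) {
    stop("base must be a cultivar_params object", call. = FALSE)
  }
  out <- base
  switches <- switch(profile,
    sensitive_both = c(TRUE, TRUE),
    drought_sensitive_only = c(TRUE, FALSE),
    heat_sensitive_only = c(FALSE, TRUE),
    tolerant = c(FALSE, FALSE)
  )
  out$drought_mech_on <- switches[1]
  out$heat_mech_on <- switches[2]
  out
}
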