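# Paired tolerant/sensitive simulation protocol and the drought / heat
# stress indices with their 95th-percentile (one-in-twenty-year)
# summaries.

#' Drought stress index for one year
#'
#' `DSI = 1 - y_d / y`, comparing the yield of a cultivar sensitive only
#' to flowering-window drought (`y_d`) with the yield of the tolerant
#' reference cultivar (`y`) on identical weather.
#'
#' @param y_d drought-sensitive yield, t ha-1.
#' @param y tolerant reference yield, t ha-1 (> 0).
#' @return Dimensionless index; vectorised.
#' @export
dsi <- function(y_d, y) {
  if (any(y <= 0)) {
    stop("tolerant reference yield must be > 0; exclude zero-yield years",
         call. = FALSE)
  }
  1 - y_d / y
}

#' Heat stress index for one year
#'
#' `HSI = 1 - y_h / y`, with `y_h` the yield of a cultivar sensitive only
#' to flowering-window heat.
#'
#' @param y_h heat-sensitive yield, t ha-1.
#' @param y tolerant reference yield, t ha-1 (> 0).
#' @return Dimensionless index; vectorised.
#' @export
hsi <- function(y_h, y) {
  if (any(y <= 0)) {
    stop("tolerant reference yield must be > 0; exclude zero-yield years",
         call. = FALSE)
  }
  1 - y_h / y
}

#' Empirical 95th percentile (linear interpolation rule)
#'
#' Order-statistics percentile with linear interpolation: for a sorted
#' vector `x` of length `n` and level `p`, the value at fractional rank
#' `h = (n - 1) p + 1`, i.e. `x[floor(h)] + (h - floor(h)) *
#' (x[floor(h) + 1] - x[floor(h)])`.  For a length-100 vector at
#' `p = 0.95` this is `x[95] + 0.05 * (x[96] - x[95])` (1-based).
#'
#' @param values numeric vector, length >= 20 (shorter vectors make
#'   1-in-20-year return-level estimation meaningless).
#' @param level percentile level in (0, 1); default 0.95.
#' @return The percentile value.
#' @export
percentile_95 <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 20L) {
    stop("need at least 20 values; return-level estimation is not ",
         "meaningful on shorter series", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  x <- sort(values)
  h <- (n - 1) * level + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

#' Return period of a percentile level
#'
#' A year exceeding the level-`p` percentile occurs with probability
#' `1 - p`, i.e. once every `1 / (1 - p)` years on average; the 95th
#' percentile is the 1-in-20-year event.
#'
#' @param percentile_level probability in (0, 1).
#' @param n_years series length for the expected exceedance count.
#' @return List with `years` (mean recurrence interval) and
#'   `expected_exceedances` (`n_years * (1 - level)`).
#' @export
return_period <- function(percentile_level, n_years = 100) {
  if (percentile_level <= 0 || percentile_level >= 1) {
    stop("percentile_level must be in (0, 1)", call. = FALSE)
  }
  list(years = 1 / (1 - percentile_level),
       expected_exceedances = n_years * (1 - percentile_level))
}

#' Run the paired tolerant/sensitive protocol for one site x scenario
#'
#' Generates one shared weather series and runs three cultivar profiles
#' on identical weather: the tolerant reference (both mechanisms off,
#' yield `Y`), a drought-sensitive-only profile (heat mechanism off,
#' `Y_D`) and a heat-sensitive-only profile (drought mechanism off,
#' `Y_H`).  Per-year DSI and HSI and their 95th percentiles follow.
#' Switching a mechanism off suppresses its yield reduction only; the
#' shared transpiration and canopy-temperature diagnostics are identical
#' across profiles, so indirect effects of water status on canopy
#' temperature are retained.
#'
#' Years whose season fails (thermal time not reached, stress window
#' truncated) or whose tolerant yield is zero are excluded from the index
#' vectors and counted in `exclusions`.
#'
#' @param site_params baseline [site_climate_params()].
#' @param cultivar base [cultivar_params()]; its switches are overridden
#'   per profile.
#' @param soil a [soil_params()] object.
#' @param sowing_doy sowing day of year.
#' @param delta optional [climate_delta()]; `NULL` means baseline.
#' @param n_years number of seasons (>= 20); one extra weather year is
#'   generated so every season can cross the year boundary.
#' @param seed integer seed for the shared weather series.
#' @param co2_baseline baseline CO2, ppm; used when `delta` is `NULL` and
#'   as the RUE reference concentration.
#' @param windows a [stress_windows()] object.
#' @param config a [crop_model_config()] list.
#' @return An object of class `stress_index_set`: list with `site_id`,
#'   `scenario_label`, `dsi_by_year`, `hsi_by_year` (index vectors over
#'   retained years), `dsi95p`, `hsi95p`, `n_years`, `exclusions`,
#'   `percentile_rule`, and `seasons`, a per-year data frame of
#'   tolerant-profile diagnostics (yields of all three profiles, anthesis
#'   day, flowering-window water status and canopy temperatures).
#' @export
run_paired_protocol <- function(site_params, cultivar, soil, sowing_doy,
                                delta = NULL, n_years = 100, seed = 1L,
                                co2_baseline = 363.8,
                                windows = stress_windows(),
                                config = crop_model_config()) {
  if (n_years < 20) stop("n_years must be >= 20", call. = FALSE)
  params <- site_params
  co2 <- co2_baseline
  label <- "baseline"
  if (!is.null(delta)) {
    params <- apply_delta(site_params, delta)
    co2 <- delta$co2
    label <- delta$label
  }
  series <- generate_series(params, n_years + 1L, seed)

  profiles <- list(
    tolerant = make_cultivar("tolerant", cultivar),
    drought = make_cultivar("drought_sensitive_only", cultivar),
    heat = make_cultivar("heat_sensitive_only", cultivar)
  )
  runs <- lapply(profiles, function(cv) {
    run_seasons(series, n_years, sowing_doy, cv, soil,
                co2 = co2, co2_ref = co2_baseline,
                windows = windows, config = config)
  })

  failed <- runs$tolerant$failed | runs$drought$failed | runs$heat$failed
  get <- function(run, field) {
    vapply(seq_len(n_years), function(i) {
      if (failed[i]) NA_real_ else as.numeric(run$results[[i]][[field]])
    }, numeric(1))
  }
  y <- get(runs$tolerant, "yield")
  y_d <- get(runs$drought, "yield")
  y_h <- get(runs$heat, "yield")

  # shared-weather contract: phenology cannot differ between profiles
  anth <- get(runs$tolerant, "anthesis_das")
  stopifnot(identical(anth, get(runs$drought, "anthesis_das")),
            identical(anth, get(runs$heat, "anthesis_das")))

  keep <- !failed & !is.na(y) & y > 0
  if (!any(keep)) {
    stop("all seasons failed or had zero reference yield at site ",
         params$site_id, call. = FALSE)
  }
  snap_unit <- function(x) {
    # tolerate accumulation round-off at the interval ends only
    x[x < 0 & x > -1e-9] <- 0
    x[x > 1 & x < 1 + 1e-9] <- 1
    x
  }
  dsi_by_year <- snap_unit(dsi(y_d[keep], y[keep]))
  hsi_by_year <- snap_unit(hsi(y_h[keep], y[keep]))

  seasons <- data.frame(
    year = seq_len(n_years),
    excluded = !keep,
    y = y, y_d = y_d, y_h = y_h,
    anthesis_das = anth,
    maturity_das = get(runs$tolerant, "maturity_das"),
    eta_at_flowering = get(runs$tolerant, "eta_at_flowering"),
    etp_at_flowering = get(runs$tolerant, "etp_at_flowering"),
    raw_at_flowering = get(runs$tolerant, "raw_at_flowering"),
    dsf = get(runs$tolerant, "dsf"),
    tcan_max_pre = get(runs$tolerant, "tcan_max_pre"),
    tcan_max_post = get(runs$tolerant, "tcan_max_post")
  )

  structure(list(
    site_id = params$site_id,
    scenario_label = label,
    scenario = if (is.null(delta)) "baseline" else delta$scenario,
    gcm = if (is.null(delta)) "none" else delta$gcm,
    dsi_by_year = dsi_by_year,
    hsi_by_year = hsi_by_year,
    dsi95p = percentile_95(dsi_by_year),
    hsi95p = percentile_95(hsi_by_year),
    n_years = as.integer(n_years),
    exclusions = as.integer(sum(!keep)),
    percentile_rule = "linear_interpolation",
    seasons = seasons
  ), class = "stress_index_set")
}
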