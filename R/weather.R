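# Stochastic daily weather: estimation of site parameters from observed
# series, generation of multi-year daily series, and delta-change
# perturbation for future scenarios.
#
# Model: first-order two-state (wet/dry) Markov occurrence chain with
# monthly transition probabilities; gamma wet-day amounts (monthly shape
# and mean, truncated below at 0.1 mm); AR(1) standard-normal temperature
# anomaly scaled by the monthly sd and added to the monthly mean tmax,
# with tmin a fixed diurnal range below tmax; lognormal daily radiation
# around the monthly mean with a global cv.  Years are 365 days.

WET_TRUNCATION_MM <- 0.1

#' Estimate weather-generator parameters from an observed daily series
#'
#' Monthly temperature and radiation moments are the sample statistics of
#' the input; wet/dry transition probabilities are maximum-likelihood
#' transition counts per month (a wet day has precipitation > 0 mm);
#' wet-day gamma parameters come from method-of-moments fits per month.
#' The temperature autocorrelation is the lag-1 autocorrelation of the
#' pooled within-year tmax anomalies about their monthly means.
#'
#' @param observed data frame with columns `year`, `doy`, `tmin_c`,
#'   `tmax_c`, `precip_mm`, `rad_mj_m2`; at least 3 complete 365-day years.
#' @param latitude site latitude, degrees.
#' @param site_id identifier carried into the result.
#' @return A [site_climate_params()] object.  Months with no wet days get
#'   `p_wet_given_* = 0` and NA wet-amount shape (flagged undefined).
#' @export
estimate_params <- function(observed, latitude = 0, site_id = "site") {
  need <- c("year", "doy", "tmin_c", "tmax_c", "precip_mm", "rad_mj_m2")
  missing_cols <- setdiff(need, names(observed))
  if (length(missing_cols)) {
    stop("observed series lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  years <- sort(unique(observed$year))
  if (length(years) < 3L) {
    stop("need at least 3 complete years of daily records", call. = FALSE)
  }
  for (y in years) {
    doys <- sort(observed$doy[observed$year == y])
    gaps <- setdiff(seq_len(DAYS_PER_YEAR), doys)
    if (length(gaps)) {
      stop(sprintf("year %s is missing day(s) of year: %s", y,
                   paste(utils::head(gaps, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  obs <- observed[order(observed$year, observed$doy), ]
  month <- month_of_doy(obs$doy)
  wet <- obs$precip_mm > 0

  mmean <- function(x) as.numeric(tapply(x, month, mean))
  msd <- function(x) {
    s <- as.numeric(tapply(x, month, stats::sd))
    ifelse(is.na(s), 0, s)
  }

  # wet/dry transitions within years (first day of each year has no
  # predecessor and is excluded from the counts)
  prev_wet <- c(NA, wet[-length(wet)])
  prev_wet[obs$doy == 1L] <- NA
  ok <- !is.na(prev_wet)
  trans_month <- month[ok]
  p_wd <- numeric(12)
  p_ww <- numeric(12)
  for (m in 1:12) {
    sel <- trans_month == m
    from_dry <- sel & !prev_wet[ok]
    from_wet <- sel & prev_wet[ok]
    p_wd[m] <- if (any(from_dry)) mean(wet[ok][from_dry]) else 0
    p_ww[m] <- if (any(from_wet)) mean(wet[ok][from_wet]) else 0
  }

  shape <- rep(NA_real_, 12)
  amt_mean <- numeric(12)
  for (m in 1:12) {
    amts <- obs$precip_mm[wet & month == m]
    if (length(amts) == 0L) {
      amt_mean[m] <- 0           # all-dry month: amount parameters undefined
    } else {
      amt_mean[m] <- mean(amts)
      v <- stats::var(amts)
      shape[m] <- if (is.na(v) || v <= 0) 1 else amt_mean[m]^2 / v
    }
  }

  monthly_mean_tmax <- mmean(obs$tmax_c)
  anom <- obs$tmax_c - monthly_mean_tmax[month]
  sd_anom <- stats::sd(anom)
  rho <- if (is.na(sd_anom) || sd_anom == 0) 0 else {
    a <- anom[-length(anom)]
    b <- anom[-1]
    keep <- obs$doy[-1] != 1L          # don't correlate across year breaks
    suppressWarnings(stats::cor(a[keep], b[keep]))
  }
  if (is.na(rho)) rho <- 0
  rho <- max(min(rho, 0.99), -0.99)

  rad_mean <- mmean(obs$rad_mj_m2)
  rad_anom_cv <- obs$rad_mj_m2 / rad_mean[month]
  rad_cv <- stats::sd(rad_anom_cv)
  if (is.na(rad_cv)) rad_cv <- 0

  site_climate_params(
    monthly_mean_tmax = monthly_mean_tmax,
    monthly_mean_tmin = mmean(obs$tmin_c),
    monthly_sd_tmax = msd(obs$tmax_c),
    monthly_sd_tmin = msd(obs$tmin_c),
    temp_autocorr = rho,
    p_wet_given_dry = p_wd,
    p_wet_given_wet = p_ww,
    wet_amount_shape = shape,
    wet_amount_mean = amt_mean,
    monthly_mean_radiation = rad_mean,
    radiation_cv = rad_cv,
    latitude = latitude,
    site_id = site_id
  )
}

#' Generate a multi-year daily weather series
#'
#' Draws `n_years` 365-day years from the stochastic model described in
#' [site_climate_params()].  The occurrence chain and the AR(1)
#' temperature anomaly run continuously across year boundaries; the chain
#' is initialised at its January stationary wet-day frequency and the
#' anomaly at its stationary distribution.  Wet-day amounts are truncated
#' below at 0.1 mm (months with zero mean amount stay dry).  Identical
#' `(params, n_years, seed)` give a byte-identical series.
#'
#' @param params a [site_climate_params()] object.
#' @param n_years number of years (>= 1).
#' @param seed integer seed.
#' @return Data frame with columns `year`, `doy`, `tmin_c`, `tmax_c`,
#'   `precip_mm`, `rad_mj_m2` and `365 * n_years` rows.
#' @export
generate_series <- function(params, n_years, seed) {
  stopifnot(inherits(params, "site_climate_params"))
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  n <- DAYS_PER_YEAR * as.integer(n_years)
  doy <- rep(seq_len(DAYS_PER_YEAR), n_years)
  year <- rep(seq_len(n_years), each = DAYS_PER_YEAR)
  m <- month_of_doy(doy)

  # --- precipitation occurrence: two-state chain, monthly probabilities
  u <- stats::runif(n)
  wet <- logical(n)
  p_wd <- params$p_wet_given_dry
  p_ww <- params$p_wet_given_wet
  denom <- 1 + p_wd[1] - p_ww[1]
  pi0 <- if (denom > 0) p_wd[1] / denom else 1   # Jan stationary frequency
  state <- stats::runif(1) < pi0
  for (i in seq_len(n)) {
    p <- if (state) p_ww[m[i]] else p_wd[m[i]]
    state <- u[i] < p
    wet[i] <- state
  }

  # --- wet-day amounts: gamma with monthly shape/mean
  precip <- numeric(n)
  iw <- which(wet)
  if (length(iw)) {
    mw <- m[iw]
    shp <- params$wet_amount_shape[mw]
    mu <- params$wet_amount_mean[mw]
    shp[is.na(shp)] <- 1
    amt <- ifelse(mu > 0,
                  pmax(stats::rgamma(length(iw), shape = shp,
                                     scale = ifelse(shp > 0, mu / shp, 0)),
                       WET_TRUNCATION_MM),
                  0)
    precip[iw] <- amt
  }

  # --- temperatures: stationary AR(1) standard anomaly, monthly scaling
  rho <- params$temp_autocorr
  eps <- stats::rnorm(n)
  z <- as.numeric(stats::filter(eps * sqrt(1 - rho^2), rho,
                                method = "recursive",
                                init = stats::rnorm(1)))
  tmax <- params$monthly_mean_tmax[m] + params$monthly_sd_tmax[m] * z
  tmin <- tmax - (params$monthly_mean_tmax[m] - params$monthly_mean_tmin[m])

  # --- radiation: lognormal around the monthly mean
  cv <- params$radiation_cv
  if (cv > 0) {
    sig2 <- log(1 + cv^2)
    rad <- stats::rlnorm(n,
                         meanlog = log(params$monthly_mean_radiation[m]) - sig2 / 2,
                         sdlog = sqrt(sig2))
  } else {
    rad <- params$monthly_mean_radiation[m]
  }

  data.frame(year = year, doy = doy, tmin_c = tmin, tmax_c = tmax,
             precip_mm = precip, rad_mj_m2 = rad)
}

#' Perturb site parameters by a delta-change scenario
#'
#' Monthly temperature means shift additively; monthly wet-day amount
#' means and radiation means scale multiplicatively.  All other
#' parameters — standard deviations, autocorrelation, transition
#' probabilities, gamma shapes — are unchanged, so scenario construction
#' perturbs first moments only.
#'
#' @param params a [site_climate_params()] object (baseline).
#' @param delta a [climate_delta()] object.
#' @return A new `site_climate_params` object.
#' @export
apply_delta <- function(params, delta) {
  stopifnot(inherits(params, "site_climate_params"),
            inherits(delta, "climate_delta"))
  out <- unclass(params)
  out$monthly_mean_tmax <- params$monthly_mean_tmax + delta$d_tmax
  out$monthly_mean_tmin <- params$monthly_mean_tmin + delta$d_tmin
  out$wet_amount_mean <- params$wet_amount_mean * delta$precip_factor
  out$monthly_mean_radiation <-
    params$monthly_mean_radiation * delta$radiation_factor
  out <- structure(out, class = "site_climate_params")
  validate_site_climate_params(out)
  out
}
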