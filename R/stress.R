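# Flowering-window stress responses.
#
# Drought acts on primary fertile grain set through a piecewise linear
# function of the drought stress factor (DSF = actual / potential
# transpiration over the drought window).  Heat acts through two clamped
# linear functions of the maximum canopy temperature: on grain set over
# the pre-anthesis window (meiosis and fertilisation) and on potential
# grain weight over the early grain-fill window (endosperm development).

#' Drought reduction factor on grain set
#'
#' Piecewise linear response of the grain-number reduction factor to the
#' drought stress factor `dsf`:
#' no reduction (`R_D = 1`) above the threshold `dsgnt`; the floor
#' `dsgnr_max` at or below the saturation `dsgns`; and in between the
#' linear segment `R_D = dsgnr_max + S * (dsf - dsgns)` with derived slope
#' `S = (1 - dsgnr_max) / (dsgnt - dsgns)`.  Continuous, non-decreasing,
#' and bounded in `[dsgnr_max, 1]`.
#'
#' @param dsf drought stress factor in \[0, 1\] (ratio of actual to
#'   potential transpiration over the drought window); vectorised.
#' @param p a [stress_params()] object.
#' @return Reduction factor(s) in \[0, 1\].
#' @export
drought_reduction_factor <- function(dsf, p) {
  stopifnot(inherits(p, "stress_params"))
  if (any(dsf < 0 | dsf > 1)) {
    stop("dsf must be in [0, 1]", call. = FALSE)
  }
  s <- (1 - p$dsgnr_max) / (p$dsgnt - p$dsgns)
  ifelse(dsf > p$dsgnt, 1,
         ifelse(dsf <= p$dsgns, p$dsgnr_max,
                p$dsgnr_max + s * (dsf - p$dsgns)))
}

#' Heat reduction factor on grain set
#'
#' `R_H = max(0, min(1, 1 - (tcan_max - t_n) * s_n))`, where `tcan_max` is
#' the maximum canopy temperature over the window from 10 days before
#' anthesis to anthesis.
#'
#' @param tcan_max maximum canopy temperature over the pre-anthesis
#'   window, degrees C; vectorised.
#' @param p a [stress_params()] object.
#' @return Reduction factor(s) in \[0, 1\].
#' @export
heat_grain_number_factor <- function(tcan_max, p) {
  stopifnot(inherits(p, "stress_params"))
  pmax(0, pmin(1, 1 - (tcan_max - p$t_n) * p$s_n))
}

#' Heat reduction factor on potential grain weight
#'
#' `R_W = max(0, min(1, 1 - (tcan_max - t_w) * s_w))`, where `tcan_max` is
#' the maximum canopy temperature over the window 5-12 days after
#' anthesis.
#'
#' @param tcan_max maximum canopy temperature over the early grain-fill
#'   window, degrees C; vectorised.
#' @param p a [stress_params()] object.
#' @return Reduction factor(s) in \[0, 1\].
#' @export
heat_grain_weight_factor <- function(tcan_max, p) {
  stopifnot(inherits(p, "stress_params"))
  pmax(0, pmin(1, 1 - (tcan_max - p$t_w) * p$s_w))
}

#' Flowering-window diagnostics from daily season series
#'
#' Computes the inputs of the stress responses from day-level season
#' output: the drought stress factor (ratio of summed actual to summed
#' potential transpiration over the drought window, with an all-zero
#' demand window defined as unstressed, DSF = 1) and the maximum canopy
#' temperature over each heat window.
#'
#' @param ta,tp,tcan daily actual transpiration, potential transpiration
#'   (mm) and canopy maximum temperature (deg C), indexed by day after
#'   sowing (element 1 = DAS 1).
#' @param anthesis_das anthesis day after sowing.
#' @param windows a [stress_windows()] object.
#' @return List with `dsf`, `tcan_max_pre`, `tcan_max_post`.
#' @export
window_diagnostics <- function(ta, tp, tcan, anthesis_das,
                               windows = stress_windows()) {
  stopifnot(inherits(windows, "stress_windows"))
  n <- length(tp)
  all_offsets <- c(windows$drought, windows$heat_number, windows$heat_weight)
  days_needed <- anthesis_das + range(all_offsets)
  if (days_needed[1] < 1L || days_needed[2] > n) {
    stop(sprintf(paste0("anthesis at DAS %d is too close to the season edge ",
                        "for a full stress window (need DAS %d..%d, have 1..%d)"),
                 anthesis_das, days_needed[1], days_needed[2], n),
         call. = FALSE)
  }
  dwin <- anthesis_das + windows$drought
  tp_sum <- sum(tp[dwin])
  dsf <- if (tp_sum > 0) sum(ta[dwin]) / tp_sum else 1
  list(dsf = dsf,
       tcan_max_pre = max(tcan[anthesis_das + windows$heat_number]),
       tcan_max_post = max(tcan[anthesis_das + windows$heat_weight]))
}
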