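# Country-level and global summaries: means over sites, GCM-ensemble
# statistics, extreme-site selection and impact rankings.

#' Unweighted mean over sites
#'
#' @param per_site_values named numeric vector (one value per site).
#' @return The arithmetic mean.
#' @export
global_mean <- function(per_site_values) {
  if (length(per_site_values) == 0L) {
    stop("no site values to average", call. = FALSE)
  }
  mean(as.numeric(per_site_values))
}

#' Select the most extreme site within a country
#'
#' Returns the site with the largest GCM-ensemble-mean stress index;
#' drought and heat selections run independently and may pick different
#' sites.  Ties break to the lexicographically smallest site id.
#'
#' @param country_sites named numeric vector: GCM-mean index per site.
#' @return The selected site id (character).
#' @export
select_extreme_site <- function(country_sites) {
  if (length(country_sites) == 0L) {
    stop("no sites in country", call. = FALSE)
  }
  v <- as.numeric(country_sites)
  ids <- names(country_sites)
  if (is.null(ids)) stop("country_sites must be named by site id", call. = FALSE)
  cand <- ids[v == max(v)]
  sort(cand)[1]
}

#' Relative change between scenarios, in percent
#'
#' `100 * (future - baseline) / baseline`.  A zero baseline makes the
#' relative change undefined: the result is `NA` with the absolute
#' difference attached as attribute `abs_difference`.
#'
#' @param future,baseline scalar values on the same scale.
#' @return Percent change (numeric scalar), or `NA` flagged as above.
#' @export
relative_change <- function(future, baseline) {
  if (baseline == 0) {
    warning("baseline is 0; relative change undefined, reporting absolute ",
            "difference in attribute 'abs_difference'", call. = FALSE)
    return(structure(NA_real_, abs_difference = future - baseline))
  }
  100 * (future - baseline) / baseline
}

#' Summarise stress indices per country, scenario and stress kind
#'
#' From a long table of per-site, per-GCM index values, computes for each
#' country x scenario x stress kind: the GCM-ensemble mean per site, the
#' country mean over sites, the extreme site (argmax of the site-level
#' GCM means), and the GCM-ensemble spread (5th, 25th, 50th, 75th, 95th
#' percentiles) of the extreme site's per-GCM values.
#'
#' @param indices data frame with columns `site`, `country`, `scenario`,
#'   `gcm`, `dsi95p`, `hsi95p` (one row per site x scenario x GCM), as
#'   written by [cmd_run_indices()].
#' @return Data frame with one row per country x scenario x stress kind
#'   and columns `country`, `scenario`, `stress`, `n_sites`,
#'   `country_mean`, `extreme_site`, `ensemble_mean`, `p05`, `p25`,
#'   `p50`, `p75`, `p95`.
#' @export
summarize_countries <- function(indices) {
  need <- c("site", "country", "scenario", "gcm", "dsi95p", "hsi95p")
  if (!all(need %in% names(indices))) {
    stop("indices table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(indices) == 0L) stop("indices table is empty", call. = FALSE)
  out <- list()
  for (stress in c("drought", "heat")) {
    col <- if (stress == "drought") "dsi95p" else "hsi95p"
    for (cc in unique(indices$country)) {
      for (sc in unique(indices$scenario)) {
        sub <- indices[indices$country == cc & indices$scenario == sc, ]
        if (nrow(sub) == 0L) next
        site_means <- tapply(sub[[col]], sub$site, mean)
        site_means <- site_means[sort(names(site_means))]
        extreme <- select_extreme_site(site_means)
        ext_vals <- sub[[col]][sub$site == extreme]
        qs <- as.numeric(stats::quantile(ext_vals,
                                         c(0.05, 0.25, 0.5, 0.75, 0.95),
                                         type = 7))
        out[[length(out) + 1L]] <- data.frame(
          country = cc, scenario = sc, stress = stress,
          n_sites = length(site_means),
          country_mean = mean(site_means),
          extreme_site = extreme,
          ensemble_mean = mean(ext_vals),
          p05 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p95 = qs[5]
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Rank countries by extreme-site ensemble-mean impact
#'
#' Descending, stable ranking of countries by the GCM-ensemble mean index
#' at each country's extreme site, for one scenario and stress kind.
#' When a baseline scenario is given, a `rank_change` column reports
#' baseline rank minus scenario rank (positive = the country moved up).
#'
#' @param summaries output of [summarize_countries()].
#' @param scenario scenario to rank.
#' @param stress `"drought"` or `"heat"`.
#' @param baseline_scenario optional scenario for rank deltas.
#' @return Data frame ordered by rank with columns `country`, `scenario`,
#'   `stress`, `extreme_site`, `ensemble_mean`, `rank` and (if a baseline
#'   was given) `rank_change`.
#' @export
rank_countries <- function(summaries, scenario, stress = c("drought", "heat"),
                           baseline_scenario = NULL) {
  stress <- match.arg(stress)
  sub <- summaries[summaries$scenario == scenario &
                     summaries$stress == stress, ]
  if (nrow(sub) == 0L) stop("no rows for that scenario and stress kind",
                            call. = FALSE)
  ord <- order(-sub$ensemble_mean)        # radix order is stable
  ranked <- sub[ord, c("country", "scenario", "stress", "extreme_site",
                       "ensemble_mean")]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$rank_change <- NA_integer_
  if (!is.null(baseline_scenario)) {
    base <- rank_countries(summaries, baseline_scenario, stress)
    ranked$rank_change <-
      base$rank[match(ranked$country, base$country)] - ranked$rank
  }
  rownames(ranked) <- NULL
  ranked
}
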