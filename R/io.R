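# Configuration files, tabular output with provenance headers, and the
# commands tying the pipeline together.  Configs are YAML; all tabular
# outputs are CSV with '#'-prefixed provenance comment lines (tool
# version, config digest, master seed) so any output can be re-derived.

pkg_version <- function() {
  as.character(utils::packageVersion("wheatstress"))
}

#' Deterministic sub-seed for a site x scenario combination
#'
#' Hashes the master seed with the site and scenario identifiers so every
#' combination gets its own reproducible stream; results stay below 2^31.
#'
#' @param master integer master seed.
#' @param site_id,scenario_label identifiers.
#' @return Integer seed.
#' @export
derive_seed <- function(master, site_id, scenario_label) {
  h <- as.integer(master) %% 2147483563
  for (c in utf8ToInt(paste(site_id, scenario_label, sep = "|"))) {
    h <- (h * 31 + c) %% 2147483563
  }
  as.integer(h)
}

provenance_header <- function(seed, digest = NA_character_) {
  c(sprintf("# wheatstress %s", pkg_version()),
    sprintf("# master_seed: %s", seed),
    sprintf("# config_digest: %s", digest))
}

#' Write a data frame as CSV with a provenance comment header
#'
#' @param df data frame.
#' @param path output path.
#' @param seed master seed recorded in the header.
#' @param digest config digest recorded in the header.
#' @return The path, invisibly.
#' @export
write_csv_provenance <- function(df, path, seed = NA, digest = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, digest), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_provenance()]
#'
#' @param path file path.
#' @return Data frame (comment lines skipped).
#' @export
read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a daily weather series CSV
#'
#' Columns `year,doy,tmin_c,tmax_c,precip_mm,rad_mj_m2`; the same format
#' is accepted wherever a weather series is an input.
#'
#' @param series weather data frame from [generate_series()].
#' @param path file path.
#' @param seed,digest provenance fields.
#' @return The path ([write_weather_csv()]) or a data frame
#'   ([read_weather_csv()]).
#' @export
write_weather_csv <- function(series, path, seed = NA, digest = NA_character_) {
  write_csv_provenance(series, path, seed, digest)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- read_csv_provenance(path)
  need <- c("year", "doy", "tmin_c", "tmax_c", "precip_mm", "rad_mj_m2")
  if (!all(need %in% names(df))) {
    stop("weather CSV ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}

# ---- site / delta / run configs (YAML) --------------------------------

#' Write and read a site configuration file
#'
#' A site config holds the climate parameter block plus the site's
#' country, sowing date, soil and cultivar (including the stress block
#' and mechanism switches).
#'
#' @param site list with elements `climate` (a [site_climate_params()]),
#'   `country`, `sowing_doy`, `soil` (a [soil_params()]), `cultivar`
#'   (a [cultivar_params()]).
#' @param path file path.
#' @return The path, invisibly ([write_site_config()]); a site list with
#'   rebuilt parameter objects ([read_site_config()]).
#' @export
write_site_config <- function(site, path) {
  stopifnot(inherits(site$climate, "site_climate_params"),
            inherits(site$soil, "soil_params"),
            inherits(site$cultivar, "cultivar_params"))
  cv <- site$cultivar
  obj <- list(
    site_id = site$climate$site_id,
    country = site$country,
    sowing_doy = as.integer(site$sowing_doy),
    climate = unclass(site$climate),
    soil = unclass(site$soil),
    cultivar = c(unclass(cv)[setdiff(names(cv), "stress")],
                 list(stress = unclass(cv$stress)))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_site_config
#' @export
read_site_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cl <- obj$climate
  climate <- site_climate_params(
    monthly_mean_tmax = cl$monthly_mean_tmax,
    monthly_mean_tmin = cl$monthly_mean_tmin,
    monthly_sd_tmax = cl$monthly_sd_tmax,
    monthly_sd_tmin = cl$monthly_sd_tmin,
    temp_autocorr = cl$temp_autocorr,
    p_wet_given_dry = cl$p_wet_given_dry,
    p_wet_given_wet = cl$p_wet_given_wet,
    wet_amount_shape = sapply(cl$wet_amount_shape,
                              function(x) if (is.null(x)) NA_real_ else x),
    wet_amount_mean = cl$wet_amount_mean,
    monthly_mean_radiation = cl$monthly_mean_radiation,
    radiation_cv = cl$radiation_cv,
    latitude = cl$latitude,
    site_id = cl$site_id
  )
  cv <- obj$cultivar
  cultivar <- cultivar_params(
    tt_sowing_to_anthesis = cv$tt_sowing_to_anthesis,
    tt_anthesis_to_maturity = cv$tt_anthesis_to_maturity,
    base_temp = cv$base_temp,
    rue_ref = cv$rue_ref,
    k_light = cv$k_light,
    max_lai = cv$max_lai,
    n_pot = cv$n_pot,
    ear_mass_fraction = cv$ear_mass_fraction,
    w_pot = cv$w_pot,
    retrans_fraction = cv$retrans_fraction,
    stress = do.call(stress_params, cv$stress),
    drought_mech_on = cv$drought_mech_on,
    heat_mech_on = cv$heat_mech_on
  )
  list(climate = climate,
       country = obj$country,
       sowing_doy = as.integer(obj$sowing_doy),
       soil = do.call(soil_params, obj$soil),
       cultivar = cultivar)
}

#' Write and read a delta-change scenario file
#'
#' @param delta a [climate_delta()] object.
#' @param path file path.
#' @return The path, invisibly ([write_delta_config()]); a
#'   `climate_delta` ([read_delta_config()]).
#' @export
write_delta_config <- function(delta, path) {
  stopifnot(inherits(delta, "climate_delta"))
  yaml::write_yaml(unclass(delta), path, precision = 15)
  invisible(path)
}

#' @rdname write_delta_config
#' @export
read_delta_config <- function(path) {
  obj <- yaml::read_yaml(path)
  climate_delta(d_tmax = obj$d_tmax, d_tmin = obj$d_tmin,
                precip_factor = obj$precip_factor,
                radiation_factor = obj$radiation_factor,
                co2 = obj$co2, label = obj$label,
                scenario = obj$scenario, gcm = obj$gcm)
}

#' Load a run configuration
#'
#' The run config lists site and scenario file paths and the global run
#' settings (years, master seed, baseline CO2, output directory,
#' percentile rule, window convention).
#'
#' @param path YAML run config path.
#' @return List of class `run_config` with resolved defaults and a
#'   `digest` (md5 of the config file).
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- list(
    sites = as.character(obj$sites),
    scenarios = as.character(obj$scenarios %||% character()),
    n_years = as.integer(obj$n_years %||% 100L),
    seed = as.integer(obj$seed %||% 1L),
    co2_baseline = as.numeric(obj$co2_baseline %||% 363.8),
    output_dir = as.character(obj$output_dir %||% "."),
    percentile_rule = as.character(obj$percentile_rule %||%
                                     "linear_interpolation"),
    window_convention = as.character(obj$window_convention %||% "inclusive"),
    digest = unname(tools::md5sum(path))
  )
  if (cfg$n_years < 20) stop("n_years must be >= 20", call. = FALSE)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  cfg$sites <- resolve(cfg$sites)
  cfg$scenarios <- if (length(cfg$scenarios)) resolve(cfg$scenarios) else
    character()
  missing_files <- c(cfg$sites, cfg$scenarios)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files)) {
    stop("referenced config file(s) not found: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline commands -------------------------------------------------

#' Generate weather CSVs for every site x scenario
#'
#' One file per site and scenario (baseline plus each delta file), seeded
#' deterministically by (master seed, site, scenario) so reruns are
#' byte-identical.
#'
#' @param config a `run_config` (or path to one).
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_generate_weather <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  deltas <- lapply(cfg$scenarios, read_delta_config)
  paths <- character()
  for (sp in cfg$sites) {
    site <- read_site_config(sp)
    for (k in seq_len(length(deltas) + 1L)) {
      if (k == 1L) {
        params <- site$climate
        label <- "baseline"
      } else {
        params <- apply_delta(site$climate, deltas[[k - 1L]])
        label <- deltas[[k - 1L]]$label
      }
      seed_k <- derive_seed(cfg$seed, site$climate$site_id, label)
      series <- generate_series(params, cfg$n_years, seed_k)
      out <- file.path(cfg$output_dir,
                       sprintf("weather_%s_%s.csv", site$climate$site_id,
                               gsub("[^A-Za-z0-9_.-]", "-", label)))
      write_weather_csv(series, out, seed = cfg$seed, digest = cfg$digest)
      paths <- c(paths, out)
    }
  }
  invisible(paths)
}

#' Run the paired stress-index protocol for every site x scenario
#'
#' Writes `indices.csv` (one row per site x scenario x GCM),
#' `indices_by_year.csv` (long per-year index vectors) and `run_log.txt`
#' (seeds, config digest, percentile rule, exclusion counts).  Per-site
#' failures are isolated and reported together at the end.
#'
#' @param config a `run_config` (or path to one).
#' @param per_year write the per-year long CSV (default TRUE).
#' @return The indices data frame, invisibly.
#' @export
cmd_run_indices <- function(config, per_year = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- stress_windows(cfg$window_convention)
  deltas <- lapply(cfg$scenarios, read_delta_config)
  scenarios <- c(list(NULL), deltas)

  rows <- list()
  yearly <- list()
  log_lines <- c(provenance_header(cfg$seed, cfg$digest),
                 sprintf("# percentile_rule: %s", cfg$percentile_rule),
                 sprintf("# window_convention: %s", cfg$window_convention))
  failures <- character()
  for (sp in cfg$sites) {
    site <- read_site_config(sp)
    sid <- site$climate$site_id
    for (delta in scenarios) {
      label <- if (is.null(delta)) "baseline" else delta$label
      seed_k <- derive_seed(cfg$seed, sid, label)
      res <- tryCatch(
        run_paired_protocol(site$climate, site$cultivar, site$soil,
                            site$sowing_doy, delta = delta,
                            n_years = cfg$n_years, seed = seed_k,
                            co2_baseline = cfg$co2_baseline,
                            windows = windows),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s x %s: %s", sid, label,
                                        conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = sid, country = site$country,
        scenario = res$scenario, gcm = res$gcm,
        scenario_label = label,
        dsi95p = res$dsi95p, hsi95p = res$hsi95p,
        n_years = res$n_years, exclusions = res$exclusions,
        percentile_rule = res$percentile_rule
      )
      if (per_year) {
        yearly[[length(yearly) + 1L]] <- data.frame(
          site = sid, scenario_label = label,
          year = seq_along(res$dsi_by_year),
          dsi = res$dsi_by_year, hsi = res$hsi_by_year
        )
      }
      log_lines <- c(log_lines,
                     sprintf("%s x %s: seed=%d exclusions=%d", sid, label,
                             seed_k, res$exclusions))
    }
  }
  indices <- NULL
  if (length(rows)) {
    indices <- do.call(rbind, rows)
    write_csv_provenance(indices, file.path(cfg$output_dir, "indices.csv"),
                         cfg$seed, cfg$digest)
    if (per_year) {
      write_csv_provenance(do.call(rbind, yearly),
                           file.path(cfg$output_dir, "indices_by_year.csv"),
                           cfg$seed, cfg$digest)
    }
  }
  writeLines(log_lines, file.path(cfg$output_dir, "run_log.txt"))
  if (length(failures)) {
    stop("site x scenario failures:\n", paste(failures, collapse = "\n"),
         call. = FALSE)
  }
  invisible(indices)
}

#' Aggregate per-site indices into country summaries and rankings
#'
#' @param config a `run_config` (or path to one).
#' @param indices_path path to an `indices.csv` written by
#'   [cmd_run_indices()]; defaults to the one in the config's output
#'   directory.
#' @return List with `summary` and `ranking` data frames, invisibly;
#'   writes `country_summary.csv` and `ranking.csv`.
#' @export
cmd_aggregate <- function(config, indices_path = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  indices_path <- indices_path %||% file.path(cfg$output_dir, "indices.csv")
  if (!file.exists(indices_path)) {
    stop("indices file not found: ", indices_path, call. = FALSE)
  }
  indices <- read_csv_provenance(indices_path)
  if (nrow(indices) == 0L) {
    stop("indices file is empty; nothing to aggregate", call. = FALSE)
  }
  summary <- summarize_countries(indices)
  scen <- unique(summary$scenario)
  base <- if ("baseline" %in% scen) "baseline" else NULL
  rankings <- do.call(rbind, lapply(scen, function(sc) {
    do.call(rbind, lapply(c("drought", "heat"), function(st) {
      rank_countries(summary, sc, st,
                     baseline_scenario = if (!is.null(base) && sc != base)
                       base else NULL)
    }))
  }))
  write_csv_provenance(summary, file.path(cfg$output_dir,
                                          "country_summary.csv"),
                       cfg$seed, cfg$digest)
  write_csv_provenance(rankings, file.path(cfg$output_dir, "ranking.csv"),
                       cfg$seed, cfg$digest)
  invisible(list(summary = summary, ranking = rankings))
}

#' Write a ready-to-run synthetic fixture tree
#'
#' Materialises a small multi-site, multi-country synthetic study —
#' site configs from the four climate archetypes, a GCM-like delta
#' ensemble per future period, and a run config wiring them together —
#' so the whole pipeline can be exercised end to end from files.
#'
#' @param dir output directory.
#' @param n_gcms ensemble members per future period.
#' @param n_years simulated years per site x scenario.
#' @param seed master seed.
#' @return Path of the written run config, invisibly.
#' @export
make_fixture_tree <- function(dir, n_gcms = 5, n_years = 100, seed = 1L) {
  dir.create(file.path(dir, "configs"), showWarnings = FALSE, recursive = TRUE)
  sites <- list(
    list(id = "alpha", arch = "cool_variable", country = "Northland"),
    list(id = "bravo", arch = "hot_narrow", country = "Southland"),
    list(id = "carlo", arch = "wet_temperate", country = "Northland"),
    list(id = "delta", arch = "dry_continental", country = "Midland"),
    list(id = "echo", arch = "dry_continental", country = "Midland")
  )
  site_paths <- vapply(sites, function(s) {
    spec <- site_fixture_spec(s$id, s$arch, seed = seed)
    site <- list(climate = make_site_params(spec), country = s$country,
                 sowing_doy = spec$sowing_doy,
                 soil = soil_params(sawc = if (s$arch == "dry_continental")
                   120 else 180,
                   initial_smd = if (s$arch == "dry_continental") 30 else 0),
                 cultivar = cultivar_params())
    p <- file.path(dir, "configs", paste0("site_", s$id, ".yaml"))
    write_site_config(site, p)
    p
  }, character(1))
  delta_paths <- character()
  futures <- list(list(scenario = "2050", warming = 2.4, co2 = 562.8),
                  list(scenario = "2090", warming = 4.8, co2 = 1001.8))
  for (f in futures) {
    ens <- make_delta_ensemble(n_gcms, f$warming, 0.8, c(0.8, 1.2),
                               co2 = f$co2,
                               seed = derive_seed(seed, "ens", f$scenario),
                               scenario = f$scenario)
    for (d in ens) {
      p <- file.path(dir, "configs",
                     paste0("delta_", gsub("@", "_", d$label), ".yaml"))
      write_delta_config(d, p)
      delta_paths <- c(delta_paths, p)
    }
  }
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(sites = as.list(site_paths),
                        scenarios = as.list(delta_paths),
                        n_years = n_years, seed = seed,
                        co2_baseline = 363.8,
                        output_dir = file.path(dir, "out"),
                        percentile_rule = "linear_interpolation",
                        window_convention = "inclusive"),
                   cfg_path)
  invisible(cfg_path)
}
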