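# End-to-end orchestration: prep -> extract -> regime split -> search/fit
# -> validate -> classify -> spatial diagnostics, behind a single config.

#' Build a pipeline run configuration
#'
#' @param tracks Track table (data.frame) or path to a track CSV.
#' @param grids Named list of [env_grid()]s or a directory of grid CSVs
#'   (read with [read_env_grid()]).
#' @param out_dir Output directory for all artifacts.
#' @param study_polygon Two-column lon/lat matrix, path to a GeoJSON
#'   Polygon, or `NULL` to skip the containment rule.
#' @param predictors Candidate predictor (grid) names offered to the model
#'   search.
#' @param detrend Predictors to latitudinally detrend; each adds a
#'   `dt<NAME>` candidate.
#' @param building_years,validation_years Calendar years assigned to the
#'   model-building (positive-NPGO) and validation (negative-NPGO) sets.
#' @param filter A [filter_config()].
#' @param npmr An [npmr_control()].
#' @param depth_grid Grid name used for the seafloor-depth filter.
#' @param seed Seed recorded in the manifest and used for any stochastic
#'   stage.
#' @param run_spatial Fit the purely spatial model and variograms?
#' @param tune Tune tolerances after the free search?
#' @return List of class `run_config`.
#' @export
run_config <- function(tracks, grids, out_dir,
                       study_polygon = NULL,
                       predictors = c("CHL", "SST", "DEPTH", "EASTNESS"),
                       detrend = "SST",
                       building_years = c(1998:2004, 2007:2008),
                       validation_years = 2005:2006,
                       filter = filter_config(study_polygon =
                         if (is.matrix(study_polygon)) study_polygon else
                           NULL),
                       npmr = npmr_control(),
                       depth_grid = "DEPTH", seed = 1L,
                       run_spatial = TRUE, tune = TRUE) {
  structure(list(tracks = tracks, grids = grids, out_dir = out_dir,
                 study_polygon = study_polygon, predictors = predictors,
                 detrend = detrend, building_years = building_years,
                 validation_years = validation_years, filter = filter,
                 npmr = npmr, depth_grid = depth_grid,
                 seed = as.integer(seed), run_spatial = run_spatial,
                 tune = tune), class = "run_config")
}

resolve_inputs <- function(config) {
  tracks <- config$tracks
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  grids <- config$grids
  if (is.character(grids)) {
    files <- list.files(grids, pattern = "\\.csv$", full.names = TRUE)
    grids <- lapply(files, read_env_grid)
    names(grids) <- vapply(grids, `[[`, "", "name")
  }
  poly <- config$study_polygon
  if (is.character(poly)) poly <- read_polygon_geojson(poly)
  list(tracks = tracks, grids = grids, polygon = poly)
}

#' Validate a run configuration
#'
#' Checks the configuration without running anything and returns every
#' violation found; an empty character vector means the pipeline can run.
#' Unreadable files are reported as violations, not raised.
#'
#' @param config A [run_config()].
#' @return Character vector of violations.
#' @export
validate_run_config <- function(config) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (is.character(config$tracks) && !file.exists(config$tracks)) {
    add(paste("track file not readable:", config$tracks))
  }
  if (is.character(config$grids) && !dir.exists(config$grids)) {
    add(paste("grid directory not readable:", config$grids))
  }
  inp <- tryCatch(suppressWarnings(resolve_inputs(config)),
                  error = function(e) NULL)
  if (is.null(inp)) {
    add("inputs could not be loaded")
    return(v)
  }
  missing_grids <- setdiff(unique(c(config$predictors, config$depth_grid)),
                           names(inp$grids))
  for (g in missing_grids) add(paste("predictor has no grid:", g))
  bad_detrend <- setdiff(config$detrend, config$predictors)
  for (g in bad_detrend) add(paste("detrend names a non-predictor:", g))
  fc <- config$filter
  for (th in c("min_days", "min_distance_km", "max_ci_radius_km",
               "max_depth_m")) {
    if (!is.null(fc[[th]]) && fc[[th]] <= 0) {
      add(paste("non-positive threshold:", th))
    }
  }
  if (!is.null(inp$tracks)) {
    yrs <- unique(as.integer(format(as.Date(inp$tracks$date), "%Y")))
    uncovered <- setdiff(yrs, c(config$building_years,
                                config$validation_years))
    if (length(uncovered)) {
      add(paste("years not covered by the regime map:",
                paste(uncovered, collapse = ", ")))
    }
  }
  v
}

fit_block <- function(fit) {
  list(predictors = c(fit$continuous, fit$categorical),
       tolerances = as.list(fit$tolerances),
       tolerance_pct = if (length(fit$tolerances)) {
         as.list(mapply(tolerance_pct, fit$tolerances, fit$ranges))
       } else list(),
       sensitivity = as.list(fit$sensitivity),
       SU = fit$SU, N_ave = fit$N_ave, n_min = fit$n_min,
       logB = fit$logB, B_ave = fit$B_ave, xR2 = fit$xR2, r = fit$r,
       chisq = fit$chisq)
}

report_block <- function(rep) {
  rep[c("cutoff", "tss", "tpr", "tnr", "fpr", "fnr", "observed_prevalence",
        "predicted_prevalence", "accuracy", "precision", "auc", "rmse",
        "brier", "n_excluded")]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: mode classification, track and location filters,
#' depth attachment, kernel-weighted environmental extraction, latitudinal
#' detrending, regime split into building/validation years, single-predictor
#' scoring and collinearity screen, free search (+ tuning) for the
#' environmental model, validation on the held-out regime, TSS-based
#' classification reports, and (optionally) the purely spatial model with
#' variogram diagnostics. Every intermediate artifact is written under
#' `config$out_dir`; a stage failure aborts with the stage name while
#' retaining the artifacts already written.
#'
#' @param config A [run_config()].
#' @return The run report (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  violations <- validate_run_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  inp <- stage("load", resolve_inputs(config))
  tracks <- inp$tracks
  tracks$date <- as.Date(tracks$date)
  note("load", n_locations = nrow(tracks),
       n_tracks = length(unique(tracks$whale_id)))

  # -- prep ----------------------------------------------------------------
  tracks$bmode_class <- stage("classify", classify_mode(tracks$bmode))
  fc <- config$filter
  if (!is.null(inp$polygon)) fc$study_polygon <- inp$polygon
  tf <- stage("filter_tracks", filter_tracks(tracks, fc))
  utils::write.csv(tf$log, file.path(out, "track_filter_log.csv"),
                   row.names = FALSE)
  tracks <- tf$tracks
  note("filter_tracks", input = nrow(tf$log), retained = sum(tf$log$retained))

  tracks$depth_m <- stage("depth", vapply(seq_len(nrow(tracks)), function(i) {
    kernel_weighted_extract(tracks[i, , drop = FALSE],
                            inp$grids[[config$depth_grid]])
  }, numeric(1)))
  fl <- stage("filter_locations", filter_locations(tracks, fc))
  jsonlite::write_json(fl$log, file.path(out, "location_filter_log.json"),
                       auto_unbox = TRUE, digits = NA)
  points <- fl$points
  note("filter_locations", input = fl$log$input, retained = fl$log$retained)
  if (!nrow(points)) stop("pipeline stage 'filter_locations' left no rows")
  write_tracks(points[setdiff(names(points), "bmode_class")],
               file.path(out, "filtered_tracks.csv"))

  # -- extract -------------------------------------------------------------
  points <- stage("extract",
                  extract_env(points, inp$grids[config$predictors]))
  for (nm in config$detrend) {
    points[[paste0("dt", nm)]] <- stage("detrend",
      detrend_latitude(points[[nm]], points$lat))
  }
  points$bmode_bin <- as.integer(points$bmode_class == "ARS")
  points$year <- as.integer(format(points$date, "%Y"))
  points$split <- ifelse(points$year %in% config$building_years, "building",
                  ifelse(points$year %in% config$validation_years,
                         "validation", NA))
  utils::write.csv(points, file.path(out, "sample_table.csv"),
                   row.names = FALSE)
  candidates <- c(config$predictors,
                  paste0("dt", config$detrend))
  building <- points[points$split %in% "building", ]
  validation <- points[points$split %in% "validation", ]
  note("split", building = nrow(building), validation = nrow(validation))

  # -- screen --------------------------------------------------------------
  cc <- stats::complete.cases(building[candidates])
  btab <- building[cc, ]
  single <- stage("screen_single", vapply(candidates, function(p) {
    cache <- search_cache(btab$bmode_bin, btab, p, character(), config$npmr)
    best <- -Inf
    for (fr in config$npmr$tolerance_grid) {
      eng <- eval_spec(cache, p, stats::setNames(fr * cache$ranges[[p]], p),
                       character())
      if (!is.null(eng) && eng$logB > best) best <- eng$logB
    }
    best
  }, numeric(1)))
  screen <- stage("screen", collinearity_screen(btab, candidates, single))
  jsonlite::write_json(
    list(single_predictor_logB = as.list(single),
         retained = screen$retained, dropped = screen$dropped,
         flagged_pairs = screen$flagged_pairs),
    file.path(out, "collinearity_screen.json"), auto_unbox = TRUE,
    digits = NA)
  note("screen", retained = length(screen$retained))

  # -- environmental model -------------------------------------------------
  search <- stage("search", npmr_search(
    stats::reformulate(screen$retained, response = "bmode_bin"),
    btab, control = config$npmr, tune = config$tune))
  env_fit <- search$fit
  jsonlite::write_json(
    list(by_size = lapply(Filter(Negate(is.null), search$by_size),
                          function(b) list(predictors = b$predictors,
                                           logB = b$logB, N_ave = b$N_ave)),
         final = fit_block(env_fit)),
    file.path(out, "search_result.json"), auto_unbox = TRUE, digits = NA)

  env_build_report <- stage("evaluate", classification_report(
    env_fit$y, env_fit$estimates))
  utils::write.csv(env_build_report$tss_curve,
                   file.path(out, "tss_curve_environmental_building.csv"),
                   row.names = FALSE)
  for (p in env_fit$continuous) {
    utils::write.csv(response_curve(env_fit, p),
                     file.path(out, paste0("response_curve_", p, ".csv")),
                     row.names = FALSE)
  }

  has_validation <- nrow(validation) > 0
  env_val <- NULL; env_val_report <- NULL
  if (has_validation) {
    env_val <- stage("validate", npmr_validate(env_fit, validation))
    env_val_report <- classification_report(env_val$y, env_val$estimates)
  }

  # -- spatial model and variograms ---------------------------------------
  spatial <- NULL
  if (isTRUE(config$run_spatial)) {
    sp_fit <- stage("spatial", npmr_spatial(btab, "bmode_bin",
                                            control = config$npmr,
                                            tune = config$tune))
    sp_report <- classification_report(sp_fit$y, sp_fit$estimates)
    sp_val <- NULL; sp_val_report <- NULL
    if (has_validation) {
      sp_val <- npmr_validate(sp_fit, validation)
      sp_val_report <- classification_report(sp_val$y, sp_val$estimates)
    }
    cmp <- stage("variogram", compare_npmr(sp_fit, env_fit,
                                           lon = sp_fit$frame$lon,
                                           lat = sp_fit$frame$lat))
    for (nm in names(cmp$variograms)) {
      utils::write.csv(as.data.frame(cmp$variograms[[nm]]),
                       file.path(out, paste0("variogram_", nm, ".csv")),
                       row.names = FALSE)
    }
    spatial <- list(fit = sp_fit, report = sp_report, validation = sp_val,
                    val_report = sp_val_report, comparison = cmp$summary,
                    anisotropy = sp_fit$anisotropy)
  }

  # -- summary -------------------------------------------------------------
  summary <- list(
    environmental = list(
      building = c(fit_block(env_fit),
                   list(classification = report_block(env_build_report))),
      validation = if (has_validation) {
        c(fit_block_validation(env_val),
          list(classification = report_block(env_val_report)))
      } else "absent"),
    spatial = if (is.null(spatial)) "absent" else list(
      building = c(fit_block(spatial$fit),
                   list(anisotropy = spatial$anisotropy,
                        classification = report_block(spatial$report))),
      validation = if (has_validation) {
        c(fit_block_validation(spatial$validation),
          list(classification = report_block(spatial$val_report)))
      } else "absent",
      comparison = spatial$comparison))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, manifest = manifest,
                 env_fit = env_fit, env_validation = env_val,
                 spatial = spatial, screen = screen, search = search,
                 points = points))
}

fit_block_validation <- function(v) {
  list(predictors = names(v$tolerances),
       tolerances = as.list(v$tolerances),
       tolerance_pct = if (length(v$tolerances)) {
         as.list(mapply(tolerance_pct, v$tolerances, v$ranges))
       } else list(),
       sensitivity = as.list(v$sensitivity),
       SU = v$SU, N_ave = v$N_ave, n_min = v$n_min, logB = v$logB,
       B_ave = v$B_ave, xR2 = v$xR2, r = v$r, chisq = v$chisq)
}

# Strip non-serializable members (functions, data) for the config echo.
serializable_config <- function(config) {
  list(
    tracks = if (is.character(config$tracks)) config$tracks else "<in-memory>",
    grids = if (is.character(config$grids)) config$grids else "<in-memory>",
    out_dir = config$out_dir,
    predictors = config$predictors, detrend = config$detrend,
    building_years = config$building_years,
    validation_years = config$validation_years,
    filter = config$filter[c("min_days", "min_distance_km",
                             "max_ci_radius_km", "max_depth_m", "months")],
    npmr = config$npmr[c("tolerance_grid", "n_min_fraction",
                         "nudge_fraction", "min_improve_fraction", "seed",
                         "n_boot", "n_rand")],
    seed = config$seed, run_spatial = config$run_spatial,
    tune = config$tune)
}

#' Bundled synthetic demo configuration
#'
#' Simulates a complete input set at the study's scale — 55 building-regime
#' and 18 validation-regime whales, four environmental grids (CHL and SST
#' time-resolved with one slice per year, regime-dependent), and a
#' rectangular study polygon — writes them under `dir`, and returns a
#' ready-to-run [run_config()].
#'
#' @param dir Directory for the simulated inputs and pipeline outputs.
#' @param seed Integer seed.
#' @param n_whales_building,n_whales_validation,days_per_whale Scale knobs.
#' @return A [run_config()].
#' @export
demo_run_config <- function(dir, seed = 1L, n_whales_building = 55,
                            n_whales_validation = 18, days_per_whale = 25) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_pos <- sim_config(n_whales = n_whales_building,
                        days_per_whale = days_per_whale, seed = seed,
                        regime = "positive")
  cfg_neg <- sim_config(n_whales = n_whales_validation,
                        days_per_whale = days_per_whale, seed = seed + 500L,
                        regime = "negative")
  fields_pos <- gen_env_fields(cfg_pos)
  fields_neg <- gen_env_fields(cfg_neg)
  tp <- gen_tracks(cfg_pos, fields_pos)
  tn <- gen_tracks(cfg_neg, fields_neg)
  tp$tracks$whale_id <- sub("^W", "P", tp$tracks$whale_id)
  tn$tracks$whale_id <- sub("^W", "N", tn$tracks$whale_id)
  tracks <- rbind(tp$tracks, tn$tracks)
  write_tracks(tracks, file.path(dir, "tracks.csv"))

  # CHL and SST vary by climatic regime: one time slice per study year,
  # cool-phase years carrying the positive-regime field
  years <- sort(c(cfg_pos$years, cfg_neg$years))
  slice_dates <- as.Date(sprintf("%d-09-01", years))
  grid_dir <- file.path(dir, "grids")
  dir.create(grid_dir, showWarnings = FALSE)
  timevary <- function(name) {
    pos <- fields_pos[[name]]; neg <- fields_neg[[name]]
    vals <- array(NA_real_, c(length(pos$lat), length(pos$lon),
                              length(years)))
    for (k in seq_along(years)) {
      vals[, , k] <- if (years[k] %in% cfg_pos$years) pos$values else
        neg$values
    }
    env_grid(name, pos$lon, pos$lat, vals, time = slice_dates)
  }
  grids <- list(CHL = timevary("CHL"), SST = timevary("SST"),
                DEPTH = fields_pos$DEPTH, EASTNESS = fields_pos$EASTNESS)
  for (nm in names(grids)) {
    write_env_grid(grids[[nm]], file.path(grid_dir, paste0(nm, ".csv")))
  }

  ex <- cfg_pos$grid_extent
  poly <- cbind(
    lon = c(ex[["lon_min"]], ex[["lon_max"]], ex[["lon_max"]],
            ex[["lon_min"]], ex[["lon_min"]]),
    lat = c(ex[["lat_min"]], ex[["lat_min"]], ex[["lat_max"]],
            ex[["lat_max"]], ex[["lat_min"]]))
  poly_path <- file.path(dir, "study_area.geojson")
  write_polygon_geojson(poly, poly_path)

  run_config(
    tracks = file.path(dir, "tracks.csv"), grids = grid_dir,
    out_dir = file.path(dir, "out"), study_polygon = poly_path,
    predictors = c("CHL", "SST", "DEPTH", "EASTNESS"), detrend = "SST",
    building_years = cfg_pos$years, validation_years = cfg_neg$years,
    npmr = npmr_control(seed = seed), seed = seed)
}
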