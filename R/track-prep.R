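# Post-processing of regularized (daily) state-space-modeled tracks:
# behavioral-mode classification, track- and location-level filters, and
# movement statistics.

#' Classify a continuous behavioral-mode value
#'
#' The state-space model emits a continuous mode value in \[1, 2\] per daily
#' location (1 = transiting, 2 = area-restricted search). Values above 1.75
#' are classified ARS, below 1.25 transiting; the band between (inclusive
#' of both boundaries) is uncertain.
#'
#' @param bmode Numeric vector in \[1, 2\].
#' @return Factor with levels `transiting`, `ARS`, `uncertain`.
#' @export
classify_mode <- function(bmode) {
  if (any(bmode < 1 | bmode > 2, na.rm = TRUE)) {
    stop("bmode outside [1, 2]")
  }
  out <- ifelse(bmode > 1.75, "ARS",
         ifelse(bmode < 1.25, "transiting", "uncertain"))
  factor(out, levels = c("transiting", "ARS", "uncertain"))
}

#' Filtering thresholds for tracks and locations
#'
#' Defaults follow the track-selection rules for the blue-whale data set:
#' tracks are kept when longer than 14 d or covering at least 888 km (the
#' typical transit time and separation between ARS patches); locations are
#' dropped when the 95% credible-limit half-width exceeds 100 km, the
#' behavioral mode is uncertain, the location is the terminal point of its
#' track, seafloor depth exceeds 2000 m, the month falls outside July to
#' November, or the point lies outside the study polygon.
#'
#' @param min_days Minimum track duration (days, exclusive).
#' @param min_distance_km Minimum cumulative track length (km, inclusive).
#' @param max_ci_radius_km Maximum credible-limit half-width (km).
#' @param max_depth_m Maximum seafloor depth (m).
#' @param months Integer months retained.
#' @param study_polygon Optional two-column lon/lat matrix (closed ring) or
#'   `NULL` to skip the containment rule.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_days = 14, min_distance_km = 888,
                          max_ci_radius_km = 100, max_depth_m = 2000,
                          months = 7:11, study_polygon = NULL) {
  stopifnot(min_days > 0, min_distance_km > 0, max_ci_radius_km > 0,
            max_depth_m > 0)
  structure(list(min_days = min_days, min_distance_km = min_distance_km,
                 max_ci_radius_km = max_ci_radius_km,
                 max_depth_m = max_depth_m, months = months,
                 study_polygon = study_polygon),
            class = "filter_config")
}

track_path_km <- function(track) {
  if (nrow(track) < 2) return(0)
  o <- order(track$date)
  lon <- track$lon[o]; lat <- track$lat[o]
  sum(great_circle_km(lon[-length(lon)], lat[-length(lat)],
                      lon[-1], lat[-1]))
}

#' Track-level filter
#'
#' Retains a track iff its duration exceeds `min_days` *or* its cumulative
#' great-circle path length reaches `min_distance_km` (a disjunction: short
#' tracks that cover enough ground are informative, as are long slow ones).
#'
#' @param tracks Data.frame of daily locations with `whale_id`, `date`,
#'   `lon`, `lat`.
#' @param cfg A [filter_config()].
#' @return List with `tracks` (retained rows) and `log` (one row per input
#'   track: id, duration, distance, retained, reason).
#' @export
filter_tracks <- function(tracks, cfg = filter_config()) {
  if (!nrow(tracks)) stop("empty track table")
  tracks$date <- as.Date(tracks$date)
  ids <- unique(tracks$whale_id)
  log <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$whale_id == id, ]
    dur <- as.numeric(max(tr$date) - min(tr$date))
    dist <- track_path_km(tr)
    keep <- dur > cfg$min_days || dist >= cfg$min_distance_km
    data.frame(whale_id = id, duration_days = dur, distance_km = dist,
               retained = keep,
               reason = if (keep) "" else "duration-and-distance")
  }))
  list(tracks = tracks[tracks$whale_id %in% log$whale_id[log$retained], ],
       log = log)
}

# Credible-limit half-width in km: the larger of the two axis half-widths,
# degrees converted at the point's latitude.
ci_halfwidth_km <- function(track) {
  hw_lon <- (track$ci_lon_hi - track$ci_lon_lo) / 2 *
    KM_PER_DEG * cos(track$lat * pi / 180)
  hw_lat <- (track$ci_lat_hi - track$ci_lat_lo) / 2 * KM_PER_DEG
  pmax(hw_lon, hw_lat)
}

#' Location-level filter
#'
#' Applies, in a fixed order so removal logs are comparable across runs:
#' month window, study-polygon containment, credible-limit size, uncertain
#' behavioral mode, terminal location of each track, and depth. Each removed
#' location is attributed to the first rule that rejects it.
#'
#' @param track Data.frame of daily locations; needs `bmode_class`
#'   (see [classify_mode()]) and, for the depth rule, a `depth_m` column
#'   (rows with missing depth are not removed by that rule).
#' @param cfg A [filter_config()].
#' @return List with `points` (retained rows) and `log` (named removal
#'   counts per rule, plus `input`, `retained`).
#' @export
filter_locations <- function(track, cfg = filter_config()) {
  n_in <- nrow(track)
  if (n_in) track$date <- as.Date(track$date)
  counts <- c(month = 0L, polygon = 0L, uncertainty = 0L, uncertain_mode = 0L,
              terminal = 0L, depth = 0L)
  drop_rule <- function(track, keep, rule) {
    keep[is.na(keep)] <- TRUE
    counts[rule] <<- counts[rule] + sum(!keep)
    track[keep, , drop = FALSE]
  }
  if (n_in) {
    track <- drop_rule(track,
      as.integer(format(track$date, "%m")) %in% cfg$months, "month")
  }
  if (nrow(track) && !is.null(cfg$study_polygon)) {
    track <- drop_rule(track,
      point_in_polygon(track$lon, track$lat, cfg$study_polygon), "polygon")
  }
  if (nrow(track)) {
    track <- drop_rule(track,
      ci_halfwidth_km(track) <= cfg$max_ci_radius_km, "uncertainty")
  }
  if (nrow(track)) {
    track <- drop_rule(track, track$bmode_class != "uncertain",
                       "uncertain_mode")
  }
  if (nrow(track)) {
    # flagged once from the incoming track and persisted, so re-filtering
    # an already-filtered table does not strip a new "last" point
    if (!"is_terminal" %in% names(track)) {
      track$is_terminal <- stats::ave(as.numeric(track$date),
                                      track$whale_id,
                                      FUN = max) == as.numeric(track$date)
    }
    track <- drop_rule(track, !track$is_terminal, "terminal")
  }
  if (nrow(track) && "depth_m" %in% names(track)) {
    track <- drop_rule(track, track$depth_m <= cfg$max_depth_m, "depth")
  }
  list(points = track,
       log = c(as.list(counts), input = n_in, retained = nrow(track)))
}

#' Daily movement statistics by behavioral mode
#'
#' Displacement between consecutive daily locations and the implied speed
#' (displacement / 24 h), grouped by the behavioral mode of the earlier
#' location of each pair, plus an overall row. Pairs are only formed from
#' locations exactly one day apart within the same track.
#'
#' @param points Data.frame with `whale_id`, `date`, `lon`, `lat` and
#'   (optionally) `bmode_class`.
#' @return Data.frame with columns `mode`, `n_pairs`, `mean_km`,
#'   `median_km`, `mean_kmh`, `median_kmh`.
#' @export
movement_stats <- function(points) {
  points$date <- as.Date(points$date)
  pieces <- lapply(split(points, points$whale_id), function(tr) {
    if (nrow(tr) < 2) return(NULL)
    tr <- tr[order(tr$date), ]
    i <- which(diff(as.numeric(tr$date)) == 1)
    if (!length(i)) return(NULL)
    data.frame(
      mode = if ("bmode_class" %in% names(tr)) {
        as.character(tr$bmode_class[i])
      } else "all",
      km = great_circle_km(tr$lon[i], tr$lat[i], tr$lon[i + 1], tr$lat[i + 1])
    )
  })
  pairs <- do.call(rbind, pieces)
  if (is.null(pairs) || !nrow(pairs)) stop("no consecutive daily pairs")
  one <- function(d, label) {
    data.frame(mode = label, n_pairs = nrow(d),
               mean_km = mean(d$km), median_km = stats::median(d$km),
               mean_kmh = mean(d$km) / 24,
               median_kmh = stats::median(d$km) / 24)
  }
  out <- do.call(rbind, lapply(split(pairs, pairs$mode),
                               function(d) one(d, d$mode[1])))
  out <- rbind(out, one(pairs, "overall"))
  rownames(out) <- NULL
  out
}
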