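# Two-state correlated-random-walk track simulator with an environmental
# behavioral switch and known ground truth.

# Nearest-cell field value at a point, preferring the cloud-free copy when
# the grid carries one.
field_value_at <- function(grid, lon, lat, complete = TRUE) {
  vals <- if (complete && !is.null(grid$complete)) grid$complete else
    grid$values
  i <- which.min(abs(grid$lat - lat))
  j <- which.min(abs(grid$lon - lon))
  vals[i, j]
}

#' Simulate satellite-tracked whale tracks
#'
#' Discrete-time two-state correlated random walk with daily steps:
#' transiting draws long gamma-distributed steps (configured mean) with
#' near-persistent headings; area-restricted search (ARS) draws short steps
#' with near-uniform turning. Each day's probability of being in ARS is the
#' configured `switch_link` evaluated on the local field values, blended
#' with a persistence term. Every location carries a continuous
#' behavioral-mode value (`bmode`): the true state (1 = transiting,
#' 2 = ARS) plus bounded noise, except for 10% of locations drawn inside
#' the uncertain band (1.25, 1.75), so thresholding recovers the true state
#' on all non-uncertain locations. A rectangular 95% credible-limit box is
#' attached per location with half-widths drawn from
#' `config$ci_halfwidth_dist`.
#'
#' @param config A [sim_config()].
#' @param fields Named list of [env_grid()]s from [gen_env_fields()];
#'   must contain every predictor the `switch_link` reads.
#' @return List with `tracks` (data.frame: `whale_id`, `date`, `lon`,
#'   `lat`, `ci_lon_lo/hi`, `ci_lat_lo/hi`, `bmode`) and `truth`
#'   (data.frame of true per-location state and ARS probability, plus the
#'   generating link and field correlation range as attributes).
#' @export
gen_tracks <- function(config, fields) {
  probe <- tryCatch({
    env0 <- lapply(fields, field_value_at,
                   lon = mean(config$grid_extent[c("lon_min", "lon_max")]),
                   lat = mean(config$grid_extent[c("lat_min", "lat_max")]))
    config$switch_link(env0)
    NULL
  }, error = function(e) e)
  if (!is.null(probe)) {
    stop("switch_link failed on the supplied fields: ",
         conditionMessage(probe))
  }
  set.seed(config$seed + 1L)
  ex <- config$grid_extent
  step_mean <- c(transit = config$step_mean_transit,
                 ars = config$step_mean_ars)
  rows <- vector("list", config$n_whales)
  truth_rows <- vector("list", config$n_whales)
  for (w in seq_len(config$n_whales)) {
    year <- if (length(config$years) == 1) config$years else
      sample(config$years, 1)
    start <- as.Date(sprintf("%d-07-01", year)) +
      sample.int(100, 1) - 1  # Jul-Oct starts keep tracks in season
    lon <- stats::runif(1, ex[["lon_min"]] + 1, ex[["lon_max"]] - 1)
    lat <- stats::runif(1, ex[["lat_min"]] + 1, ex[["lat_max"]] - 1)
    heading <- stats::runif(1, -pi, pi)
    env <- lapply(fields, field_value_at, lon = lon, lat = lat)
    state <- stats::rbinom(1, 1, config$switch_link(env))  # 1 = ARS
    nd <- config$days_per_whale
    out <- data.frame(
      whale_id = sprintf("W%03d", w), date = start + seq_len(nd) - 1,
      lon = NA_real_, lat = NA_real_, ci_lon_lo = NA_real_,
      ci_lon_hi = NA_real_, ci_lat_lo = NA_real_, ci_lat_hi = NA_real_,
      bmode = NA_real_)
    tru <- data.frame(whale_id = out$whale_id, date = out$date,
                      state = NA_integer_, p_ars = NA_real_)
    for (t in seq_len(nd)) {
      out$lon[t] <- lon; out$lat[t] <- lat
      hw_lon <- config$ci_halfwidth_dist(1) /
        (KM_PER_DEG * cos(lat * pi / 180))
      hw_lat <- config$ci_halfwidth_dist(1) / KM_PER_DEG
      out$ci_lon_lo[t] <- lon - hw_lon; out$ci_lon_hi[t] <- lon + hw_lon
      out$ci_lat_lo[t] <- lat - hw_lat; out$ci_lat_hi[t] <- lat + hw_lat
      u <- stats::runif(1)
      out$bmode[t] <- if (u < 0.1) {
        stats::runif(1, 1.25, 1.75)  # exercises the uncertain filter
      } else if (state == 1) {
        2 - abs(stats::runif(1, -0.2, 0.2))
      } else {
        1 + abs(stats::runif(1, -0.2, 0.2))
      }
      env <- lapply(fields, field_value_at, lon = lon, lat = lat)
      p_link <- config$switch_link(env)
      tru$state[t] <- state
      tru$p_ars[t] <- p_link
      # move according to the current state
      step <- stats::rgamma(1, shape = config$step_shape,
                            scale = step_mean[[state + 1]] /
                              config$step_shape)
      heading <- if (state == 1) {
        stats::runif(1, -pi, pi)  # tortuous ARS turning
      } else {
        heading + stats::rnorm(1, 0, config$heading_sd_transit)
      }
      lat_new <- lat + step * cos(heading) / KM_PER_DEG
      lon_new <- lon + step * sin(heading) /
        (KM_PER_DEG * cos(lat * pi / 180))
      if (lon_new < ex[["lon_min"]] || lon_new > ex[["lon_max"]] ||
          lat_new < ex[["lat_min"]] || lat_new > ex[["lat_max"]]) {
        heading <- heading + pi  # bounce off the domain edge
        lat_new <- min(max(lat_new, ex[["lat_min"]]), ex[["lat_max"]])
        lon_new <- min(max(lon_new, ex[["lon_min"]]), ex[["lon_max"]])
      }
      lon <- lon_new; lat <- lat_new
      # next day's state: environmental link blended with persistence
      p_eff <- (1 - config$persistence) * p_link +
        config$persistence * state
      state <- stats::rbinom(1, 1, p_eff)
    }
    rows[[w]] <- out
    truth_rows[[w]] <- tru
  }
  tracks <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  attr(truth, "switch_link") <- config$switch_link
  attr(truth, "grf_range_km") <- config$grf_range_km
  list(tracks = tracks, truth = truth)
}

#' Write / read a track table as CSV
#'
#' Columns: `whale_id`, `date` (ISO-8601), `lon`, `lat`, `ci_lon_lo`,
#' `ci_lon_hi`, `ci_lat_lo`, `ci_lat_hi`, `bmode`.
#'
#' @param tracks Track data.frame.
#' @param path File path.
#' @return `read_tracks` returns the data.frame with `date` parsed.
#' @export
write_tracks <- function(tracks, path) {
  tracks$date <- format(as.Date(tracks$date))
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  df$date <- as.Date(df$date)
  df
}
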