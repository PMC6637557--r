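# EnvGrid: a named regular lon/lat raster, optionally time-resolved.
#
# Values are stored as an array indexed [lat, lon] (static) or
# [lat, lon, time]. Missing cells (cloud cover) are NA.

#' Construct an environmental grid
#'
#' @param name Predictor label, e.g. `"CHL"`, `"SST"`, `"DEPTH"`, `"EASTNESS"`.
#' @param lon,lat Strictly monotone, regularly spaced axis coordinates
#'   (degrees, cell centers).
#' @param values Matrix `[lat, lon]` or array `[lat, lon, time]`; `NA` allowed.
#' @param time Optional vector of `Date`s, one per time slice.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(name, lon, lat, values, time = NULL) {
  check_axis <- function(ax, label) {
    if (length(ax) < 2) stop(label, " axis needs >= 2 coordinates")
    d <- diff(ax)
    if (any(d <= 0)) stop(label, " axis must be strictly increasing")
    if (diff(range(d)) > 1e-9) stop(label, " axis spacing not constant")
    d[1]
  }
  dlon <- check_axis(lon, "lon")
  dlat <- check_axis(lat, "lat")
  values <- if (is.null(time)) as.matrix(values) else as.array(values)
  expected <- c(length(lat), length(lon), if (!is.null(time)) length(time))
  if (!identical(dim(values), as.integer(expected))) {
    stop("values dimensions ", paste(dim(values), collapse = "x"),
         " do not match axes ", paste(expected, collapse = "x"))
  }
  structure(list(name = name, lon = lon, lat = lat, time = time,
                 values = values, res = c(lon = dlon, lat = dlat)),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat("Environmental grid '", x$name, "': ",
      length(x$lat), " x ", length(x$lon), " cells at ",
      signif(x$res[["lon"]], 4), " deg",
      if (!is.null(x$time)) paste0(", ", length(x$time), " time slices"),
      "; ", round(100 * mean(is.na(x$values)), 1), "% missing\n", sep = "")
  invisible(x)
}

is_time_resolved <- function(grid) !is.null(grid$time)

# Native temporal resolution (days); used as the tolerance for time matching.
grid_time_step <- function(grid) {
  if (!is_time_resolved(grid) || length(grid$time) < 2) return(Inf)
  stats::median(as.numeric(diff(grid$time)))
}

# Slice of the values array nearest in time to `date`; NULL if nothing lies
# within one native time step.
nearest_slice <- function(grid, date) {
  if (!is_time_resolved(grid)) return(grid$values)
  if (is.null(date) || is.na(date)) return(NULL)
  dt <- abs(as.numeric(grid$time - as.Date(date)))
  i <- which.min(dt)
  if (dt[i] > grid_time_step(grid)) return(NULL)
  grid$values[, , i]
}

#' Write / read an environmental grid as plain text
#'
#' Grids are serialized as CSV with a commented header describing the axes
#' (a simple CF-like text container: regular lon/lat axes, optional time).
#' Rows are in long format `time?,lat,lon,value`; missing cells are kept so
#' the grid round-trips exactly.
#'
#' @param grid An [env_grid()].
#' @param path File path.
#' @return `read_env_grid` returns an `env_grid`; `write_env_grid` its path,
#'   invisibly.
#' @export
write_env_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# env_grid name=", grid$name),
    paste0("# lon_start=", format(grid$lon[1], digits = 15),
           " lon_step=", format(grid$res[["lon"]], digits = 15),
           " lon_n=", length(grid$lon)),
    paste0("# lat_start=", format(grid$lat[1], digits = 15),
           " lat_step=", format(grid$res[["lat"]], digits = 15),
           " lat_n=", length(grid$lat)),
    if (is_time_resolved(grid)) {
      paste0("# time=", paste(format(grid$time), collapse = ","))
    }
  ), con)
  df <- grid_to_df(grid)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

grid_to_df <- function(grid) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (is_time_resolved(grid)) {
    nt <- length(grid$time)
    data.frame(
      time = rep(format(grid$time), each = nlat * nlon),
      lat = rep(rep(grid$lat, nlon), nt),
      lon = rep(rep(grid$lon, each = nlat), nt),
      value = as.vector(grid$values)
    )
  } else {
    data.frame(lat = rep(grid$lat, nlon),
               lon = rep(grid$lon, each = nlat),
               value = as.vector(grid$values))
  }
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    line <- hdr[grepl(paste0(key, "="), hdr, fixed = TRUE)][1]
    sub(paste0(".*", key, "=([^ ]+).*"), "\\1", line)
  }
  name <- get("name")
  lon <- as.numeric(get("lon_start")) +
    as.numeric(get("lon_step")) * (seq_len(as.integer(get("lon_n"))) - 1)
  lat <- as.numeric(get("lat_start")) +
    as.numeric(get("lat_step")) * (seq_len(as.integer(get("lat_n"))) - 1)
  time <- NULL
  tline <- hdr[grepl("time=", hdr, fixed = TRUE)]
  if (length(tline)) {
    time <- as.Date(strsplit(sub(".*time=", "", tline[1]), ",")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  dims <- c(length(lat), length(lon), if (!is.null(time)) length(time))
  env_grid(name, lon, lat, array(df$value, dim = dims), time = time)
}

#' Kernel-weighted extraction of a gridded value at a track location
#'
#' Averages grid cells whose centers fall inside the location's 95%
#' credible-limit box, weighted by a smooth taper of great-circle distance
#' from the estimated location: `w(d) = (1 - (d/d_max)^2)^2`, where `d_max`
#' is the distance from the location to the farthest box corner, so weights
#' fall from 1 at the location to 0 at the box edge. This propagates the
#' state-space location uncertainty into the environmental values and makes
#' extraction robust to cloud-masked cells.
#'
#' For time-resolved grids the slice nearest the location's date is used;
#' if no slice lies within one native time step, the value is missing.
#'
#' @param point A one-row data.frame (or list) with `lon`, `lat`,
#'   `ci_lon_lo`, `ci_lon_hi`, `ci_lat_lo`, `ci_lat_hi`, and `date` (only
#'   needed for time-resolved grids).
#' @param grid An [env_grid()].
#' @param kernel Optional alternative taper `function(u)` of `u = d/d_max`
#'   on `[0, 1]`; defaults to the quartic bump `(1 - u^2)^2`.
#' @return The weighted mean over non-missing in-box cells, or `NA` if no
#'   non-missing cell center lies inside the box.
#' @export
kernel_weighted_extract <- function(point, grid, kernel = NULL) {
  kernel <- kernel %||% function(u) (1 - u^2)^2
  vals <- nearest_slice(grid, point$date %||% NA)
  if (is.null(vals)) return(NA_real_)
  lon_lo <- point$ci_lon_lo; lon_hi <- point$ci_lon_hi
  lat_lo <- point$ci_lat_lo; lat_hi <- point$ci_lat_hi
  # cell-center membership, half-open on the east/north edges
  ilon <- which(grid$lon >= lon_lo &
                (grid$lon < lon_hi | (lon_lo == lon_hi & grid$lon == lon_hi)))
  ilat <- which(grid$lat >= lat_lo &
                (grid$lat < lat_hi | (lat_lo == lat_hi & grid$lat == lat_hi)))
  if (!length(ilon) || !length(ilat)) return(NA_real_)
  z <- vals[ilat, ilon, drop = FALSE]
  ok <- !is.na(z)
  if (!any(ok)) return(NA_real_)
  cell_lon <- rep(grid$lon[ilon], each = length(ilat))
  cell_lat <- rep(grid$lat[ilat], length(ilon))
  d <- great_circle_km(point$lon, point$lat, cell_lon, cell_lat)
  corners <- expand.grid(lon = c(lon_lo, lon_hi), lat = c(lat_lo, lat_hi))
  d_max <- max(great_circle_km(point$lon, point$lat, corners$lon, corners$lat))
  w <- if (d_max <= 0) rep(1, length(d)) else kernel(pmin(d / d_max, 1))
  w <- as.vector(w)[ok]; z <- z[ok]
  if (sum(w) <= 0) return(mean(z))
  sum(w * z) / sum(w)
}

#' Attach environmental predictors to track locations
#'
#' Runs [kernel_weighted_extract()] for every location against every grid
#' and returns the track table with one new column per predictor.
#'
#' @param track Data.frame of track locations (see
#'   [kernel_weighted_extract()] for required columns).
#' @param grids List of [env_grid()] objects; names default to each grid's
#'   own `name`.
#' @param kernel Passed through to [kernel_weighted_extract()].
#' @return `track` with one extracted column per grid.
#' @export
extract_env <- function(track, grids, kernel = NULL) {
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    names(grids) <- vapply(grids, `[[`, "", "name")
  }
  for (nm in names(grids)) {
    g <- grids[[nm]]
    track[[nm]] <- vapply(seq_len(nrow(track)), function(i) {
      kernel_weighted_extract(track[i, , drop = FALSE], g, kernel = kernel)
    }, numeric(1))
  }
  track
}

#' Latitudinal loess detrending
#'
#' Removes the large-scale north--south gradient from an oceanographic
#' variable by fitting a locally linear loess smoother on latitude
#' (degree 1, span 0.75) and returning the residual "spatial anomaly".
#'
#' @param values Numeric vector (missing allowed).
#' @param lats Latitudes (degrees), same length.
#' @param degree,span Loess parameters.
#' @return Vector of anomalies; `NA` where `values` is `NA`.
#' @export
detrend_latitude <- function(values, lats, degree = 1, span = 0.75) {
  ok <- !is.na(values) & !is.na(lats)
  if (!any(ok)) stop("all values missing")
  if (sum(ok) < 10) stop("need >= 10 non-missing value/latitude pairs")
  out <- rep(NA_real_, length(values))
  df <- data.frame(v = values[ok], lat = lats[ok])
  fit <- stats::loess(v ~ lat, data = df, degree = degree, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out[ok] <- df$v - stats::predict(fit, newdata = df)
  out
}

#' Collinearity screen for candidate predictors
#'
#' Computes pairwise Pearson correlations on pairwise-complete rows and
#' iteratively drops, from each pair with `|r| >=` the threshold, the member
#' with the lower single-predictor model score (logB), until no flagged
#' pair remains. Zero-variance predictors are flagged degenerate and
#' dropped first.
#'
#' @param table Data.frame holding the candidate predictor columns.
#' @param predictors Character vector of column names to screen.
#' @param single_scores Named numeric vector: single-predictor logB per
#'   candidate (used to pick which member of a redundant pair survives).
#' @param threshold Absolute correlation at or above which a pair is
#'   redundant (default 0.7).
#' @return List with `retained` (character), `dropped` (character),
#'   `flagged_pairs` (data.frame of pair, r, dropped member).
#' @export
collinearity_screen <- function(table, predictors, single_scores,
                                threshold = 0.7) {
  stopifnot(all(predictors %in% names(table)),
            all(predictors %in% names(single_scores)))
  retained <- predictors
  flagged <- data.frame(pred1 = character(), pred2 = character(),
                        r = numeric(), dropped = character())
  degen <- retained[vapply(retained, function(p) {
    v <- table[[p]]; length(unique(v[!is.na(v)])) < 2
  }, logical(1))]
  retained <- setdiff(retained, degen)
  repeat {
    if (length(retained) < 2) break
    cm <- suppressWarnings(
      stats::cor(table[retained], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (all(abs(cm) < threshold, na.rm = TRUE)) break
    worst <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)[1, ]
    p1 <- retained[worst[1]]; p2 <- retained[worst[2]]
    drop <- if (single_scores[[p1]] < single_scores[[p2]]) p1 else p2
    flagged <- rbind(flagged, data.frame(
      pred1 = p1, pred2 = p2, r = cm[worst[1], worst[2]], dropped = drop))
    retained <- setdiff(retained, drop)
  }
  list(retained = retained,
       dropped = c(degen, flagged$dropped),
       degenerate = degen,
       flagged_pairs = flagged)
}
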