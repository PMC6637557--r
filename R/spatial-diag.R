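# Spatial autocorrelation diagnostics: a purely spatial NPMR model
# (longitude x latitude), classical sample variograms of neighborhood
# sizes and predictions, and a spatial-vs-environmental comparison.

#' Fit the purely spatial NPMR model
#'
#' Fits an NPMR model with longitude and latitude as the only (forced)
#' predictors, scanning the tolerance grid jointly over both axes and then
#' tuning. The ratio of the axis tolerances (as percent of range) measures
#' the anisotropy of the spatial structure in the tracking data.
#'
#' @param data Data.frame with the response and `lon`, `lat` columns.
#' @param response Name of the binary response column.
#' @param control An [npmr_control()].
#' @param tune Refine tolerances with [npmr_tune()]?
#' @return An [npmr()] fit with an extra `anisotropy` element
#'   (`tolerance_pct(lon) / tolerance_pct(lat)`).
#' @export
npmr_spatial <- function(data, response = "bmode_bin",
                         control = npmr_control(), tune = TRUE) {
  stopifnot(all(c("lon", "lat", response) %in% names(data)))
  tm <- parse_npmr_terms(stats::reformulate(c("lon", "lat"), response), data)
  cache <- search_cache(tm$y, tm$frame, c("lon", "lat"), character(),
                        control)
  grid <- rev(control$tolerance_grid)
  best <- NULL
  for (fl in grid) {
    for (ft in grid) {
      sg <- c(lon = fl * cache$ranges[["lon"]],
              lat = ft * cache$ranges[["lat"]])
      eng <- eval_spec(cache, c("lon", "lat"), sg, character())
      if (!is.null(eng) && (is.null(best) || eng$logB > best$logB)) {
        best <- list(sigmas = sg, logB = eng$logB)
      }
    }
  }
  if (is.null(best)) stop("no populated spatial model")
  fit <- npmr(stats::reformulate(c("lon", "lat"), response), tm$frame,
              tolerances = best$sigmas, control = control)
  if (tune) fit <- npmr_tune(fit)
  fit$anisotropy <- tolerance_pct(fit$tolerances[["lon"]],
                                  fit$ranges[["lon"]]) /
    tolerance_pct(fit$tolerances[["lat"]], fit$ranges[["lat"]])
  fit
}

#' Empirical (sample) variogram
#'
#' Classical Matheron estimator
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over point pairs whose
#' great-circle separation falls in each distance bin; pairs beyond
#' `max_lag_km` are ignored.
#'
#' @param lon,lat Coordinates (degrees).
#' @param values Variable to examine (e.g. neighborhood sizes or model
#'   predictions); missing values excluded.
#' @param bin_width_km,max_lag_km Lag binning (km).
#' @return Data.frame of class `variogram`: `lag` (bin center, km),
#'   `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(lon, lat, values, bin_width_km = 20,
                                max_lag_km = 500) {
  ok <- !is.na(values) & !is.na(lon) & !is.na(lat)
  if (sum(ok) < 2) stop("need >= 2 points with non-missing values")
  lon <- lon[ok]; lat <- lat[ok]; z <- values[ok]
  D <- great_circle_matrix_km(lon, lat)
  iu <- upper.tri(D)
  d <- D[iu]
  dz2 <- (outer(z, z, "-")^2)[iu]
  keep <- d <= max_lag_km
  d <- d[keep]; dz2 <- dz2[keep]
  bin <- pmin(floor(d / bin_width_km), ceiling(max_lag_km / bin_width_km) - 1)
  centers <- (sort(unique(bin)) + 0.5) * bin_width_km
  agg_n <- tapply(dz2, bin, length)
  agg_s <- tapply(dz2, bin, sum)
  out <- data.frame(lag = centers, gamma = as.numeric(agg_s / (2 * agg_n)),
                    n_pairs = as.integer(agg_n))
  attr(out, "bin_width_km") <- bin_width_km
  attr(out, "max_lag_km") <- max_lag_km
  class(out) <- c("variogram", "data.frame")
  out
}

#' @export
plot.variogram <- function(x, ...) {
  graphics::plot(x$lag, x$gamma, type = "b", xlab = "lag (km)",
                 ylab = expression(gamma(h)), ...)
  invisible(x)
}

# First lag at which the semivariance reaches `frac` of the sill; the sill
# defaults to the mean gamma over the top half of the lags, or can be given
# (e.g. the sample variance of a stationary field). NA when never reached.
variogram_range <- function(vg, frac = 0.95, sill = NULL) {
  sill <- sill %||% mean(vg$gamma[vg$lag >= stats::median(vg$lag)])
  i <- which(vg$gamma >= frac * sill)[1]
  if (is.na(i)) NA_real_ else vg$lag[i]
}

#' Compare spatial and environmental NPMR fits row by row
#'
#' Matched-row differences of neighborhood size and estimates between the
#' purely spatial and the environmental model, plus variograms of each
#' model's neighborhood sizes and predictions — the diagnostic for how much
#' spatial autocorrelation the environmental predictors absorb.
#'
#' @param spatial_fit,env_fit [npmr()] fits computed on the same rows.
#' @param lon,lat Row coordinates (taken from the spatial fit's frame when
#'   omitted).
#' @param ... Binning arguments passed to [empirical_variogram()].
#' @return List with `per_row` (data.frame of `d_nstar`, `d_estimate`),
#'   `summary` (counts and mean absolute differences), and `variograms`
#'   (list of four `variogram` objects).
#' @export
compare_npmr <- function(spatial_fit, env_fit, lon = NULL, lat = NULL, ...) {
  n <- length(spatial_fit$y)
  if (n != length(env_fit$y)) stop("fits computed on different row sets")
  lon <- lon %||% spatial_fit$frame$lon
  lat <- lat %||% spatial_fit$frame$lat
  both <- !is.na(spatial_fit$estimates) & !is.na(env_fit$estimates)
  per_row <- data.frame(
    d_nstar = spatial_fit$nstar - env_fit$nstar,
    d_estimate = spatial_fit$estimates - env_fit$estimates)
  vg <- list(
    nstar_spatial = empirical_variogram(lon, lat, spatial_fit$nstar, ...),
    nstar_env = empirical_variogram(lon, lat, env_fit$nstar, ...),
    est_spatial = empirical_variogram(lon, lat, spatial_fit$estimates, ...),
    est_env = empirical_variogram(lon, lat, env_fit$estimates, ...))
  list(per_row = per_row,
       summary = list(n = n, n_compared = sum(both),
                      n_excluded = sum(!both),
                      mean_abs_d_nstar = mean(abs(per_row$d_nstar[both])),
                      mean_abs_d_estimate =
                        mean(abs(per_row$d_estimate[both]))),
       variograms = vg)
}
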