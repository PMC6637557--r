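# Simulation configuration for synthetic tracks and environmental fields.

#' Configuration for the track-and-field simulator
#'
#' Defaults reproduce the scale of the blue-whale study conditions: 72
#' tagged whales with ~25 daily locations each (~1800 locations), mean
#' daily displacement 81.5 km when transiting and 27.3 km during
#' area-restricted search, a 12 x 19 degree coastal study extent, and a
#' "regime" switch distinguishing cool/productive (positive NPGO phase)
#' years from warm/low-productivity (negative phase) years.
#'
#' @param n_whales Number of simulated individuals.
#' @param days_per_whale Daily locations per track.
#' @param seed Integer seed; identical configs + seed give byte-identical
#'   output.
#' @param step_mean_transit,step_mean_ars Mean daily displacement (km) in
#'   each behavioral state.
#' @param switch_link Function mapping a named list of local predictor
#'   values to the per-day probability of ARS; the default is a saturating
#'   logistic response to chlorophyll (more ARS in productive water).
#' @param regime `"positive"` (cool, productive) or `"negative"` (warm):
#'   the negative regime warms the SST field, thins chlorophyll, and stamps
#'   track dates into the validation years.
#' @param grid_extent Named vector `lon_min, lon_max, lat_min, lat_max`
#'   (degrees).
#' @param grid_resolution Grid cell size (degrees).
#' @param ci_halfwidth_dist Function of `n` drawing credible-limit
#'   half-widths in km (lognormal by default, median 30 km).
#' @param grf_range_km Practical correlation range of the simulated
#'   chlorophyll / temperature anomaly fields (distance at which the
#'   semivariance reaches 95% of the sill).
#' @param grf_sd Standard deviation of the anomaly fields.
#' @param missing_frac Fraction of satellite-product cells masked as
#'   missing (cloud cover); static fields are complete.
#' @param sst_lat_slope Deterministic SST trend in degC per degree
#'   latitude (negative: cooler north).
#' @param persistence Behavioral-state stickiness in \[0, 1); the realized
#'   per-day ARS probability is
#'   `(1 - persistence) * switch_link(env) + persistence * (state == ARS)`.
#' @param step_shape Gamma shape of daily step lengths.
#' @param heading_sd_transit Heading-change SD (radians) while transiting
#'   (near-persistent); ARS turning is near-uniform.
#' @param years Calendar years tracks are stamped into; defaults to the
#'   cool-phase building years for `regime = "positive"` and the two warm
#'   validation years for `"negative"`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_whales = 72, days_per_whale = 25, seed = 1L,
                       step_mean_transit = 81.5, step_mean_ars = 27.3,
                       switch_link = NULL,
                       regime = c("positive", "negative"),
                       grid_extent = c(lon_min = -129, lon_max = -117,
                                       lat_min = 30, lat_max = 49),
                       grid_resolution = 0.25,
                       ci_halfwidth_dist = function(n)
                         stats::rlnorm(n, log(30), 0.6),
                       grf_range_km = 150, grf_sd = 0.5,
                       missing_frac = 0.15, sst_lat_slope = -0.45,
                       persistence = 0.25, step_shape = 4,
                       heading_sd_transit = 0.3,
                       years = NULL) {
  regime <- match.arg(regime)
  stopifnot(step_mean_transit > step_mean_ars, step_mean_ars > 0,
            grid_resolution > 0, missing_frac >= 0, missing_frac < 1,
            persistence >= 0, persistence < 1)
  if (grid_extent[["lon_max"]] <= grid_extent[["lon_min"]] ||
      grid_extent[["lat_max"]] <= grid_extent[["lat_min"]]) {
    stop("degenerate grid extent")
  }
  switch_link <- switch_link %||% function(env) {
    stats::plogis(1.2 + 1.8 * log(pmax(env[["CHL"]], 1e-6)))
  }
  years <- years %||% if (regime == "positive") {
    c(1998:2004, 2007:2008)
  } else 2005:2006
  structure(list(
    n_whales = n_whales, days_per_whale = days_per_whale,
    seed = as.integer(seed), step_mean_transit = step_mean_transit,
    step_mean_ars = step_mean_ars, switch_link = switch_link,
    regime = regime, grid_extent = grid_extent,
    grid_resolution = grid_resolution,
    ci_halfwidth_dist = ci_halfwidth_dist, grf_range_km = grf_range_km,
    grf_sd = grf_sd, missing_frac = missing_frac,
    sst_lat_slope = sst_lat_slope, persistence = persistence,
    step_shape = step_shape, heading_sd_transit = heading_sd_transit,
    years = years), class = "sim_config")
}
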