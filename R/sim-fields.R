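# Synthetic environmental fields: spatially correlated anomalies via
# circulant-embedding FFT sampling, a deterministic SST latitudinal trend,
# a parametric shelf bathymetry, and an EASTNESS aspect field.

# Sample a stationary Gaussian random field on a regular grid by circulant
# embedding: the covariance is laid out on a doubled torus, its FFT gives
# the (non-negative, up to embedding error) spectrum, and filtering white
# noise through the square-root spectrum yields a field with exactly that
# covariance. Gaussian covariance C(d) = sd^2 * exp(-(d/phi)^2); the
# practical range (95%-of-sill semivariance) is phi * sqrt(ln 20).
# range_km = 0 gives pure white noise.
grf_sample <- function(nlat, nlon, dlat_km, dlon_km, range_km, sd) {
  if (range_km <= 0) {
    return(matrix(stats::rnorm(nlat * nlon, sd = sd), nlat, nlon))
  }
  phi <- range_km / sqrt(log(20))
  m2 <- 2 * nlat; n2 <- 2 * nlon
  # minimal torus offsets in km
  off_lat <- pmin(0:(m2 - 1), m2 - (0:(m2 - 1))) * dlat_km
  off_lon <- pmin(0:(n2 - 1), n2 - (0:(n2 - 1))) * dlon_km
  D2 <- outer(off_lat^2, off_lon^2, "+")
  C <- sd^2 * exp(-D2 / phi^2)
  lam <- Re(stats::fft(C))
  lam[lam < 0] <- 0  # clamp tiny negative embedding eigenvalues
  e <- matrix(stats::rnorm(m2 * n2), m2, n2)
  X <- Re(stats::fft(sqrt(lam) * stats::fft(e), inverse = TRUE)) / (m2 * n2)
  X[seq_len(nlat), seq_len(nlon)]
}

#' Generate synthetic environmental fields
#'
#' Builds the predictor grids the simulator's whales respond to:
#' * `CHL` — lognormal chlorophyll (mg/m^3), spatially correlated, higher
#'   near the coast (eastern edge), a stated fraction of cells missing;
#' * `SST` — sea-surface temperature with a deterministic monotone
#'   latitudinal trend plus a correlated anomaly, same missing fraction;
#' * `DEPTH` — static seafloor depth (m): a shallow shelf along the eastern
#'   margin dropping off westward to abyssal depths;
#' * `EASTNESS` — static east--west aspect in \[-1, 1\].
#'
#' Under the `"negative"` (warm) regime SST gains +1.5 degC and CHL is
#' scaled by 0.6, emulating low-productivity conditions. Reproducible under
#' the config seed.
#'
#' @param config A [sim_config()].
#' @return Named list of [env_grid()] objects (`CHL`, `SST`, `DEPTH`,
#'   `EASTNESS`).
#' @export
gen_env_fields <- function(config) {
  ex <- config$grid_extent
  res <- config$grid_resolution
  if (res <= 0) stop("non-positive resolution")
  if (ex[["lon_max"]] - ex[["lon_min"]] < 2 * res ||
      ex[["lat_max"]] - ex[["lat_min"]] < 2 * res) {
    stop("degenerate extent: spans fewer than two cells")
  }
  lon <- seq(ex[["lon_min"]] + res / 2, ex[["lon_max"]] - res / 2, by = res)
  lat <- seq(ex[["lat_min"]] + res / 2, ex[["lat_max"]] - res / 2, by = res)
  nlat <- length(lat); nlon <- length(lon)
  mid_lat <- mean(lat)
  dlat_km <- res * KM_PER_DEG
  dlon_km <- res * KM_PER_DEG * cos(mid_lat * pi / 180)
  set.seed(config$seed)

  # coast proxy: distance (in degrees) west of the eastern grid edge
  west_of_coast <- outer(rep(1, nlat), ex[["lon_max"]] - lon)

  chl_anom <- grf_sample(nlat, nlon, dlat_km, dlon_km, config$grf_range_km,
                         config$grf_sd)
  chl_mu <- log(1.2) - 0.25 * west_of_coast  # richer inshore
  if (config$regime == "negative") chl_mu <- chl_mu + log(0.6)
  chl <- exp(chl_mu + chl_anom)

  sst_anom <- grf_sample(nlat, nlon, dlat_km, dlon_km, config$grf_range_km,
                         config$grf_sd)
  sst_trend <- outer(config$sst_lat_slope * (lat - mid_lat), rep(1, nlon)) +
    16
  if (config$regime == "negative") sst_trend <- sst_trend + 1.5
  sst <- sst_trend + sst_anom

  # shelf: shallow inshore, a break around 8 deg offshore, dropping to
  # ~4000 m abyssal depths at the western margin
  depth <- 100 + 3900 * stats::plogis((west_of_coast - 8) / 1.5)

  eastness <- grf_sample(nlat, nlon, dlat_km, dlon_km,
                         config$grf_range_km, 0.6)
  eastness[eastness > 1] <- 1
  eastness[eastness < -1] <- -1

  chl_full <- chl; sst_full <- sst
  if (config$missing_frac > 0) {
    mask <- function(m) {
      m[stats::runif(length(m)) < config$missing_frac] <- NA_real_
      m
    }
    chl <- mask(chl); sst <- mask(sst)
  }
  out <- list(CHL = env_grid("CHL", lon, lat, chl),
              SST = env_grid("SST", lon, lat, sst),
              DEPTH = env_grid("DEPTH", lon, lat, depth),
              EASTNESS = env_grid("EASTNESS", lon, lat, eastness))
  # cloud-free copies so the simulator's behavioral link sees the true
  # field even under masked cells
  out$CHL$complete <- chl_full
  out$SST$complete <- sst_full
  out
}
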