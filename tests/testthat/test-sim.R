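# Synthetic fields and tracks: reproducibility, movement scales, the
# behavioral link, and the correlation structure of simulated fields.

small_cfg <- function(...) {
  sim_config(n_whales = 4, days_per_whale = 20, seed = 5,
             grid_extent = c(lon_min = -126, lon_max = -118,
                             lat_min = 32, lat_max = 42),
             grid_resolution = 0.5, ...)
}

test_that("identical config and seed give identical fields and tracks", {
  cfg <- small_cfg()
  f1 <- gen_env_fields(cfg); f2 <- gen_env_fields(cfg)
  expect_identical(f1$CHL$values, f2$CHL$values)
  expect_identical(f1$SST$values, f2$SST$values)
  t1 <- gen_tracks(cfg, f1); t2 <- gen_tracks(cfg, f2)
  expect_identical(t1$tracks, t2$tracks)
  expect_identical(t1$truth$state, t2$truth$state)
})

test_that("simulator rejects degenerate configurations", {
  expect_error(sim_config(step_mean_transit = 10, step_mean_ars = 30))
  expect_error(sim_config(grid_resolution = -1),
               "grid_resolution")
  cfg <- small_cfg()
  cfg$grid_resolution <- 0
  expect_error(gen_env_fields(cfg), "resolution")
  cfg2 <- small_cfg()
  cfg2$grid_extent["lon_max"] <- cfg2$grid_extent[["lon_min"]] + 0.1
  expect_error(gen_env_fields(cfg2), "extent")
})

test_that("fields carry the stated structure", {
  cfg <- small_cfg(missing_frac = 0.15)
  f <- gen_env_fields(cfg)
  # masked satellite products, complete static fields
  expect_gt(mean(is.na(f$CHL$values)), 0.10)
  expect_lt(mean(is.na(f$CHL$values)), 0.20)
  expect_false(anyNA(f$DEPTH$values))
  expect_true(all(f$EASTNESS$values >= -1 & f$EASTNESS$values <= 1))
  expect_true(all(f$CHL$values > 0, na.rm = TRUE))
  # monotone latitudinal SST trend: column means decrease northward
  col_means <- rowMeans(f$SST$complete)
  trend <- coef(lm(col_means ~ f$SST$lat))[[2]]
  expect_equal(trend, cfg$sst_lat_slope, tolerance = 0.15)
})

test_that("a zero-variance anomaly leaves a pure recoverable trend", {
  cfg <- small_cfg(grf_sd = 0, missing_frac = 0)
  f <- gen_env_fields(cfg)
  df <- data.frame(sst = as.vector(f$SST$values),
                   lat = rep(f$SST$lat, length(f$SST$lon)))
  anom <- detrend_latitude(df$sst, df$lat)
  expect_lt(max(abs(anom)), 1e-6)
})

test_that("warm-regime fields are warmer and less productive", {
  fp <- gen_env_fields(small_cfg(missing_frac = 0, grf_sd = 0))
  fn <- gen_env_fields(small_cfg(missing_frac = 0, grf_sd = 0,
                                 regime = "negative"))
  expect_equal(mean(fn$SST$values) - mean(fp$SST$values), 1.5,
               tolerance = 1e-6)
  expect_equal(mean(fn$CHL$values) / mean(fp$CHL$values), 0.6,
               tolerance = 1e-6)
})

test_that("white-noise fields have a flat variogram at the variance", {
  cfg <- small_cfg(grf_range_km = 0, grf_sd = 1, missing_frac = 0)
  f <- gen_env_fields(cfg)
  # sample cells and detrend nothing: use the anomaly directly
  set.seed(2)
  nlat <- length(f$SST$lat); nlon <- length(f$SST$lon)
  idx <- sample(nlat * nlon, 300)
  z <- (f$SST$complete - outer(16 + cfg$sst_lat_slope *
                                 (f$SST$lat - mean(f$SST$lat)),
                               rep(1, nlon)))[idx]
  lons <- rep(f$SST$lon, each = nlat)[idx]
  lats <- rep(f$SST$lat, nlon)[idx]
  vg <- empirical_variogram(lons, lats, z, bin_width_km = 50,
                            max_lag_km = 500)
  v <- var(z)
  # flat at the variance within sampling error; the 20% bound was frozen
  # from a 40-replicate study of this estimator at this sample size
  expect_lt(max(abs(vg$gamma - v) / v), 0.20)
})

test_that("two-state displacements converge to the configured means", {
  cfg <- sim_config(n_whales = 12, days_per_whale = 450, seed = 8,
                    grid_extent = c(lon_min = -160, lon_max = -110,
                                    lat_min = 10, lat_max = 60),
                    grid_resolution = 1,
                    switch_link = function(env) 0.5,
                    persistence = 0, missing_frac = 0)
  f <- gen_env_fields(cfg)
  tt <- gen_tracks(cfg, f)
  tr <- tt$tracks; tu <- tt$truth
  disp <- function(state) {
    out <- c()
    for (w in unique(tr$whale_id)) {
      i <- which(tr$whale_id == w)
      first <- i[-length(i)]
      d <- great_circle_km(tr$lon[first], tr$lat[first],
                           tr$lon[first + 1], tr$lat[first + 1])
      out <- c(out, d[tu$state[first] == state])
    }
    out
  }
  d_transit <- disp(0); d_ars <- disp(1)
  expect_gt(length(d_transit), 2000)
  se_t <- sd(d_transit) / sqrt(length(d_transit))
  se_a <- sd(d_ars) / sqrt(length(d_ars))
  # boundary reflections can only shorten steps; allow 2 SE + small bias
  expect_lt(abs(mean(d_transit) - cfg$step_mean_transit),
            2 * se_t + 0.03 * cfg$step_mean_transit)
  expect_lt(abs(mean(d_ars) - cfg$step_mean_ars),
            2 * se_a + 0.03 * cfg$step_mean_ars)
  expect_gt(mean(d_transit), mean(d_ars))
})

test_that("a constant link of 1 yields pure ARS at the ARS step scale", {
  cfg <- sim_config(n_whales = 4, days_per_whale = 300, seed = 3,
                    grid_extent = c(lon_min = -150, lon_max = -110,
                                    lat_min = 15, lat_max = 55),
                    grid_resolution = 1,
                    switch_link = function(env) 1, persistence = 0)
  f <- gen_env_fields(cfg)
  tt <- gen_tracks(cfg, f)
  expect_true(all(tt$truth$state == 1))
  tr <- tt$tracks
  d <- c()
  for (w in unique(tr$whale_id)) {
    i <- which(tr$whale_id == w)
    d <- c(d, great_circle_km(tr$lon[i[-length(i)]], tr$lat[i[-length(i)]],
                              tr$lon[i[-1]], tr$lat[i[-1]]))
  }
  expect_lt(abs(mean(d) - cfg$step_mean_ars),
            2 * sd(d) / sqrt(length(d)) + 0.03 * cfg$step_mean_ars)
})

test_that("bmode thresholding recovers the true state outside the band", {
  cfg <- small_cfg()
  f <- gen_env_fields(cfg)
  tt <- gen_tracks(cfg, f)
  cls <- classify_mode(tt$tracks$bmode)
  certain <- cls != "uncertain"
  expect_gte(mean(certain), 0.85)  # ~10% drawn in the uncertain band
  recovered <- as.integer(cls[certain] == "ARS")
  expect_equal(recovered, tt$truth$state[certain])
  # credible boxes contain the location
  expect_true(all(tt$tracks$ci_lon_lo <= tt$tracks$lon &
                  tt$tracks$lon <= tt$tracks$ci_lon_hi))
  expect_true(all(tt$tracks$ci_lat_lo <= tt$tracks$lat &
                  tt$tracks$lat <= tt$tracks$ci_lat_hi))
  # dates strictly daily within each track
  for (w in unique(tt$tracks$whale_id)[1:2]) {
    d <- tt$tracks$date[tt$tracks$whale_id == w]
    expect_true(all(diff(as.numeric(d)) == 1))
  }
})

test_that("the ARS fraction tracks a logistic chlorophyll link", {
  link <- function(env) plogis(3 * (log(pmax(env[["CHL"]], 1e-6)) - 0))
  cfg <- sim_config(n_whales = 25, days_per_whale = 400, seed = 21,
                    grid_extent = c(lon_min = -129, lon_max = -117,
                                    lat_min = 30, lat_max = 49),
                    grid_resolution = 0.5, switch_link = link,
                    persistence = 0, missing_frac = 0)
  f <- gen_env_fields(cfg)
  tt <- gen_tracks(cfg, f)
  # each day's state is drawn from the link at the previous day's
  # location, so bin states by the previous location's local chlorophyll
  chl <- vapply(seq_len(nrow(tt$tracks)), function(i) {
    arsnpmr:::field_value_at(f$CHL, tt$tracks$lon[i], tt$tracks$lat[i])
  }, numeric(1))
  same_whale <- c(FALSE, tt$tracks$whale_id[-1] ==
                           tt$tracks$whale_id[-nrow(tt$tracks)])
  i2 <- which(same_whale)
  chl_prev <- chl[i2 - 1]
  state <- tt$truth$state[i2]
  bins <- cut(log(chl_prev), breaks = quantile(log(chl_prev), 0:8 / 8),
              include.lowest = TRUE)
  obs <- tapply(state, bins, mean)
  pred <- tapply(plogis(3 * log(chl_prev)), bins, mean)
  n_bin <- tapply(state, bins, length)
  se <- sqrt(pmax(pred * (1 - pred), 0.01) / n_bin)
  expect_true(all(abs(obs - pred) < 4 * se))
})

test_that("track tables round-trip through CSV", {
  cfg <- small_cfg()
  f <- gen_env_fields(cfg)
  tt <- gen_tracks(cfg, f)
  path <- tempfile(fileext = ".csv")
  write_tracks(tt$tracks, path)
  back <- read_tracks(path)
  expect_equal(back$lon, tt$tracks$lon, tolerance = 1e-12)
  expect_equal(back$date, tt$tracks$date)
  expect_equal(back$bmode, tt$tracks$bmode, tolerance = 1e-12)
})
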