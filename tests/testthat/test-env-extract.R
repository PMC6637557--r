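# Credible-box kernel extraction, latitudinal detrending, collinearity.

grid_const <- function(value, name = "F") {
  env_grid(name, lon = seq(-121, -119, by = 0.25),
           lat = seq(34, 36, by = 0.25),
           values = matrix(value, 9, 9))
}

pt <- function(lon = -120, lat = 35, hw_lon = 0.6, hw_lat = 0.6,
               date = as.Date("2000-08-15")) {
  data.frame(lon = lon, lat = lat, ci_lon_lo = lon - hw_lon,
             ci_lon_hi = lon + hw_lon, ci_lat_lo = lat - hw_lat,
             ci_lat_hi = lat + hw_lat, date = date)
}

test_that("extraction of a constant field returns the constant exactly", {
  expect_equal(kernel_weighted_extract(pt(), grid_const(3.7)), 3.7)
})

test_that("a single non-missing center cell dominates regardless of box", {
  g <- grid_const(NA_real_)
  g$values[5, 5] <- 42  # the cell at (-120, 35), distance 0 from the point
  expect_equal(kernel_weighted_extract(pt(), g), 42)
})

test_that("the quartic taper reproduces the hand-computed 1-D example", {
  # cells on a line at d/d_max = 0, 0.5, 1.0 with values 10, 20, 30:
  # (1*10 + 0.5625*20 + 0*30) / 1.5625 = 13.6
  g <- env_grid("F", lon = c(0, 0.1, 0.2), lat = c(-1e-7, 0, 1e-7),
                values = matrix(rep(c(10, 20, 30), each = 3), 3, 3))
  p <- data.frame(lon = 0, lat = 0, ci_lon_lo = -0.2, ci_lon_hi = 0.2001,
                  ci_lat_lo = -1e-6, ci_lat_hi = 1e-6,
                  date = as.Date("2000-01-01"))
  # d_max is the distance to the box corner at lon 0.2001 -> the third
  # cell sits at d/d_max ~ 1 and takes ~zero weight
  expect_equal(kernel_weighted_extract(p, g), 13.6, tolerance = 1e-3)
})

test_that("extraction returns missing iff no non-missing cell in the box", {
  g <- grid_const(NA_real_)
  expect_true(is.na(kernel_weighted_extract(pt(), g)))
  g2 <- grid_const(5)
  outside <- pt(lon = -130, lat = 20, hw_lon = 0.1, hw_lat = 0.1)
  expect_true(is.na(kernel_weighted_extract(outside, g2)))
})

test_that("extraction stays within the hull of contributing cells", {
  set.seed(3)
  g <- grid_const(0)
  g$values[] <- runif(81, -5, 5)
  v <- kernel_weighted_extract(pt(), g)
  expect_gte(v, min(g$values))
  expect_lte(v, max(g$values))
})

test_that("a single-cell box reproduces nearest-cell extraction", {
  set.seed(4)
  g <- grid_const(0)
  g$values[] <- runif(81)
  p <- pt(hw_lon = 0.1, hw_lat = 0.1)  # only the center cell inside
  expect_equal(kernel_weighted_extract(p, g), g$values[5, 5])
})

test_that("time-resolved grids use the nearest slice within resolution", {
  vals <- array(c(matrix(1, 9, 9), matrix(2, 9, 9)), c(9, 9, 2))
  g <- env_grid("F", lon = seq(-121, -119, by = 0.25),
                lat = seq(34, 36, by = 0.25), values = vals,
                time = as.Date(c("2000-08-01", "2000-08-09")))
  expect_equal(kernel_weighted_extract(pt(date = as.Date("2000-08-02")), g),
               1)
  expect_equal(kernel_weighted_extract(pt(date = as.Date("2000-08-08")), g),
               2)
  # beyond one native step (8 d) from any slice -> missing
  expect_true(is.na(
    kernel_weighted_extract(pt(date = as.Date("2000-09-15")), g)))
})

test_that("grids round-trip through the text format", {
  set.seed(5)
  g <- grid_const(0)
  g$values[] <- round(runif(81), 6)
  g$values[c(3, 10)] <- NA
  path <- tempfile(fileext = ".csv")
  write_env_grid(g, path)
  g2 <- read_env_grid(path)
  expect_equal(g2$values, g$values)
  expect_equal(g2$lon, g$lon)
  expect_equal(g2$name, g$name)
})

test_that("detrend_latitude removes linear trends and is idempotent", {
  lats <- seq(30, 49, length.out = 200)
  vals <- 25 - 0.4 * lats
  a <- detrend_latitude(vals, lats)
  expect_lt(max(abs(a)), 1e-8 * diff(range(vals)))
  expect_equal(detrend_latitude(rep(7, 50), seq(30, 49, length.out = 50)),
               rep(0, 50), tolerance = 1e-10)
  # trend + noise: anomalies uncorrelated with latitude
  set.seed(11)
  lats <- runif(1000, 30, 49)
  vals <- 25 - 0.4 * lats + rnorm(1000, 0, 0.5)
  a <- detrend_latitude(vals, lats)
  expect_lt(abs(cor(a, lats)), 0.05)
  # approximate idempotence: loess is a linear but non-projective
  # smoother, so re-detrending noisy anomalies moves them only slightly;
  # on noiseless trends (above) the residual change is exactly zero
  a2 <- detrend_latitude(a, lats)
  expect_lt(max(abs(a2 - a)), 0.02 * diff(range(a)))
  # missing propagation
  vals[c(5, 9)] <- NA
  a3 <- detrend_latitude(vals, lats)
  expect_true(all(is.na(a3[c(5, 9)])))
  expect_false(anyNA(a3[-c(5, 9)]))
  expect_error(detrend_latitude(rep(NA_real_, 20), 1:20), "missing")
})

test_that("collinearity screen drops the weaker member of redundant pairs", {
  set.seed(6)
  n <- 200
  tab <- data.frame(a = rnorm(n))
  tab$b <- tab$a            # r = 1 duplicate
  tab$c <- rnorm(n)         # independent
  scores <- c(a = 5, b = 3, c = 1)
  res <- collinearity_screen(tab, c("a", "b", "c"), scores)
  expect_setequal(res$retained, c("a", "c"))
  expect_equal(res$flagged_pairs$dropped, "b")
  # the member with lower single-predictor logB goes, not a fixed side
  res2 <- collinearity_screen(tab, c("a", "b", "c"),
                              c(a = 2, b = 6, c = 1))
  expect_true("b" %in% res2$retained)
  expect_false("a" %in% res2$retained)
  # independent predictors all retained
  tab2 <- data.frame(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  res3 <- collinearity_screen(tab2, c("p", "q", "r"),
                              c(p = 1, q = 1, r = 1))
  expect_setequal(res3$retained, c("p", "q", "r"))
  # zero-variance predictor flagged degenerate
  tab2$z <- 1
  res4 <- collinearity_screen(tab2, c("p", "q", "z"),
                              c(p = 1, q = 1, z = 9))
  expect_equal(res4$degenerate, "z")
  expect_false("z" %in% res4$retained)
})
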