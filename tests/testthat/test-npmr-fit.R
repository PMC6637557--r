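# NPMR local-mean estimation against brute-force oracles, fit statistics,
# tolerance/sensitivity reporting, prediction on new rows.

test_that("kernel_weight matches its closed forms", {
  a <- list(x = 1, g = "u"); b <- list(x = 1, g = "u")
  expect_equal(kernel_weight(a, b, c(x = 0.3), "g"), 1)
  b$x <- 1.3
  expect_equal(kernel_weight(a, b, c(x = 0.3)), exp(-0.5))
  a2 <- list(x = 0, z = 0); b2 <- list(x = 1, z = 1)
  expect_equal(kernel_weight(a2, b2, c(x = 1, z = 1)), exp(-1))
  b$g <- "v"
  expect_equal(kernel_weight(a, b, c(x = 0.3), "g"), 0)
  expect_error(kernel_weight(a, b, c(x = -1)), "positive")
})

test_that("LOO estimates and neighborhood sizes match the brute force", {
  tab <- toy_table(n = 20)
  sig <- c(x1 = diff(range(tab$x1)) / 2, x2 = diff(range(tab$x2)) / 3)
  fit <- npmr(y ~ x1 + x2, tab, tolerances = sig, sensitivity = FALSE)
  for (t in seq_len(nrow(tab))) {
    o <- oracle_loo(tab, tab$y, t, sig, n_min = fit$n_min)
    expect_equal(fit$nstar[t], o$nstar, tolerance = 1e-10)
    if (is.na(o$estimate)) {
      expect_true(is.na(fit$estimates[t]))
    } else {
      expect_equal(fit$estimates[t], o$estimate, tolerance = 1e-10)
    }
  }
})

test_that("categorical predictors use the exact-match kernel", {
  tab <- toy_table(n = 24)
  sig <- c(x1 = 0.3)
  fit <- npmr(y ~ x1 + id, tab, tolerances = sig, sensitivity = FALSE)
  for (t in c(1, 7, 13)) {
    o <- oracle_loo(tab, tab$y, t, sig, categorical = "id",
                    n_min = fit$n_min)
    expect_equal(fit$nstar[t], o$nstar, tolerance = 1e-10)
  }
})

test_that("infinite tolerance gives the leave-one-out global mean", {
  tab <- toy_table(n = 25)
  fit <- npmr(y ~ x1, tab, tolerances = c(x1 = 1e9), sensitivity = FALSE)
  n <- nrow(tab)
  expect_equal(fit$nstar, rep(n - 1, n), tolerance = 1e-6)
  loo_means <- (sum(tab$y) - tab$y) / (n - 1)
  expect_equal(fit$estimates, loo_means, tolerance = 1e-6)
})

test_that("pure-ARS neighborhoods estimate 1", {
  tab <- data.frame(x1 = c(1:10 / 10, 5), y = c(rep(1, 10), 1))
  fit <- npmr(y ~ x1, tab, tolerances = c(x1 = 0.5), sensitivity = FALSE)
  expect_equal(fit$estimates[!is.na(fit$estimates)],
               rep(1, sum(!is.na(fit$estimates))), tolerance = 1e-12)
})

test_that("logB matches a term-by-term likelihood oracle", {
  tab <- toy_table(n = 40, seed = 9)
  fit <- npmr(y ~ x1, tab, tolerances = c(x1 = 0.2), sensitivity = FALSE)
  su <- fit$su
  eps <- 1 / (2 * fit$SU)
  expect_equal(fit$logB,
               oracle_logB(fit$y[su], fit$estimates[su], eps),
               tolerance = 1e-12)
  expect_equal(fit$B_ave, 10^(fit$logB / fit$SU), tolerance = 1e-12)
  expect_equal(fit$chisq, 2 * log(10) * fit$logB, tolerance = 1e-12)
})

test_that("the naive model scores logB 0, B_ave 1, xR2 0 exactly", {
  y <- c(0, 1, 1, 0, 1, 1, 1, 0)
  st <- arsnpmr:::npmr_fit_stats(y, rep(mean(y), 8), rep(TRUE, 8))
  expect_identical(st$logB, 0)
  expect_identical(st$B_ave, 1)
  expect_equal(st$xR2, 0, tolerance = 1e-15)
})

test_that("fit statistics are invariant to row permutation", {
  tab <- toy_table(n = 35, seed = 2)
  sig <- c(x1 = 0.25, x2 = 0.4)
  f1 <- npmr(y ~ x1 + x2, tab, tolerances = sig, sensitivity = FALSE)
  set.seed(99)
  perm <- sample(nrow(tab))
  f2 <- npmr(y ~ x1 + x2, tab[perm, ], tolerances = sig,
             sensitivity = FALSE)
  for (s in c("SU", "N_ave", "n_min", "logB", "B_ave", "xR2", "r")) {
    expect_equal(f1[[s]], f2[[s]], tolerance = 1e-10)
  }
  expect_equal(f1$estimates[perm], f2$estimates, tolerance = 1e-10)
})

test_that("estimates stay within [0,1] and the neighbor response hull", {
  tab <- toy_table(n = 60, seed = 5)
  fit <- npmr(y ~ x1 + x2, tab, tolerances = c(x1 = 0.15, x2 = 0.3),
              sensitivity = FALSE)
  e <- fit$estimates[!is.na(fit$estimates)]
  expect_true(all(e >= 0 & e <= 1))
})

test_that("tolerance_pct reproduces the published percentage arithmetic", {
  expect_equal(tolerance_pct(0.30, 7.55), 4.0)
  expect_equal(tolerance_pct(571.98, 1972.30), 29.0)
  expect_equal(tolerance_pct(5, 5), 100)
  expect_error(tolerance_pct(1, 0), "positive")
})

test_that("sensitivity matches brute-force nudged re-estimation", {
  tab <- toy_table(n = 25, seed = 13)
  sig <- c(x1 = 0.2, x2 = 0.35)
  fit <- npmr(y ~ x1 + x2, tab, tolerances = sig)
  nf <- fit$control$nudge_fraction
  rg <- diff(range(tab$x1))
  diffs <- c()
  for (dd in c(-nf * rg, nf * rg)) {
    for (t in seq_len(nrow(tab))) {
      nudged <- tab
      nudged$x1[t] <- nudged$x1[t] + dd
      # neighbors keep original values; target excluded from itself
      w <- ys <- numeric(0)
      for (i in seq_len(nrow(tab))) {
        if (i == t) next
        w <- c(w, oracle_weight(
          data.frame(x1 = c(nudged$x1[t], tab$x1[i]),
                     x2 = c(tab$x2[t], tab$x2[i])), 1, 2, sig))
        ys <- c(ys, tab$y[i])
      }
      est <- if (sum(w) >= fit$n_min) sum(w * ys) / sum(w) else NA
      diffs <- c(diffs, abs(est - fit$estimates[t]))
    }
  }
  q_oracle <- mean(diffs, na.rm = TRUE) / nf
  expect_equal(unname(fit$sensitivity["x1"]), q_oracle, tolerance = 1e-10)
})

test_that("a predictor with huge tolerance has near-zero sensitivity", {
  tab <- toy_table(n = 30, seed = 21)
  fit <- npmr(y ~ x1 + x2, tab, tolerances = c(x1 = 0.2, x2 = 1e9))
  expect_lt(fit$sensitivity[["x2"]], 1e-6)
})

test_that("sensitivity scales as published: Q times nudge in response %", {
  # Q = 0.71 -> a 20% predictor change moves the response by ~14%
  expect_equal(round(0.71 * 20), 14)
})

test_that("predict on new rows matches the non-LOO brute force", {
  tab <- toy_table(n = 20, seed = 31)
  sig <- c(x1 = 0.3, x2 = 0.5)
  fit <- npmr(y ~ x1 + x2, tab, tolerances = sig, sensitivity = FALSE)
  new <- data.frame(x1 = c(tab$x1[4], 0.2, 0.8),
                    x2 = c(tab$x2[4], 0.5, 0.1))
  pred <- predict(fit, new)
  nm <- attr(pred, "n_min")
  for (k in seq_len(nrow(new))) {
    o <- oracle_predict(new[k, ], tab, tab$y, sig, n_min = nm)
    if (is.na(o)) expect_true(is.na(pred[k])) else
      expect_equal(unname(pred[k]), o, tolerance = 1e-12)
  }
  # a new row identical to a building row includes that row (non-LOO)
  self_w <- oracle_predict(tab[4, ], tab, tab$y, sig, n_min = 0)
  expect_equal(unname(pred[1]), self_w, tolerance = 1e-12)
  expect_error(predict(fit, data.frame(x1 = 1)), "lacks")
})

test_that("validation neighborhoods shrink in sparse predictor space", {
  set.seed(77)
  build <- data.frame(x1 = rnorm(200, 0, 1))
  build$y <- rbinom(200, 1, plogis(build$x1))
  fit <- npmr(y ~ x1, build, tolerances = c(x1 = 0.5), sensitivity = FALSE)
  # shifted regime: new rows occupy the thin tail of the building cloud
  shifted <- data.frame(x1 = rnorm(100, 3, 1),
                        y = rbinom(100, 1, 0.5))
  v <- npmr_validate(fit, shifted, sensitivity = FALSE)
  expect_lt(v$N_ave, fit$N_ave)
  expect_true(all(v$estimates >= 0 & v$estimates <= 1, na.rm = TRUE))
})

test_that("model frame enforces the data:predictor ratio and binary y", {
  tab <- toy_table(n = 15)
  expect_error(npmr(y ~ x1 + x2, tab,
                    tolerances = c(x1 = 0.2, x2 = 0.2)), "10")
  tab2 <- toy_table(n = 30)
  tab2$y <- runif(30)
  expect_error(npmr(y ~ x1, tab2, tolerances = c(x1 = 0.2)), "binary")
})
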