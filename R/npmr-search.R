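# Free stepwise search over candidate predictors and tolerance grids,
# local tolerance tuning, bootstrap confidence intervals for logB, and a
# randomization (Monte Carlo) test against a shuffled-response null.

# Precomputes everything that does not depend on the response permutation:
# squared-difference matrices per continuous candidate and equality masks
# per categorical candidate.
search_cache <- function(y, data, continuous, categorical, control) {
  D2 <- lapply(continuous, function(j) {
    d <- outer(data[[j]], data[[j]], "-")
    d * d
  })
  names(D2) <- continuous
  G <- lapply(categorical, function(k) {
    g <- as.character(data[[k]])
    outer(g, g, "==") * 1
  })
  names(G) <- categorical
  ranges <- vapply(continuous, function(j) diff(range(data[[j]])), numeric(1))
  if (any(ranges <= 0)) stop("zero-range candidate predictor")
  list(y = y, n = length(y), D2 = D2, G = G, ranges = ranges,
       continuous = continuous, categorical = categorical, control = control)
}

# Evaluate one model spec against the cache; NULL if no populated
# neighborhood. sigmas is named over the selected continuous predictors.
eval_spec <- function(cache, cont_sel, sigmas, cat_sel) {
  S <- 0
  for (j in cont_sel) S <- S + cache$D2[[j]] / sigmas[[j]]^2
  W <- if (length(cont_sel)) exp(-0.5 * S) else
    matrix(1, cache$n, cache$n)
  for (k in cat_sel) W <- W * cache$G[[k]]
  tryCatch(npmr_engine(cache$y, W, cache$control$n_min_fraction),
           error = function(e) NULL)
}

# Forward-stepwise free search. At each size the incumbent predictors keep
# their tolerances and each remaining candidate is scanned over the full
# tolerance grid; a larger model is accepted only if it clears the
# improvement threshold. Ties prefer larger tolerances (the grid is scanned
# from large to small with strict improvement).
free_search_engine <- function(cache) {
  ctrl <- cache$control
  max_p <- ctrl$max_predictors %||% max(1L, floor(cache$n / 30))
  grid <- rev(ctrl$tolerance_grid)
  best_ext <- function(cont_sel, sigmas, cat_sel, cand) {
    if (cand %in% cache$categorical) {
      eng <- eval_spec(cache, cont_sel, sigmas, c(cat_sel, cand))
      if (is.null(eng)) return(NULL)
      return(list(cont = cont_sel, sigmas = sigmas,
                  cat = c(cat_sel, cand), eng = eng))
    }
    best <- NULL
    for (fr in grid) {
      sg <- c(sigmas, stats::setNames(fr * cache$ranges[[cand]], cand))
      eng <- eval_spec(cache, c(cont_sel, cand), sg, cat_sel)
      if (!is.null(eng) && (is.null(best) || eng$logB > best$eng$logB)) {
        best <- list(cont = c(cont_sel, cand), sigmas = sg, cat = cat_sel,
                     eng = eng)
      }
    }
    best
  }
  candidates <- c(cache$continuous, cache$categorical)
  by_size <- list()
  incumbent <- NULL
  remaining <- candidates
  repeat {
    size <- length(c(incumbent$cont, incumbent$cat)) + 1L
    if (size > max_p || !length(remaining)) break
    step_best <- NULL
    for (cand in remaining) {
      ext <- best_ext(incumbent$cont, incumbent$sigmas, incumbent$cat, cand)
      if (!is.null(ext) && (is.null(step_best) ||
                            ext$eng$logB > step_best$eng$logB)) {
        step_best <- ext
      }
    }
    if (is.null(step_best)) break
    by_size[[size]] <- list(
      predictors = c(step_best$cont, step_best$cat),
      tolerances = step_best$sigmas, logB = step_best$eng$logB,
      N_ave = step_best$eng$N_ave)
    if (is.null(incumbent)) {
      incumbent <- step_best
    } else {
      inc_logB <- incumbent$eng$logB
      thresh <- if (inc_logB > 0) {
        cache$control$min_improve_fraction * abs(inc_logB)
      } else 1.0
      if (step_best$eng$logB >= inc_logB + thresh) {
        incumbent <- step_best
      } else break
    }
    remaining <- setdiff(remaining, c(incumbent$cont, incumbent$cat))
  }
  if (is.null(incumbent)) stop("no candidate yields a populated model")
  list(by_size = by_size, final = incumbent)
}

#' Free search for the best NPMR model
#'
#' Forward-stepwise search over the candidate predictors on the right-hand
#' side of `formula`: every candidate is scanned over the tolerance grid as
#' a single-predictor model; the best model of each size is then extended by
#' each remaining candidate (with a full tolerance-grid scan for the added
#' predictor) and a larger model is accepted only when its logB beats the
#' incumbent by the improvement threshold — a parsimony control against
#' overfitting. Rows with a missing value in any candidate are excluded
#' (complete cases). Deterministic given the control settings.
#'
#' @param formula Response and candidate predictors, e.g.
#'   `ars ~ CHL + SST + DEPTH + EASTNESS`.
#' @param data Data.frame.
#' @param control An [npmr_control()].
#' @param tune Refine the selected model's tolerances with [npmr_tune()]?
#' @return Object of class `npmr_search`: `by_size` (best model per
#'   explored size), `fit` (the chosen final [npmr()] fit), `data` (the
#'   complete-case rows used).
#' @export
npmr_search <- function(formula, data, control = npmr_control(),
                        tune = FALSE) {
  tm <- parse_npmr_terms(formula, data)
  cache <- search_cache(tm$y, tm$frame, tm$continuous, tm$categorical,
                        control)
  res <- free_search_engine(cache)
  resp <- names(tm$frame)[1]
  final_preds <- c(res$final$cont, res$final$cat)
  fit <- npmr(stats::reformulate(final_preds, response = resp), tm$frame,
              tolerances = res$final$sigmas, control = control)
  if (tune) fit <- npmr_tune(fit)
  structure(list(by_size = res$by_size, fit = fit, data = tm$frame,
                 control = control), class = "npmr_search")
}

#' @export
print.npmr_search <- function(x, ...) {
  cat("NPMR free search\n")
  for (s in seq_along(x$by_size)) {
    b <- x$by_size[[s]]
    if (is.null(b)) next
    cat(sprintf("  size %d: %s  logB = %.2f  N_ave = %.2f\n", s,
                paste(b$predictors, collapse = " x "), b$logB, b$N_ave))
  }
  cat("Final model:\n")
  print(x$fit)
  invisible(x)
}

#' Tune the tolerances of a fitted NPMR model
#'
#' Coordinate-wise local refinement: each tolerance is scanned over a fine
#' grid spanning one coarse grid step either side (five subdivisions per
#' step), keeping the others fixed; sweeps repeat until logB improves by
#' less than `min_gain`. The returned fit never has lower logB than the
#' input.
#'
#' @param fit An [npmr()] fit.
#' @param min_gain Stop when a full sweep gains less than this much logB.
#' @return A tuned [npmr()] fit.
#' @export
npmr_tune <- function(fit, min_gain = 0.01) {
  if (!length(fit$continuous)) return(fit)
  ctrl <- fit$control
  grid_step <- if (length(ctrl$tolerance_grid) > 1) {
    diff(ctrl$tolerance_grid[1:2])
  } else 0.05
  cache <- search_cache(fit$y, fit$frame, fit$continuous, fit$categorical,
                        ctrl)
  sigmas <- fit$tolerances
  best_logB <- fit$logB
  repeat {
    sweep_start <- best_logB
    for (j in fit$continuous) {
      step <- grid_step * fit$ranges[[j]] / 5
      cand <- sigmas[[j]] + step * (-5:5)
      cand <- sort(cand[cand > 0], decreasing = TRUE)  # ties -> larger sigma
      for (s in cand) {
        sg <- sigmas; sg[[j]] <- s
        eng <- eval_spec(cache, fit$continuous, sg, fit$categorical)
        if (!is.null(eng) && eng$logB > best_logB) {
          best_logB <- eng$logB
          sigmas <- sg
        }
      }
    }
    if (best_logB - sweep_start < min_gain) break
  }
  if (identical(sigmas, fit$tolerances)) return(fit)
  npmr(fit$formula, fit$frame, tolerances = sigmas, control = ctrl)
}

#' Bootstrap confidence interval for logB
#'
#' Resamples the rows with replacement, refits the model (fixed predictors
#' and tolerances) on each replicate, and reports the 5th/95th percentiles
#' and median of logB. Replicates where no neighborhood is populated are
#' recorded as missing. Reproducible: replicate `i` uses `seed + i`.
#'
#' @param fit An [npmr()] fit.
#' @param n_boot Number of replicates (default from the fit's control).
#' @param seed Base seed (default from the fit's control).
#' @return Object of class `npmr_boot` with `logB` (per replicate), `ci`
#'   (5th/95th percentiles), `median`, `n_failed`.
#' @export
npmr_boot <- function(fit, n_boot = fit$control$n_boot,
                      seed = fit$control$seed) {
  n <- length(fit$y)
  W0 <- npmr_weight_matrix(fit$X, fit$tolerances, fit$groups)
  logB <- vapply(seq_len(n_boot), function(i) {
    set.seed(seed + i)
    idx <- sample.int(n, n, replace = TRUE)
    eng <- tryCatch(
      npmr_engine(fit$y[idx], W0[idx, idx, drop = FALSE],
                  fit$control$n_min_fraction),
      error = function(e) NULL)
    if (is.null(eng)) NA_real_ else eng$logB
  }, numeric(1))
  structure(list(logB = logB,
                 ci = stats::quantile(logB, c(0.05, 0.95), na.rm = TRUE),
                 median = stats::median(logB, na.rm = TRUE),
                 n_failed = sum(is.na(logB)), observed = fit$logB),
            class = "npmr_boot")
}

#' @export
print.npmr_boot <- function(x, ...) {
  cat(sprintf(
    "Bootstrap logB (%d replicates%s): median %.2f, 90%% interval %.2f-%.2f\n",
    length(x$logB),
    if (x$n_failed) paste0(", ", x$n_failed, " failed") else "",
    x$median, x$ci[[1]], x$ci[[2]]))
  invisible(x)
}

#' Randomization test for the free-search model
#'
#' Shuffles the response, reruns the full free search, and records the best
#' achievable null logB, `n_rand` times. The p-value is
#' `(1 + #(null >= observed)) / (1 + n_rand)` (never exactly zero). Tests
#' whether the observed fit could be obtained by chance from unrelated
#' predictors.
#'
#' @param formula,data,control As in [npmr_search()].
#' @param observed_logB Observed best logB; computed by an initial
#'   free search when omitted.
#' @param n_rand,seed Override the control's replicate count / base seed.
#' @return Object of class `npmr_randomization` with `p_value`,
#'   `null_logB`, `null_mean`, `null_var`, `observed`.
#' @export
npmr_randomization <- function(formula, data, control = npmr_control(),
                               observed_logB = NULL,
                               n_rand = control$n_rand,
                               seed = control$seed) {
  tm <- parse_npmr_terms(formula, data)
  cache <- search_cache(tm$y, tm$frame, tm$continuous, tm$categorical,
                        control)
  if (is.null(observed_logB)) {
    observed_logB <- free_search_engine(cache)$final$eng$logB
  }
  null_logB <- vapply(seq_len(n_rand), function(i) {
    set.seed(seed + 10000L + i)
    cache$y <- sample(cache$y)
    res <- tryCatch(free_search_engine(cache), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$final$eng$logB
  }, numeric(1))
  p <- (1 + sum(null_logB >= observed_logB, na.rm = TRUE)) / (1 + n_rand)
  structure(list(p_value = p, null_logB = null_logB,
                 null_mean = mean(null_logB, na.rm = TRUE),
                 null_var = stats::var(null_logB, na.rm = TRUE),
                 observed = observed_logB, n_rand = n_rand),
            class = "npmr_randomization")
}

#' @export
print.npmr_randomization <- function(x, ...) {
  cat(sprintf(
    "Randomization test (%d runs): observed logB = %.2f, null mean = %.2f, null var = %.2f, p = %.4g\n",
    x$n_rand, x$observed, x$null_mean, x$null_var, x$p_value))
  invisible(x)
}
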