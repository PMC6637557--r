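# Nonparametric multiplicative regression (NPMR) for a binary response.
#
# A local-mean model: the estimate at a target point is the weighted average
# of the response over all *other* sample units (leave-one-out), with
# univariate Gaussian kernel weights over each continuous predictor combined
# multiplicatively, and exact-match indicator weights for categorical
# predictors. The standard deviation of each Gaussian (the predictor's
# "tolerance") sets the smoothing scale; the summed weight at a target point
# is its "neighborhood size" n*. Estimates are only produced where the
# neighborhood is sufficiently populated (n* >= n_min).

#' Control parameters for NPMR fitting and search
#'
#' @param tolerance_grid Candidate tolerances as fractions of each
#'   predictor's observed range (free-search scan grid).
#' @param n_min_fraction Minimum neighborhood size as a fraction of the
#'   average neighborhood size (`n_min = n_min_fraction * N_ave`).
#' @param nudge_fraction Predictor nudge (fraction of range) used by the
#'   sensitivity statistic.
#' @param min_improve_fraction A predictor is only added during free search
#'   when it improves logB by at least this fraction of the incumbent logB
#'   (or by >= 1.0 when the incumbent logB is non-positive).
#' @param max_predictors Cap on model size; defaults to `floor(n / 30)`
#'   (a 30:1 data-to-predictor ratio).
#' @param seed Base seed for bootstrap/randomization streams.
#' @param n_boot Bootstrap replicates.
#' @param n_rand Randomization-test replicates.
#' @return List of class `npmr_control`.
#' @export
npmr_control <- function(tolerance_grid = seq(0.05, 1, by = 0.05),
                         n_min_fraction = 0.25, nudge_fraction = 0.05,
                         min_improve_fraction = 0.05, max_predictors = NULL,
                         seed = 1L, n_boot = 100L, n_rand = 100L) {
  stopifnot(all(tolerance_grid > 0), all(tolerance_grid <= 1),
            n_min_fraction > 0, n_min_fraction <= 1,
            nudge_fraction > 0, nudge_fraction <= 1,
            n_boot >= 1, n_rand >= 1)
  structure(list(tolerance_grid = sort(tolerance_grid),
                 n_min_fraction = n_min_fraction,
                 nudge_fraction = nudge_fraction,
                 min_improve_fraction = min_improve_fraction,
                 max_predictors = max_predictors, seed = as.integer(seed),
                 n_boot = as.integer(n_boot), n_rand = as.integer(n_rand)),
            class = "npmr_control")
}

#' Multiplicative kernel weight between two rows
#'
#' `w = prod_j exp(-((x_tj - x_ij)^2) / (2 sigma_j^2))` over continuous
#' predictors, times an exact-match indicator over categorical predictors.
#'
#' @param target,other Named lists/one-row data.frames of predictor values.
#' @param tolerances Named vector of Gaussian kernel standard deviations for
#'   the continuous predictors.
#' @param categorical Character vector of categorical predictor names.
#' @return Weight in \[0, 1\].
#' @export
kernel_weight <- function(target, other, tolerances, categorical = character()) {
  if (any(tolerances <= 0)) stop("tolerances must be positive")
  w <- 1
  for (j in names(tolerances)) {
    w <- w * exp(-0.5 * ((target[[j]] - other[[j]]) / tolerances[[j]])^2)
  }
  for (k in categorical) {
    w <- w * as.numeric(target[[k]] == other[[k]])
  }
  w
}

# Full n x n weight matrix. X: numeric matrix (n x p, may have 0 cols);
# sigma: length-p positive; groups: list of factors for categorical terms.
npmr_weight_matrix <- function(X, sigma, groups = list()) {
  n <- if (ncol(X)) nrow(X) else length(groups[[1]])
  S <- matrix(0, n, n)
  for (j in seq_len(ncol(X))) {
    d <- outer(X[, j], X[, j], "-") / sigma[j]
    S <- S + d * d
  }
  W <- exp(-0.5 * S)
  for (g in groups) W <- W * outer(g, g, "==")
  W
}

# Cross weight matrix (new rows x building rows), no leave-one-out.
npmr_cross_weights <- function(Xnew, Xb, sigma, groups_new = list(),
                               groups_b = list()) {
  n_new <- if (ncol(Xnew)) nrow(Xnew) else length(groups_new[[1]])
  n_b <- if (ncol(Xb)) nrow(Xb) else length(groups_b[[1]])
  S <- matrix(0, n_new, n_b)
  for (j in seq_len(ncol(Xb))) {
    d <- outer(Xnew[, j], Xb[, j], "-") / sigma[j]
    S <- S + d * d
  }
  W <- exp(-0.5 * S)
  for (k in seq_along(groups_b)) {
    W <- W * outer(groups_new[[k]], groups_b[[k]], "==")
  }
  W
}

# n_min is defined self-referentially (n_min = f * N_ave, N_ave = mean n*
# over rows with n* >= n_min); resolved by fixed-point iteration from the
# all-rows mean. Returns list(n_min, su, N_ave).
resolve_n_min <- function(nstar, n_min_fraction) {
  n_min <- n_min_fraction * mean(nstar)
  for (i in 1:100) {
    su <- nstar >= n_min & nstar > 0
    if (!any(su)) stop("no populated neighborhoods (SU = 0)")
    n_new <- n_min_fraction * mean(nstar[su])
    if (abs(n_new - n_min) < 1e-10) break
    n_min <- n_new
  }
  su <- nstar >= n_min & nstar > 0
  list(n_min = n_min, su = su, N_ave = mean(nstar[su]))
}

# Fit statistics from response + estimates over the populated rows.
# logB is the base-10 log likelihood ratio against a naive model that
# predicts the observed prevalence everywhere; estimates are clamped to
# [eps, 1-eps], eps = 1/(2 SU), before likelihood evaluation.
npmr_fit_stats <- function(y, yhat, su) {
  SU <- sum(su)
  ys <- y[su]; es <- yhat[su]
  pbar <- mean(ys)
  eps <- 1 / (2 * SU)
  ec <- pmin(pmax(es, eps), 1 - eps)
  pc <- pmin(pmax(pbar, eps), 1 - eps)
  logB <- sum(ifelse(ys == 1, log10(ec) - log10(pc),
                     log10(1 - ec) - log10(1 - pc)))
  denom <- sum((ys - pbar)^2)
  xR2 <- if (denom > 0) 1 - sum((ys - es)^2) / denom else NA_real_
  r <- if (stats::sd(ys) > 0 && stats::sd(es) > 0) {
    stats::cor(ys, es)
  } else NA_real_
  list(SU = SU, prevalence = pbar, logB = logB, B_ave = 10^(logB / SU),
       xR2 = xR2, r = r, chisq = 2 * log(10) * logB)
}

# Core LOO engine: weight matrix -> estimates, neighborhood sizes, stats.
npmr_engine <- function(y, W, n_min_fraction) {
  diag(W) <- 0
  nstar <- unname(rowSums(W))
  nm <- resolve_n_min(nstar, n_min_fraction)
  yhat <- as.vector(W %*% y)
  yhat <- ifelse(nstar > 0, yhat / nstar, NA_real_)
  yhat[!nm$su] <- NA_real_
  stats <- npmr_fit_stats(y, yhat, nm$su)
  c(list(estimates = yhat, nstar = nstar, n_min = nm$n_min,
         N_ave = nm$N_ave, su = nm$su), stats)
}

parse_npmr_terms <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- mf[[1]]
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop("response must be binary (0/1 absence/presence of ARS)")
  }
  pred_names <- names(mf)[-1]
  is_cat <- vapply(mf[-1], function(v) is.factor(v) || is.character(v),
                   logical(1))
  cc <- stats::complete.cases(mf)
  list(y = y[cc], frame = mf[cc, , drop = FALSE],
       continuous = pred_names[!is_cat], categorical = pred_names[is_cat],
       n_dropped = sum(!cc))
}

#' Fit an NPMR local-mean model
#'
#' Fits the binary-response NPMR model with given tolerances: every row's
#' estimate is the kernel-weighted, leave-one-out average of the response
#' over the other rows. Rows with any missing value in the model's variables
#' are dropped (complete cases). Reported statistics: SU (sample units in
#' populated neighborhoods), N_ave (mean neighborhood size over SU), n_min
#' (`n_min_fraction * N_ave`, resolved jointly with SU), logB (base-10 log
#' likelihood ratio against the naive prevalence model), B_ave
#' (`10^(logB/SU)`, the per-sample-unit likelihood ratio), the
#' cross-validated pseudo-R-squared xR2, the Pearson correlation r between
#' response and estimate, the deviance chi-square `2 ln(10) logB`, and
#' per-predictor sensitivities.
#'
#' @param formula e.g. `ars ~ CHL + SST + DEPTH + whale_id`; numeric terms
#'   are continuous predictors (each needs a tolerance), factor/character
#'   terms are categorical (exact-match kernel).
#' @param data Data.frame with the model variables.
#' @param tolerances Named vector of kernel standard deviations, predictor
#'   units, one per continuous predictor.
#' @param control An [npmr_control()].
#' @param sensitivity Compute per-predictor sensitivities (costs two extra
#'   estimation passes per predictor)?
#' @return Object of class `npmr`.
#' @seealso [npmr_search()], [predict.npmr()], [npmr_validate()],
#'   [npmr_sensitivity()]
#' @export
npmr <- function(formula, data, tolerances, control = npmr_control(),
                 sensitivity = TRUE) {
  tm <- parse_npmr_terms(formula, data)
  n <- length(tm$y)
  p <- length(tm$continuous) + length(tm$categorical)
  if (n < 10 * p) {
    stop("need >= 10 complete rows per predictor (have ", n, " for ", p, ")")
  }
  if (!all(tm$continuous %in% names(tolerances))) {
    stop("tolerances missing for: ",
         paste(setdiff(tm$continuous, names(tolerances)), collapse = ", "))
  }
  tolerances <- tolerances[tm$continuous]
  if (any(tolerances <= 0)) stop("tolerances must be positive")
  X <- as.matrix(tm$frame[tm$continuous])
  groups <- lapply(tm$frame[tm$categorical], as.character)
  ranges <- if (length(tm$continuous)) {
    apply(X, 2, function(v) diff(range(v)))
  } else numeric()
  if (any(ranges <= 0)) stop("zero-range continuous predictor")
  W <- npmr_weight_matrix(X, tolerances, groups)
  eng <- npmr_engine(tm$y, W, control$n_min_fraction)
  fit <- structure(list(
    call = match.call(), formula = formula, frame = tm$frame, y = tm$y,
    X = X, groups = groups, continuous = tm$continuous,
    categorical = tm$categorical, tolerances = tolerances, ranges = ranges,
    control = control, n_dropped = tm$n_dropped,
    estimates = eng$estimates, nstar = eng$nstar, su = eng$su,
    SU = eng$SU, N_ave = eng$N_ave, n_min = eng$n_min,
    prevalence = eng$prevalence, logB = eng$logB, B_ave = eng$B_ave,
    xR2 = eng$xR2, r = eng$r, chisq = eng$chisq), class = "npmr")
  if (sensitivity && length(tm$continuous)) {
    fit$sensitivity <- vapply(tm$continuous, function(j) {
      npmr_sensitivity(fit, j)
    }, numeric(1))
  }
  fit
}

#' Tolerance as a percentage of predictor range
#'
#' The tolerance (kernel standard deviation) divided by the predictor's
#' observed range, times 100; reported to one decimal place so tolerances
#' are comparable across predictors with different units.
#'
#' @param sigma Tolerance in predictor units.
#' @param range Predictor range (max - min), same units.
#' @return Percentage, rounded to 1 dp.
#' @export
tolerance_pct <- function(sigma, range) {
  if (any(range <= 0)) stop("range must be positive")
  round(100 * sigma / range, 1)
}

#' Sensitivity of the response to a predictor
#'
#' Each row's value of the predictor is nudged by plus/minus
#' `nudge_fraction * range`, estimates are recomputed (same neighbors,
#' leave-one-out), and the sensitivity is the mean absolute change in the
#' estimate, as a proportion of the response range (1 for a binary
#' response), divided by the nudge fraction. A sensitivity Q means a 20%
#' change in the predictor moves the estimated ARS likelihood by
#' about `Q * 20%`. Rows whose base or nudged estimate is missing are
#' skipped.
#'
#' @param fit An [npmr()] fit.
#' @param predictor Name of a continuous predictor in the model.
#' @param nudge_fraction Nudge size as a fraction of the predictor range;
#'   defaults to the fit's control setting.
#' @return Sensitivity Q (non-negative scalar).
#' @export
npmr_sensitivity <- function(fit, predictor,
                             nudge_fraction = fit$control$nudge_fraction) {
  if (!predictor %in% fit$continuous) stop("predictor not in model: ",
                                           predictor)
  if (!any(fit$su)) stop("fit has no populated estimates")
  delta <- nudge_fraction * fit$ranges[[predictor]]
  base <- fit$estimates
  diffs <- lapply(c(-delta, delta), function(d) {
    Xn <- fit$X
    Xn[, predictor] <- Xn[, predictor] + d
    W <- npmr_cross_weights(Xn, fit$X, fit$tolerances, fit$groups, fit$groups)
    diag(W) <- 0  # leave-one-out: the target never informs itself
    nstar <- unname(rowSums(W))
    yhat <- as.vector(W %*% fit$y)
    yhat <- ifelse(nstar >= fit$n_min & nstar > 0, yhat / nstar, NA_real_)
    abs(yhat - base)
  })
  d_all <- c(diffs[[1]], diffs[[2]])
  mean(d_all, na.rm = TRUE) / nudge_fraction
}

#' Predict ARS likelihood for new rows
#'
#' Estimates for new rows use the building rows as neighbors with the
#' building-fit tolerances (no leave-one-out: a new row identical to a
#' building row includes that row). The minimum neighborhood size is
#' re-resolved on the new rows (`n_min_fraction * N_ave` over the new
#' rows), so sparse regions of predictor space yield missing estimates.
#'
#' @param object An [npmr()] fit.
#' @param newdata Data.frame with the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of estimates in \[0, 1\] with `NA` for
#'   unpopulated neighborhoods, with attributes `nstar`, `n_min`, `N_ave`.
#' @export
predict.npmr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$estimates)
  miss <- setdiff(c(object$continuous, object$categorical), names(newdata))
  if (length(miss)) stop("newdata lacks predictors: ",
                         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(
    newdata[c(object$continuous, object$categorical)])
  Xn <- as.matrix(newdata[cc, object$continuous, drop = FALSE])
  gn <- lapply(newdata[cc, object$categorical, drop = FALSE], as.character)
  W <- npmr_cross_weights(Xn, object$X, object$tolerances, gn, object$groups)
  nstar <- unname(rowSums(W))
  nm <- resolve_n_min(nstar, object$control$n_min_fraction)
  yhat <- as.vector(W %*% object$y)
  yhat <- ifelse(nstar > 0, yhat / nstar, NA_real_)
  yhat[!nm$su] <- NA_real_
  out <- rep(NA_real_, nrow(newdata))
  out[cc] <- yhat
  ns <- rep(NA_real_, nrow(newdata)); ns[cc] <- nstar
  structure(out, nstar = ns, n_min = nm$n_min, N_ave = nm$N_ave)
}

#' Validate a fitted NPMR model on held-out rows
#'
#' Computes estimates for the held-out rows (building rows as neighbors,
#' building tolerances; see [predict.npmr()]) and the full statistic suite
#' (SU, N_ave, n_min, logB against the held-out prevalence, B_ave, xR2, r,
#' chi-square) plus per-predictor sensitivities on the held-out set.
#'
#' @param fit An [npmr()] fit (building set).
#' @param newdata Held-out rows incl. the response column.
#' @param sensitivity Compute validation-set sensitivities?
#' @return Object of class `npmr_validation`.
#' @export
npmr_validate <- function(fit, newdata, sensitivity = TRUE) {
  resp <- all.vars(fit$formula)[1]
  tm <- parse_npmr_terms(fit$formula, newdata)
  Xn <- as.matrix(tm$frame[fit$continuous])
  gn <- lapply(tm$frame[fit$categorical], as.character)
  W <- npmr_cross_weights(Xn, fit$X, fit$tolerances, gn, fit$groups)
  nstar <- unname(rowSums(W))
  nm <- resolve_n_min(nstar, fit$control$n_min_fraction)
  yhat <- as.vector(W %*% fit$y)
  yhat <- ifelse(nstar > 0, yhat / nstar, NA_real_)
  yhat[!nm$su] <- NA_real_
  stats <- npmr_fit_stats(tm$y, yhat, nm$su)
  out <- structure(c(list(
    estimates = yhat, y = tm$y, frame = tm$frame, nstar = nstar,
    su = nm$su, N_ave = nm$N_ave, n_min = nm$n_min,
    tolerances = fit$tolerances,
    ranges = if (length(fit$continuous)) {
      apply(Xn, 2, function(v) diff(range(v)))
    } else numeric(),
    n_dropped = tm$n_dropped), stats), class = "npmr_validation")
  if (sensitivity && length(fit$continuous)) {
    out$sensitivity <- vapply(fit$continuous, function(j) {
      delta <- fit$control$nudge_fraction * out$ranges[[j]]
      diffs <- lapply(c(-delta, delta), function(d) {
        X2 <- Xn; X2[, j] <- X2[, j] + d
        W2 <- npmr_cross_weights(X2, fit$X, fit$tolerances, gn, fit$groups)
        ns2 <- unname(rowSums(W2))
        e2 <- ifelse(ns2 >= nm$n_min & ns2 > 0,
                     as.vector(W2 %*% fit$y) / ns2, NA_real_)
        abs(e2 - yhat)
      })
      mean(c(diffs[[1]], diffs[[2]]), na.rm = TRUE) /
        fit$control$nudge_fraction
    }, numeric(1))
  }
  out
}

#' Response curve of a fitted NPMR model along one predictor
#'
#' Sweeps one predictor across its observed range with the other continuous
#' predictors held at their medians (categorical at the modal level) and
#' returns the model estimate along the sweep — the model's functional
#' response.
#'
#' @param fit An [npmr()] fit.
#' @param predictor Continuous predictor to sweep.
#' @param n Number of grid points.
#' @return Data.frame with the swept predictor and `estimate`.
#' @export
response_curve <- function(fit, predictor, n = 100) {
  if (!predictor %in% fit$continuous) stop("not a continuous predictor")
  grid <- seq(min(fit$X[, predictor]), max(fit$X[, predictor]),
              length.out = n)
  nd <- as.data.frame(lapply(fit$continuous, function(j) {
    if (j == predictor) grid else rep(stats::median(fit$X[, j]), n)
  }))
  names(nd) <- fit$continuous
  for (k in fit$categorical) {
    tab <- table(fit$groups[[k]])
    nd[[k]] <- names(tab)[which.max(tab)]
  }
  data.frame(stats::setNames(list(grid), predictor),
             estimate = as.numeric(predict(fit, nd)))
}

#' @export
print.npmr <- function(x, ...) {
  cat("NPMR local-mean model (binary response)\n")
  cat("Predictors:", paste(c(x$continuous, x$categorical), collapse = " x "),
      "\n")
  if (length(x$tolerances)) {
    cat("Tolerances:\n")
    for (j in x$continuous) {
      cat(sprintf("  %-10s %.4g (%s%% of range)\n", j, x$tolerances[[j]],
                  format(tolerance_pct(x$tolerances[[j]], x$ranges[[j]]))))
    }
  }
  cat(sprintf("SU = %d, N_ave = %.2f, n_min = %.2f\n", x$SU, x$N_ave,
              x$n_min))
  cat(sprintf("logB = %.2f, B_ave = %.2f, xR2 = %.2f, r = %.2f, chisq = %.2f\n",
              x$logB, x$B_ave, x$xR2, x$r, x$chisq))
  invisible(x)
}

#' @export
summary.npmr <- function(object, ...) {
  s <- list(
    predictors = c(object$continuous, object$categorical),
    tolerances = object$tolerances,
    tolerance_pct = if (length(object$tolerances)) {
      mapply(tolerance_pct, object$tolerances, object$ranges)
    } else numeric(),
    sensitivity = object$sensitivity,
    n = length(object$y), n_dropped = object$n_dropped,
    SU = object$SU, N_ave = object$N_ave, n_min = object$n_min,
    prevalence = object$prevalence, logB = object$logB,
    B_ave = object$B_ave, xR2 = object$xR2, r = object$r,
    chisq = object$chisq)
  class(s) <- "summary.npmr"
  s
}

#' @export
print.summary.npmr <- function(x, ...) {
  cat("NPMR model summary\n")
  cat(sprintf("  n = %d complete rows (%d dropped), SU = %d\n",
              x$n, x$n_dropped, x$SU))
  cat(sprintf("  N_ave = %.2f  n_min = %.2f  prevalence = %.2f\n",
              x$N_ave, x$n_min, x$prevalence))
  cat(sprintf("  logB = %.2f  B_ave = %.2f  xR2 = %.2f  r = %.2f  chisq = %.2f\n",
              x$logB, x$B_ave, x$xR2, x$r, x$chisq))
  if (length(x$tolerances)) {
    tab <- data.frame(tolerance = unlist(x$tolerances),
                      tol_pct = unlist(x$tolerance_pct))
    if (!is.null(x$sensitivity)) tab$sensitivity <- round(x$sensitivity, 2)
    print(tab)
  }
  invisible(x)
}

#' @export
coef.npmr <- function(object, ...) object$tolerances

#' @export
fitted.npmr <- function(object, ...) object$estimates

#' @export
residuals.npmr <- function(object, ...) object$y - object$estimates

#' @export
plot.npmr <- function(x, predictors = x$continuous, n = 100, ...) {
  old <- graphics::par(mfrow = c(1, max(1, length(predictors))))
  on.exit(graphics::par(old))
  for (j in predictors) {
    rc <- response_curve(x, j, n = n)
    graphics::plot(rc[[1]], rc$estimate, type = "l", xlab = j,
                   ylab = "Likelihood of ARS", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' @export
simulate.npmr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$estimates
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    ifelse(is.na(p), NA_integer_, stats::rbinom(length(p), 1, ifelse(is.na(p), 0, p)))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
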