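# Brute-force reference implementations, written independently of the
# package internals: plain double loops over rows, no matrix algebra.

# Gaussian multiplicative kernel weight between rows i and t of a table.
oracle_weight <- function(tab, t, i, sigmas, categorical = character()) {
  w <- 1
  for (j in names(sigmas)) {
    w <- w * exp(-((tab[[j]][t] - tab[[j]][i])^2) / (2 * sigmas[[j]]^2))
  }
  for (k in categorical) {
    w <- w * (tab[[k]][t] == tab[[k]][i])
  }
  w
}

# Leave-one-out estimate and neighborhood size at one row.
oracle_loo <- function(tab, y, t, sigmas, categorical = character(),
                       n_min = 0) {
  w <- numeric(0); yy <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    if (i == t) next
    w <- c(w, oracle_weight(tab, t, i, sigmas, categorical))
    yy <- c(yy, y[i])
  }
  nstar <- sum(w)
  est <- if (nstar >= n_min && nstar > 0) sum(w * yy) / nstar else NA_real_
  list(estimate = est, nstar = nstar)
}

# Non-LOO prediction for a new row against building rows.
oracle_predict <- function(newrow, tab, y, sigmas,
                           categorical = character(), n_min = 0) {
  w <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ww <- 1
    for (j in names(sigmas)) {
      ww <- ww * exp(-((newrow[[j]] - tab[[j]][i])^2) / (2 * sigmas[[j]]^2))
    }
    for (k in categorical) ww <- ww * (newrow[[k]] == tab[[k]][i])
    w[i] <- ww
  }
  nstar <- sum(w)
  if (nstar >= n_min && nstar > 0) sum(w * y) / nstar else NA_real_
}

# Term-by-term base-10 log likelihood ratio against the prevalence model.
oracle_logB <- function(y, est, eps) {
  pbar <- mean(y)
  total <- 0
  for (i in seq_along(y)) {
    e <- min(max(est[i], eps), 1 - eps)
    p <- min(max(pbar, eps), 1 - eps)
    li <- if (y[i] == 1) e else 1 - e
    l0 <- if (y[i] == 1) p else 1 - p
    total <- total + log10(li) - log10(l0)
  }
  total
}

# Pairwise-concordance AUC with half ties.
oracle_auc <- function(y, est) {
  pos <- est[y == 1]; neg <- est[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive TSS scan over every candidate cutoff.
oracle_best_cutoff <- function(y, est) {
  cuts <- sort(unique(c(0, est, 1)))
  best <- NULL
  for (ct in cuts) {
    pred <- est >= ct
    tpr <- sum(pred & y == 1) / sum(y == 1)
    tnr <- sum(!pred & y == 0) / sum(y == 0)
    tss <- tpr + tnr - 1
    if (is.null(best) || tss > best$tss) best <- list(cutoff = ct, tss = tss)
  }
  best
}

# Small deterministic modeling table with a smooth signal in x1.
toy_table <- function(n = 30, seed = 42) {
  set.seed(seed)
  tab <- data.frame(x1 = runif(n), x2 = runif(n),
                    id = sample(c("a", "b"), n, replace = TRUE))
  tab$y <- rbinom(n, 1, plogis(5 * (tab$x1 - 0.5)))
  if (length(unique(tab$y)) < 2) tab$y[1:2] <- c(0, 1)
  tab
}
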