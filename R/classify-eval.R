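# Binary conversion of continuous ARS-likelihood estimates at the
# TSS-maximizing cutoff, and the associated evaluation metric suite.

#' Scan cutoffs and find the TSS-maximizing one
#'
#' Candidate cutoffs are the unique estimate values plus 0 and 1; a row is
#' predicted present when its estimate is `>=` the cutoff. For each cutoff
#' the true positive rate and true negative rate give
#' `TSS = TPR + TNR - 1`; the lowest cutoff attaining the maximum TSS is
#' returned. Rows with missing estimates are excluded (count reported).
#'
#' @param y Binary response (0 = absence/transiting, 1 = presence/ARS).
#' @param estimates Continuous estimates in \[0, 1\].
#' @return List with `cutoff`, `tss_max`, `curve` (data.frame cutoff, tpr,
#'   tnr, tss) and `n_excluded`.
#' @export
scan_cutoffs <- function(y, estimates) {
  keep <- !is.na(estimates) & !is.na(y)
  n_excluded <- sum(!keep)
  y <- y[keep]; e <- estimates[keep]
  if (length(unique(y)) < 2) stop("both classes must be present")
  cuts <- sort(unique(c(0, e, 1)))
  npos <- sum(y == 1); nneg <- sum(y == 0)
  curve <- do.call(rbind, lapply(cuts, function(ct) {
    pred <- e >= ct
    tpr <- sum(pred & y == 1) / npos
    tnr <- sum(!pred & y == 0) / nneg
    data.frame(cutoff = ct, tpr = tpr, tnr = tnr, tss = tpr + tnr - 1)
  }))
  best <- which(curve$tss == max(curve$tss))[1]  # lowest cutoff on ties
  list(cutoff = curve$cutoff[best], tss_max = curve$tss[best],
       curve = curve, n_excluded = n_excluded)
}

#' Confusion matrix at a cutoff
#'
#' @param y Binary response.
#' @param estimates Continuous estimates (missing rows excluded).
#' @param cutoff Predict presence when `estimate >= cutoff`.
#' @return Object of class `confusion` with `tn`, `fp`, `fn`, `tp` and the
#'   number of excluded rows.
#' @export
confusion <- function(y, estimates, cutoff) {
  keep <- !is.na(estimates) & !is.na(y)
  y <- y[keep]; pred <- estimates[keep] >= cutoff
  structure(list(tn = sum(!pred & y == 0), fp = sum(pred & y == 0),
                 fn = sum(!pred & y == 1), tp = sum(pred & y == 1),
                 cutoff = cutoff, n_excluded = sum(!keep)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(observed = c("absence", "presence"),
                              predicted = c("absence", "presence")))
  print(m)
  if (!is.null(x$cutoff)) cat("cutoff:", x$cutoff, "\n")
  invisible(x)
}

as_confusion <- function(tn, fp, fn, tp, cutoff = NULL) {
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp, cutoff = cutoff,
                 n_excluded = 0L), class = "confusion")
}

#' Threshold-based classification metrics
#'
#' Rates derived from a confusion matrix: TPR, TNR, FPR, FNR,
#' `TSS = TPR + TNR - 1`, observed prevalence `(tp + fn) / total`,
#' predicted prevalence `(tp + fp) / total`, accuracy
#' `(tp + tn) / total`, and precision `tp / (tp + fp)`. Ratios with zero
#' denominators are reported as `NA`.
#'
#' @param cm A [confusion()] matrix.
#' @return List of class `classification_metrics`.
#' @export
confusion_metrics <- function(cm) {
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total <= 0) stop("empty confusion matrix")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  tpr <- div(cm$tp, cm$tp + cm$fn)
  tnr <- div(cm$tn, cm$tn + cm$fp)
  structure(list(
    cutoff = cm$cutoff, tpr = tpr, tnr = tnr,
    fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
    fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
    tss = tpr + tnr - 1,
    observed_prevalence = (cm$tp + cm$fn) / total,
    predicted_prevalence = (cm$tp + cm$fp) / total,
    accuracy = (cm$tp + cm$tn) / total,
    precision = div(cm$tp, cm$tp + cm$fp),
    total = total), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  v <- unlist(x[c("tss", "tpr", "tnr", "fpr", "fnr", "observed_prevalence",
                  "predicted_prevalence", "accuracy", "precision")])
  print(round(v, 3))
  invisible(x)
}

#' Threshold-free scores: AUC, RMSE, Brier
#'
#' AUC is the probability that a random presence receives a higher estimate
#' than a random absence (ties count one half); RMSE is
#' `sqrt(mean((y - estimate)^2))` and the Brier score is its square (the
#' mean squared residual). Missing estimates are excluded.
#'
#' @param y Binary response.
#' @param estimates Continuous estimates.
#' @return List with `auc` (`NA` when only one class is present), `rmse`,
#'   `brier`, `n`.
#' @export
score_metrics <- function(y, estimates) {
  keep <- !is.na(estimates) & !is.na(y)
  y <- y[keep]; e <- estimates[keep]
  auc <- if (length(unique(y)) < 2) NA_real_ else {
    # rank formulation of pairwise concordance with half-ties
    r <- rank(e)
    npos <- sum(y == 1); nneg <- sum(y == 0)
    (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  mse <- mean((y - e)^2)
  list(auc = auc, rmse = sqrt(mse), brier = mse, n = length(y))
}

#' Full classification report at the TSS-optimal cutoff
#'
#' Finds the TSS-maximizing cutoff ([scan_cutoffs()]), builds the confusion
#' matrix there, and combines the threshold metrics with AUC, RMSE and the
#' Brier score.
#'
#' @param y Binary response.
#' @param estimates Continuous estimates in \[0, 1\].
#' @param cutoff Optional fixed cutoff; defaults to the TSS-optimal one.
#' @return Object of class `classification_report`.
#' @export
classification_report <- function(y, estimates, cutoff = NULL) {
  sc <- if (is.null(cutoff)) scan_cutoffs(y, estimates) else NULL
  cutoff <- cutoff %||% sc$cutoff
  cm <- confusion(y, estimates, cutoff)
  out <- c(list(confusion = cm), confusion_metrics(cm),
           score_metrics(y, estimates),
           list(tss_curve = sc$curve, n_excluded = cm$n_excluded))
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification at cutoff %.3f (TSS = %.2f)\n", x$cutoff,
              x$tss))
  print(x$confusion)
  cat(sprintf("prevalence obs/pred = %.2f/%.2f  accuracy = %.2f  precision = %.2f\n",
              x$observed_prevalence, x$predicted_prevalence, x$accuracy,
              x$precision))
  cat(sprintf("AUC = %.2f  RMSE = %.2f  Brier = %.2f  (n = %d, %d excluded)\n",
              x$auc, x$rmse, x$brier, x$n, x$n_excluded))
  invisible(x)
}

#' Reference confusion matrices from the blue-whale ARS analysis
#'
#' The four published confusion matrices for the binary conversion of the
#' estimated likelihood of ARS — environmental and purely spatial NPMR
#' models, each on the building (positive-NPGO years) and validation
#' (negative-NPGO years) sets. Cells are ordered true-absence predicted
#' absent (tn), true-absence predicted present (fp), true-presence
#' predicted absent (fn), true-presence predicted present (tp). Useful as
#' fixtures for the metric suite.
#'
#' @return Named list of four [confusion()] objects:
#'   `environmental_building`, `environmental_validation`,
#'   `spatial_building`, `spatial_validation`.
#' @export
ref_confusion_tables <- function() {
  list(
    environmental_building   = as_confusion(tn = 149, fp = 77,
                                            fn = 401, tp = 665),
    environmental_validation = as_confusion(tn = 17,  fp = 47,
                                            fn = 12,  tp = 112),
    spatial_building         = as_confusion(tn = 113, fp = 45,
                                            fn = 404, tp = 696),
    spatial_validation       = as_confusion(tn = 83,  fp = 39,
                                            fn = 59,  tp = 146)
  )
}
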