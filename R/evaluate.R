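#' Sensitivity, specificity and precision from confusion counts
#'
#' Computes sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)` and
#' precision `TP/(TP+FP)`, all counted in IDRs. A ratio with a zero
#' denominator is reported as 0 and flagged in `undefined` rather than
#' propagating NaN, so term-averaged summary tables stay computable and the
#' degenerate cells auditable.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; alternatively pass a
#'   single named vector/list as `tp`.
#' @return List with `sensitivity`, `specificity`, `precision` and
#'   `undefined` (character vector naming flagged metrics).
#' @export
#' @examples
#' confusion_metrics(tp = 5, fp = 0, tn = 10, fn = 5)
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp); fp <- cc$fp; tn <- cc$tn; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion_metrics: counts must be non-negative")
  if (sum(counts) == 0) stop("confusion_metrics: all counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else 0
  undefined <- character(0)
  if (tp + fn == 0) undefined <- c(undefined, "sensitivity")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision   = ratio(tp, tp + fp),
       undefined   = undefined)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' summary of a binary confusion matrix in `[-1, 1]` (0 is chance level).
#' When any factor of the denominator is zero the MCC is defined as 0, the
#' usual convention for degenerate margins.
#'
#' @inheritParams confusion_metrics
#' @return Numeric scalar in `[-1, 1]`.
#' @export
#' @examples
#' mcc(tp = 6, fp = 1, tn = 8, fn = 2)  # 46 / sqrt(5040)
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && (is.list(tp) || length(tp) == 4L)) {
    cc <- as.list(tp); fp <- cc$fp; tn <- cc$tn; fn <- cc$fn; tp <- cc$tp
  }
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Per-term metric table from cross-validated confusion counts
#'
#' Attaches sensitivity, specificity, precision and MCC (at the 0.5
#' operating point the counts were produced with) to each evaluated term of
#' a [cv_all_terms()] result; skipped terms keep NA metrics.
#'
#' @param confusion data.frame from [cv_all_terms()].
#' @return The input with columns sensitivity, specificity, precision, mcc
#'   appended.
#' @export
term_metrics <- function(confusion) {
  n <- nrow(confusion)
  sens <- spec <- prec <- mccs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!identical(confusion$status[i], "ok")) next
    m <- confusion_metrics(confusion$tp[i], confusion$fp[i],
                           confusion$tn[i], confusion$fn[i])
    sens[i] <- m$sensitivity; spec[i] <- m$specificity; prec[i] <- m$precision
    mccs[i] <- mcc(confusion$tp[i], confusion$fp[i],
                   confusion$tn[i], confusion$fn[i])
  }
  confusion$sensitivity <- sens
  confusion$specificity <- spec
  confusion$precision <- prec
  confusion$mcc <- mccs
  confusion
}

#' Average metrics over all evaluated terms
#'
#' Unweighted means of sensitivity, specificity and precision (and MCC) over
#' the terms a family's classifiers could be evaluated on, the per-family
#' summary used to compare feature families. Skipped terms are excluded and
#' counted.
#'
#' @param metrics data.frame from [term_metrics()] (one family).
#' @return List with `n_terms`, `n_skipped`, and mean `sensitivity`,
#'   `specificity`, `precision`, `mcc`.
#' @export
average_over_terms <- function(metrics) {
  ok <- metrics[metrics$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L) stop("average_over_terms: no evaluated terms")
  list(n_terms = nrow(ok),
       n_skipped = sum(metrics$status != "ok"),
       sensitivity = mean(ok$sensitivity),
       specificity = mean(ok$specificity),
       precision = mean(ok$precision),
       mcc = mean(ok$mcc))
}

#' Is a term classifier performing better than random?
#'
#' A random classifier has equal true and false positive rates, so a
#' classifier is better than random exactly when its sensitivity exceeds its
#' false positive rate `1 - specificity` (strictly; a point on the random
#' line is not better than random).
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`; `sensitivity` may
#'   also be a list with both fields (e.g. a [confusion_metrics()] result).
#' @return Logical scalar.
#' @export
better_than_random <- function(sensitivity, specificity = NULL) {
  if (is.list(sensitivity)) {
    specificity <- sensitivity$specificity
    sensitivity <- sensitivity$sensitivity
  }
  sensitivity > 1 - specificity
}

#' Sample a held-out test set of IDRs
#'
#' Uniform, seeded sample without replacement; the remainder is the training
#' set. Default size 105.
#'
#' @param idr_ids Character vector of candidate ids.
#' @param n Test-set size (default 105).
#' @param seed Integer seed.
#' @return List with `test` and `train` id vectors.
#' @export
sample_test_set <- function(idr_ids, n = 105L, seed = 1L) {
  if (n >= length(idr_ids))
    stop("sample_test_set: n must be smaller than the dataset")
  test <- with_seed(seed, idr_ids[sample.int(length(idr_ids), n)])
  list(test = test, train = setdiff(idr_ids, test))
}

#' Per-IDR precision-recall analysis over a probability grid
#'
#' For each held-out IDR r and threshold p, the predicted term set is every
#' term scored at probability p or higher; against the IDR's known
#' (ancestor-expanded) term set this yields `TP[r,p]` (known terms
#' predicted), `FP[r,p]` (predicted but not known) and `FN[r,p]` (known but
#' not predicted), hence per-IDR recall `rho = TP/(TP+FN)` and precision
#' `pi = TP/(TP+FP)` (0 when the IDR predicts nothing at p). The curve
#' reports, per threshold: overall precision `N_correct/N_total`, where
#' `N_correct` counts IDRs predicting at least one known term at p or
#' higher; average recall, the mean of `rho` over all test IDRs; and the
#' mean per-IDR precision as a companion quantity.
#'
#' @param predictions data.frame with columns idr_id, term_id, probability
#'   (from [predict_test_set()]).
#' @param known_terms Named list: idr id -> expanded known term set,
#'   covering every test IDR.
#' @param test_ids Character vector of test IDR ids (defaults to the ids in
#'   `predictions`).
#' @param prob_grid Thresholds (default `seq(0, 1, by = 0.05)`).
#' @return Object of class `pr_curve`: list with `points` (data.frame p,
#'   overall_precision, average_recall, mean_idr_precision, n_correct) and
#'   `test_set_size`.
#' @export
pr_analysis <- function(predictions, known_terms,
                        test_ids = unique(predictions$idr_id),
                        prob_grid = seq(0, 1, by = 0.05)) {
  if (length(test_ids) == 0L) stop("pr_analysis: empty test set")
  if (!all(test_ids %in% names(known_terms)))
    stop("pr_analysis: every test IDR needs a known-term set")
  if (any(prob_grid < 0 | prob_grid > 1))
    stop("pr_analysis: prob_grid must lie in [0, 1]")
  pred_by_idr <- split(predictions[, c("term_id", "probability")],
                       factor(predictions$idr_id, levels = test_ids))
  n_total <- length(test_ids)
  pts <- lapply(prob_grid, function(p) {
    rho <- pi_r <- numeric(n_total)
    correct <- logical(n_total)
    for (i in seq_len(n_total)) {
      id <- test_ids[i]
      pr <- pred_by_idr[[id]]
      predicted <- if (is.null(pr)) character(0) else
        pr$term_id[pr$probability >= p]
      known <- known_terms[[id]]
      tp <- length(intersect(known, predicted))
      fp <- length(setdiff(predicted, known))
      fn <- length(setdiff(known, predicted))
      rho[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
      pi_r[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      correct[i] <- tp >= 1L
    }
    data.frame(p = p,
               overall_precision = sum(correct) / n_total,
               average_recall = mean(rho),
               mean_idr_precision = mean(pi_r),
               n_correct = sum(correct))
  })
  structure(list(points = do.call(rbind, pts), test_set_size = n_total),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d test IDRs, %d thresholds\n",
              x$test_set_size, nrow(x$points)))
  print(utils::head(x$points, 5))
  invisible(x)
}

#' Plot a precision-recall curve
#'
#' Base-graphics plot of overall precision against average recall across the
#' probability grid.
#'
#' @param x A `pr_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  pts <- x$points[order(x$points$average_recall), ]
  plot(pts$average_recall, pts$overall_precision, type = "b", pch = 16,
       xlab = "Average recall", ylab = "Overall precision",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  invisible(x)
}
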