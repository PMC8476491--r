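#' Confusion counts from truth and predicted labels
#'
#' @param truth,predicted equal-length binary label vectors
#'   ("deleterious"/"benign", logical, or 0/1); deleterious is the
#'   positive class.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(truth, predicted) {
  t <- normaliseLabels(truth)
  p <- normaliseLabels(predicted)
  if (length(t) != length(p)) stop("truth and predicted differ in length")
  new("ConfusionCounts",
      tp = sum(t & p), tn = sum(!t & !p),
      fp = sum(!t & p), fn = sum(t & !p))
}

#' Point metrics of a confusion matrix
#'
#' Accuracy, Matthews correlation coefficient, precision, specificity,
#' sensitivity (recall), F-score and negative predictive value, by the
#' standard formulas. Degenerate denominators fall back to 0 (MCC with a
#' zero factor, precision/NPV with an empty predicted class, F-score with
#' precision + recall = 0), keeping reports total.
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return named numeric vector with elements \code{accuracy, mcc,
#'   precision, specificity, sensitivity, f_score, npv}.
#' @export
pointMetrics <- function(counts) {
  tp <- as.numeric(counts@tp); tn <- as.numeric(counts@tn)
  fp <- as.numeric(counts@fp); fn <- as.numeric(counts@fn)
  n <- tp + tn + fp + fn
  safe <- function(num, den) if (den == 0) 0 else num / den
  acc <- safe(tp + tn, n)
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  prec <- safe(tp, tp + fp)
  spec <- safe(tn, fp + tn)
  sens <- safe(tp, tp + fn)
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  npv <- safe(tn, tn + fn)
  c(accuracy = acc, mcc = mcc, precision = prec, specificity = spec,
    sensitivity = sens, f_score = f, npv = npv)
}

#' ROC-AUC by the rank (Mann-Whitney U) definition
#'
#' The probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, ties counting one half. \code{scores} are
#' deleteriousness scores: higher means more deleterious, so pass
#' \code{-z} when ranking by z-score.
#'
#' @param scores numeric deleteriousness scores.
#' @param truth binary truth labels (deleterious = positive).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, truth) {
  t <- normaliseLabels(truth)
  nPos <- sum(t); nNeg <- sum(!t)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present for ROC-AUC")
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[t]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' PR-AUC as step-wise average precision
#'
#' Sweeps the decision threshold over the distinct score values in
#' descending order and accumulates precision times the recall increment
#' (a step-function integral, avoiding optimistic linear interpolation in
#' precision-recall space).
#'
#' @inheritParams rocAuc
#' @return average precision in [0, 1].
#' @export
prAuc <- function(scores, truth) {
  t <- normaliseLabels(truth)
  nPos <- sum(t)
  if (nPos == 0) stop("positives must be present for PR-AUC")
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; lastRecall <- 0
  for (s in thr) {
    sel <- scores >= s
    tp <- sum(t & sel)
    prec <- tp / sum(sel)
    recall <- tp / nPos
    ap <- ap + (recall - lastRecall) * prec
    lastRecall <- recall
  }
  ap
}

#' Full metrics report
#'
#' The nine evaluation metrics in the conventional report order: ROC-AUC
#' and PR-AUC from the continuous scores, the seven point metrics from
#' the predicted labels.
#'
#' @param scores deleteriousness scores (higher = more deleterious).
#' @param truth binary truth labels.
#' @param predicted binary predicted labels.
#' @return named numeric vector of the nine metrics.
#' @export
metricsReport <- function(scores, truth, predicted) {
  pm <- pointMetrics(confusionCounts(truth, predicted))
  c(roc_auc = rocAuc(scores, truth), pr_auc = prAuc(scores, truth),
    pm[c("accuracy", "mcc", "precision", "specificity", "sensitivity",
         "f_score", "npv")])
}

# round half up at k decimals (printed-table convention)
roundHalfUp <- function(x, k) floor(x * 10^k + 0.5) / 10^k

#' Reconstruct integer confusion counts from printed rounded rates
#'
#' Exhaustively searches the integer confusion matrices with the stated
#' class sizes whose sensitivity, specificity, precision and NPV all
#' round (half-up, 3 decimals) to the printed values, and returns the
#' unique solution. Used to check that a published metrics row is
#' internally consistent.
#'
#' @param sensitivity,specificity,precision,npv printed rates (3 d.p.).
#' @param nPos,nNeg class sizes.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
reconstructConfusion <- function(sensitivity, specificity, precision, npv,
                                 nPos, nNeg) {
  if (nPos < 1 || nNeg < 1) stop("class sizes must be positive")
  tpCand <- which(roundHalfUp((0:nPos) / nPos, 3) == sensitivity) - 1L
  tnCand <- which(roundHalfUp((0:nNeg) / nNeg, 3) == specificity) - 1L
  if (length(tpCand) == 0L || length(tnCand) == 0L)
    stop("no integer counts reproduce the printed sensitivity/specificity")
  grid <- expand.grid(tp = tpCand, tn = tnCand)
  grid$fn <- nPos - grid$tp
  grid$fp <- nNeg - grid$tn
  precOk <- with(grid, (tp + fp) > 0 &
                   roundHalfUp(tp / (tp + fp), 3) == precision)
  npvOk <- with(grid, (tn + fn) > 0 &
                  roundHalfUp(tn / (tn + fn), 3) == npv)
  sol <- grid[precOk & npvOk, , drop = FALSE]
  if (nrow(sol) == 0L)
    stop("printed rates are mutually inconsistent: no integer solution")
  if (nrow(sol) > 1L)
    stop("printed rates are ambiguous: ", nrow(sol), " integer solutions (",
         paste(apply(sol, 1, paste, collapse = "/"), collapse = "; "), ")")
  new("ConfusionCounts", tp = as.integer(sol$tp), tn = as.integer(sol$tn),
      fp = as.integer(sol$fp), fn = as.integer(sol$fn))
}

#' Write a single-row metrics report as tab-separated text
#'
#' @param metrics named vector from \code{\link{metricsReport}}.
#' @param path output path.
#' @export
writeMetricsReport <- function(metrics, path) {
  tab <- as.data.frame(as.list(metrics))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
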