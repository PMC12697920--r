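#' Confusion counts for epoch-by-epoch comparison
#'
#' Sleep (1) is the positive class; polysomnography is the actual class and
#' actigraphy the predicted class, so a true positive is a minute both score
#' as sleep.
#'
#' @param pred predicted binary series ([epoch_series()] or 0/1 vector).
#' @param actual ground-truth binary series of the same length.
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, actual) {
  p <- if (inherits(pred, "epoch_series")) pred$values else as.numeric(pred)
  a <- if (inherits(actual, "epoch_series")) actual$values else as.numeric(actual)
  if (length(p) != length(a))
    stop("predicted and actual series differ in length", call. = FALSE)
  if (!all(p %in% c(0, 1)) || !all(a %in% c(0, 1)))
    stop("expected binary labels", call. = FALSE)
  c(tp = sum(p == 1 & a == 1), fp = sum(p == 1 & a == 0),
    tn = sum(p == 0 & a == 0), fn = sum(p == 0 & a == 1))
}

#' Agreement metrics from confusion counts
#'
#' Computes accuracy, sensitivity (sleep detection), specificity (wake
#' detection), precision, F1, Cohen's kappa and the Matthews correlation
#' coefficient.  Kappa corrects observed agreement for the chance agreement
#' implied by the marginals; MCC is the Pearson correlation of the two
#' binary label vectors.  Metrics with a degenerate denominator (e.g. MCC
#' when the predictor is constant) are reported as `NA` with the reason in
#' the `undefined` attribute, never silently as 0.
#'
#' @param counts confusion counts from [confusion()] (named vector with
#'   `tp`, `fp`, `tn`, `fn`), or a predicted series (then `actual` must be
#'   given).
#' @param actual optional ground-truth series; when supplied, counts are
#'   computed via [confusion()].
#' @return named numeric vector with elements `n`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `kappa`, `mcc`;
#'   attribute `undefined` names metrics with degenerate denominators.
#' @examples
#' agreement_metrics(c(tp = 40, fp = 10, tn = 40, fn = 10))
#' @export
agreement_metrics <- function(counts, actual = NULL) {
  if (!is.null(actual)) counts <- confusion(counts, actual)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  undefined <- character(0)

  accuracy <- (tp + tn) / n
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity (no actual sleep)"); NA_real_ }
  specificity <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "specificity (no actual wake)"); NA_real_ }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision (no predicted sleep)"); NA_real_ }
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else {
    undefined <- c(undefined, "f1 (degenerate)"); NA_real_ }

  po <- accuracy
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else {
    if (po == 1) 1 else {
      undefined <- c(undefined, "kappa (chance agreement 1)"); NA_real_ }
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else {
    undefined <- c(undefined, "mcc (constant margin)"); NA_real_ }

  out <- c(n = n, accuracy = accuracy, sensitivity = sensitivity,
           specificity = specificity, precision = precision, f1 = f1,
           kappa = kappa, mcc = mcc)
  attr(out, "undefined") <- undefined
  out
}

#' ROC curve and AUC from raw scores
#'
#' Full threshold sweep over the unique raw score values, with sleep as the
#' positive class.  For algorithms whose decision rule points toward sleep
#' at low scores (Cole-Kripke, UCSD, Kripke 2010, Philips) scores are
#' negated before the sweep (`orientation = "lower_is_sleep"`); Sadeh's PS
#' is used as-is.  AUC is the trapezoidal integral of TPR over FPR, which
#' equals the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores raw-score [epoch_series()] or numeric vector.
#' @param actual binary ground truth of the same length.
#' @param orientation `"lower_is_sleep"` or `"higher_is_sleep"`; see
#'   [score_orientation()].
#' @return object of class `roc_result`: list with `thresholds`
#'   (descending, on the oriented scale), `tpr`, `fpr`, `auc`, `n_pos`,
#'   `n_neg`.  With single-class truth, `auc` is `NA` with attribute
#'   `undefined`.
#' @export
roc_auc <- function(scores, actual,
                    orientation = c("lower_is_sleep", "higher_is_sleep")) {
  orientation <- match.arg(orientation)
  s <- if (inherits(scores, "epoch_series")) scores$values else
    as.numeric(scores)
  a <- if (inherits(actual, "epoch_series")) actual$values else
    as.numeric(actual)
  if (length(s) != length(a))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("expected binary truth", call. = FALSE)
  u <- if (orientation == "lower_is_sleep") -s else s
  n_pos <- sum(a == 1); n_neg <- sum(a == 0)

  thr <- c(Inf, sort(unique(u), decreasing = TRUE))
  # predict sleep when oriented score >= threshold
  ord <- order(u, decreasing = TRUE)
  us <- u[ord]; as_ <- a[ord]
  cum_tp <- cumsum(as_ == 1)
  cum_fp <- cumsum(as_ == 0)
  last_of_value <- which(c(us[-1] != us[-length(us)], TRUE))
  tpr <- c(0, cum_tp[last_of_value] / max(n_pos, 1))
  fpr <- c(0, cum_fp[last_of_value] / max(n_neg, 1))

  res <- list(thresholds = thr, tpr = tpr, fpr = fpr,
              n_pos = n_pos, n_neg = n_neg, orientation = orientation)
  if (n_pos == 0 || n_neg == 0) {
    res$auc <- NA_real_
    attr(res, "undefined") <- "auc (single-class truth)"
  } else {
    res$auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %s over %d thresholds (%d sleep / %d wake)\n",
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              length(x$thresholds), x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l",
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Epoch-weighted pooled summary of per-participant metrics
#'
#' Pools per-participant agreement metrics weighting each participant by the
#' number of compared epochs, so longer nights contribute proportionally.
#' The weighted SD uses the weight-normalized form
#' `sqrt(sum(w * (x - m)^2) / sum(w))`; a single participant therefore has
#' SD 0.
#'
#' @param values numeric vector of per-participant metric values (`NA`s are
#'   dropped with their weights).
#' @param weights positive weights (epochs per participant).
#' @return named vector `mean`, `sd`, `n_used`.
#' @export
weighted_summary <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights differ in length", call. = FALSE)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; weights <- weights[keep]
  if (!length(values) || sum(weights) <= 0)
    stop("no usable values / zero total weight", call. = FALSE)
  if (any(weights < 0)) stop("weights must be positive", call. = FALSE)
  m <- sum(weights * values) / sum(weights)
  s <- sqrt(sum(weights * (values - m)^2) / sum(weights))
  c(mean = m, sd = s, n_used = length(values))
}
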