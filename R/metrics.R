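# Classification metrics: Gini impurity, sensitivity/specificity, Matthews
# correlation coefficient, and the trapezoidal ROC AUC.

#' Gini impurity of a node
#'
#' `1 - sum(p_i^2)` for class proportions `p`. Zero for a pure node,
#' `1 - 1/J` at the uniform distribution over `J` classes.
#'
#' @param p numeric vector of class proportions (must sum to 1).
#' @return Gini impurity in `[0, 1 - 1/length(p)]`.
#' @export
gini <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  1 - sum(p^2)
}

#' Confusion counts at a score threshold
#'
#' The positive class is BBBP+ (label 1). Scores exactly at the threshold
#' classify as positive.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y <- as.integer(y_true)
  pred <- as.integer(scores >= threshold)
  c(tp = sum(pred == 1L & y == 1L),
    fp = sum(pred == 1L & y == 0L),
    tn = sum(pred == 0L & y == 0L),
    fn = sum(pred == 0L & y == 1L))
}

mcc_from_counts <- function(cc) {
  tp <- as.numeric(cc["tp"]); fp <- as.numeric(cc["fp"])
  tn <- as.numeric(cc["tn"]); fn <- as.numeric(cc["fn"])
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)  # degenerate fold convention
  (tp * tn - fp * fn) / den
}

#' Trapezoidal ROC AUC
#'
#' Area under the receiver operating characteristic computed by the
#' trapezoidal rule over the empirical ROC, with tied scores handled by
#' threshold averaging (each distinct score is one threshold step). For
#' tie-free scores this equals the Mann-Whitney statistic divided by
#' `n_pos * n_neg`.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores numeric scores; larger means more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  y <- as.integer(y_true)
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # step through distinct thresholds, accumulating trapezoids
  steps <- which(!duplicated(s))
  bounds <- c(steps - 1L, length(s))
  cum_tp <- cumsum(y == 1L)
  cum_fp <- cumsum(y == 0L)
  tpr <- c(0, cum_tp[bounds[-1]] / n1)
  fpr <- c(0, cum_fp[bounds[-1]] / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Classification metrics report
#'
#' Sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` for the BBBP+
#' positive class, Matthews correlation coefficient (0 by convention when
#' its denominator vanishes), and trapezoidal ROC AUC.
#'
#' @inheritParams confusion_counts
#' @return a `bbb_metrics` object: list with `sn`, `sp`, `mcc`, `auc`,
#'   `confusion` and `threshold`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- as.integer(y_true)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both classes must be present in y_true", call. = FALSE)
  }
  cc <- confusion_counts(y, scores, threshold)
  structure(list(
    sn = as.numeric(cc["tp"] / (cc["tp"] + cc["fn"])),
    sp = as.numeric(cc["tn"] / (cc["tn"] + cc["fp"])),
    mcc = mcc_from_counts(cc),
    auc = roc_auc(y, scores),
    confusion = cc,
    threshold = threshold), class = "bbb_metrics")
}

#' @export
print.bbb_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("SN %.1f%%  SP %.1f%%  MCC %.*f  AUC %.*f\n",
              100 * x$sn, 100 * x$sp, digits, x$mcc, digits, x$auc))
  invisible(x)
}
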