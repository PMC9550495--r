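POSITIVE_CLASS <- "CWM"
NEGATIVE_CLASS <- "FWM"
METRIC_NAMES <- c("acc", "sn", "ppv", "fscore", "auc")

#' Confusion counts with CWM as the positive class
#'
#' @param truth,predicted character/factor vectors of `"CWM"`/`"FWM"`
#'   labels, equal length.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @examples
#' confusionCounts(c("CWM", "CWM", "FWM"), c("CWM", "FWM", "FWM"))
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (!length(truth)) stop("need at least one observation")
  ok <- c(POSITIVE_CLASS, NEGATIVE_CLASS)
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    stop("labels must be '", POSITIVE_CLASS, "' or '", NEGATIVE_CLASS, "'")
  c(TP = sum(truth == POSITIVE_CLASS & predicted == POSITIVE_CLASS),
    FP = sum(truth == NEGATIVE_CLASS & predicted == POSITIVE_CLASS),
    TN = sum(truth == NEGATIVE_CLASS & predicted == NEGATIVE_CLASS),
    FN = sum(truth == POSITIVE_CLASS & predicted == NEGATIVE_CLASS))
}

#' Classification metrics for one evaluation
#'
#' Computes accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, positive
#' predictive value `TP/(TP+FP)`, F-score `2TP/(2TP+FP+FN)` and, when
#' per-row positive-class scores are supplied, the AUC as the probability
#' that a random positive outranks a random negative (ties counted one
#' half). Ratios with a zero denominator are reported as `NA`, never
#' coerced to 0; AUC is `NA` with a warning when only one class is present.
#'
#' @param TP,FP,TN,FN confusion counts (or `TP` may be a named vector from
#'   [confusionCounts()]).
#' @param scores optional numeric positive-class scores, one per row.
#' @param truth label vector matching `scores` (required with `scores`).
#' @return one-row data.frame with columns `acc`, `sn`, `ppv`, `fscore`,
#'   `auc`.
#' @export
classificationMetrics <- function(TP, FP = NULL, TN = NULL, FN = NULL,
                                  scores = NULL, truth = NULL) {
  if (length(TP) == 4L && !is.null(names(TP))) {
    FP <- TP[["FP"]]; TN <- TP[["TN"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  n <- TP + FP + TN + FN
  if (n < 1) stop("empty confusion table")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth)) stop("truth labels are required to compute the AUC")
    auc <- rankAuc(scores, truth)
  }
  data.frame(acc = (TP + TN) / n,
             sn = safe(TP, TP + FN),
             ppv = safe(TP, TP + FP),
             fscore = safe(2 * TP, 2 * TP + FP + FN),
             auc = auc)
}

#' Rank-statistic AUC
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks.
#'
#' @param scores numeric positive-class scores.
#' @param truth matching `"CWM"`/`"FWM"` labels.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when one class is
#'   absent.
#' @export
rankAuc <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- truth == POSITIVE_CLASS
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
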