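# Confusion-matrix metrics used to train and select imbalanced QSAR
# classifiers: the Matthews correlation coefficient (the optimization
# penalty) and balanced accuracy.

#' Confusion-matrix counts from label and prediction vectors
#'
#' @param truth,pred vectors coercible to 0/1 integers.
#' @return named list with elements `TP`, `TN`, `FP`, `FN`.
#' @export
confusionCounts <- function(truth, pred) {
  truth <- as.integer(as.character(truth))
  pred <- as.integer(as.character(pred))
  stopifnot(length(truth) == length(pred), all(truth %in% 0:1),
            all(pred %in% 0:1))
  list(TP = sum(truth == 1L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FP = sum(truth == 0L & pred == 1L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), in [-1, 1].
#' When any factor of the denominator is zero (a degenerate predictor or a
#' single-class sample) the coefficient is defined as 0, which keeps the
#' optimization objective finite.
#'
#' @param cm a list with elements `TP`, `TN`, `FP`, `FN` (e.g. from
#'   [confusionCounts()]); alternatively give the four counts as named
#'   arguments.
#' @param TP,TN,FP,FN the counts when given separately.
#' @return the coefficient as a single number.
#' @examples
#' mccScore(TP = 5, TN = 5, FP = 0, FN = 0)   # 1
#' mccScore(TP = 25, TN = 25, FP = 25, FN = 25) # 0
#' @export
mccScore <- function(cm, TP = NULL, TN = NULL, FP = NULL, FN = NULL) {
  if (!missing(cm) && is.list(cm)) {
    TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  } else if (!missing(cm) && is.null(TP)) TP <- cm
  stopifnot(all(c(TP, TN, FP, FN) >= 0), TP + TN + FP + FN >= 1)
  TP <- as.double(TP); TN <- as.double(TN)
  FP <- as.double(FP); FN <- as.double(FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Balanced accuracy
#'
#' The mean of sensitivity and specificity,
#' 0.5 * (TP/(TP+FN) + TN/(TN+FP)). Undefined (an error) when a class is
#' absent from the truth.
#'
#' @inheritParams mccScore
#' @return balanced accuracy in [0, 1].
#' @examples
#' balancedAccuracy(TP = 40, FN = 10, TN = 30, FP = 20) # 0.7
#' @export
balancedAccuracy <- function(cm, TP = NULL, TN = NULL, FP = NULL, FN = NULL) {
  if (!missing(cm) && is.list(cm)) {
    TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  } else if (!missing(cm) && is.null(TP)) TP <- cm
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  if (TP + FN < 1 || TN + FP < 1)
    stop("balanced accuracy is undefined when a class is absent")
  0.5 * (TP / (TP + FN) + TN / (TN + FP))
}
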