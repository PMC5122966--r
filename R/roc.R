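#' ROC curve and AUC
#'
#' Computes the receiver operating characteristic obtained by sweeping a
#' discriminating threshold over the scores, and its area. The AUC equals
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half (equivalently, the
#' trapezoidal area under the ROC curve); it is computed by the midrank
#' (Mann-Whitney) identity.
#'
#' @param scores numeric scores (higher = more mutant-like).
#' @param labels logical or 0/1 vector; \code{TRUE}/1 marks the positive
#'   (mutant) class. Both classes must be present.
#' @return a list with \code{auc} (scalar) and \code{roc}, a data.frame of
#'   \code{threshold}, \code{fpr}, \code{tpr} points from (0,0) to (1,1).
#' @examples
#' rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  tpr <- cumsum(l)[keep] / n1
  fpr <- cumsum(!l)[keep] / n0
  roc <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}
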