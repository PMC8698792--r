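# Regression metrics for affinity prediction: MSE, concordance index with a
# three-valued step function on prediction differences, Pearson and Spearman
# correlation.

.checkPaired <- function(y_true, y_pred) {
  stopifnot(is.numeric(y_true), is.numeric(y_pred))
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred)))
    stop("scores must be finite")
}

#' Mean squared error
#'
#' @param y_true,y_pred numeric vectors of equal length >= 1.
#' @return mean of squared differences.
#' @examples
#' mseScore(c(1, 3), c(2, 2))  # 1
#' @export
mseScore <- function(y_true, y_pred) {
  .checkPaired(y_true, y_pred)
  if (length(y_true) == 0) stop("empty input")
  mean((y_true - y_pred)^2)
}

#' Three-valued step function
#'
#' Returns 0 for negative input, 0.5 at zero, 1 for positive input; used to
#' score prediction-difference ties in the concordance index.
#'
#' @param x finite numeric vector.
#' @return numeric vector of 0, 0.5 or 1.
#' @export
stepH <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  ifelse(x < 0, 0, ifelse(x > 0, 1, 0.5))
}

#' Concordance index
#'
#' Over all ordered pairs whose true affinities differ, the mean of
#' [stepH()] applied to the difference of the corresponding predictions
#' (taken larger-true minus smaller-true): 1 for each correctly ordered
#' pair, 0.5 for each predicted tie, 0 otherwise. Pairs tied in the true
#' value are excluded from both the sum and the normalizer.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return concordance index in `[0, 1]`.
#' @examples
#' concordanceIndex(c(1, 2), c(5, 5))  # 0.5
#' @export
concordanceIndex <- function(y_true, y_pred) {
  .checkPaired(y_true, y_pred)
  dtrue <- outer(y_true, y_true, `-`)
  sel <- dtrue > 0                      # ordered pairs with delta_x > delta_y
  Z <- sum(sel)
  if (Z == 0) stop("concordance index undefined: all true values are equal")
  dpred <- outer(y_pred, y_pred, `-`)
  sum(stepH(dpred[sel])) / Z
}

#' Pearson correlation coefficient
#'
#' Sample covariance over the product of sample standard deviations.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2, non-constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearsonCor <- function(y_true, y_pred) {
  .checkPaired(y_true, y_pred)
  if (length(y_true) < 2) stop("need at least 2 observations")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("correlation undefined for a constant vector")
  stats::cov(y_true, y_pred) / (stats::sd(y_true) * stats::sd(y_pred))
}

#' Spearman rank correlation
#'
#' In the tie-free case uses the classical rank-difference formula
#' `1 - 6 sum(d^2) / (n (n^2 - 1))`; with ties, average ranks are used and
#' the Pearson coefficient of the rank vectors is returned (the
#' rank-difference formula assumes distinct ranks).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2, non-constant.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearmanCor <- function(y_true, y_pred) {
  .checkPaired(y_true, y_pred)
  n <- length(y_true)
  if (n < 2) stop("need at least 2 observations")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(y_true)
  ry <- rank(y_pred)
  if (anyDuplicated(rx) || anyDuplicated(ry))
    return(pearsonCor(rx, ry))
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

#' All evaluation metrics at once
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return named list with elements `mse`, `ci`, `pearson`, `spearman`.
#' @export
evaluatePredictions <- function(y_true, y_pred) {
  list(mse = mseScore(y_true, y_pred),
       ci = concordanceIndex(y_true, y_pred),
       pearson = pearsonCor(y_true, y_pred),
       spearman = spearmanCor(y_true, y_pred))
}
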