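# Performance metrics for simulation studies: ROC/PRC areas from
# inclusion scores, power at a specificity floor, out-of-sample
# predictive error and coverage, and edge-level graph recovery.

#' ROC and precision-recall areas under the curve
#'
#' Curves are traced by sweeping a cutoff over the inclusion scores
#' (marginal inclusion probabilities for the Bayesian fits); areas use
#' the trapezoid rule.  Ties in the scores are handled by grouping (the
#' ROC area then equals the Mann-Whitney statistic with midranks).
#'
#' @param scores numeric scores, higher = more evidence for inclusion.
#' @param truth 0/1 vector of true inclusion status.
#' @return list with \code{roc_auc} and \code{prc_auc}.
#' @export
roc_prc_auc <- function(scores, truth) {
  truth <- as.integer(truth != 0)
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  if (np == 0 || nn == 0) stop("truth must contain positives and negatives")
  r <- rank(scores)
  roc <- (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
  # PRC by descending unique thresholds
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(1 - t)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]
  fp <- fp[last]
  rec <- c(0, tp / np)
  prec <- c(1, tp / (tp + fp))
  prc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(roc_auc = roc, prc_auc = prc)
}

#' Sensitivity at a specificity floor
#'
#' Scans the nested models obtained by descending score cutoffs and
#' returns the sensitivity of the largest model whose specificity is at
#' least \code{spec_level} (tied scores enter together).
#'
#' @param scores numeric inclusion scores.
#' @param truth 0/1 vector of true status.
#' @param spec_level required specificity (default 0.9).
#' @return sensitivity in [0, 1].
#' @export
power_at_fdr <- function(scores, truth, spec_level = 0.9) {
  truth <- as.integer(truth != 0)
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  if (np == 0 || nn == 0) stop("truth must contain positives and negatives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(1 - t)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]
  fp <- fp[last]
  sens <- c(0, tp / np)
  spec <- c(1, (nn - fp) / nn)
  max(sens[spec >= spec_level])
}

#' Out-of-sample predictive metrics
#'
#' @param pred_mean,pred_lower,pred_upper posterior predictive means and
#'   interval bounds for the test samples.
#' @param y_test held-out responses.
#' @return list with \code{mspe} (mean squared prediction error) and
#'   \code{coverage95} (fraction of test responses inside the interval).
#' @export
predictive_metrics <- function(pred_mean, pred_lower, pred_upper, y_test) {
  n <- length(y_test)
  stopifnot(length(pred_mean) == n, length(pred_lower) == n,
            length(pred_upper) == n)
  list(mspe = mean((pred_mean - y_test)^2),
       coverage95 = mean(y_test >= pred_lower & y_test <= pred_upper))
}

#' Edge-level graph recovery metrics
#'
#' Sensitivity and specificity over the unordered pairs i < j, plus the
#' Frobenius norm of the precision estimation error when the matrices
#' are supplied.
#'
#' @param estimated,truth p x p symmetric 0/1 adjacencies.
#' @param omega_hat,omega_true optional precision matrices.
#' @return list with \code{sensitivity}, \code{specificity} and
#'   \code{fnorm} (NA when no precision matrices given).
#' @export
graph_metrics <- function(estimated, truth, omega_hat = NULL,
                          omega_true = NULL) {
  if (!all(dim(estimated) == dim(truth))) stop("dimension mismatch")
  ut <- upper.tri(truth)
  e <- estimated[ut] != 0
  t <- truth[ut] != 0
  sens <- if (any(t)) mean(e[t]) else NA_real_
  spec <- if (any(!t)) mean(!e[!t]) else NA_real_
  fn <- NA_real_
  if (!is.null(omega_hat) && !is.null(omega_true)) {
    if (!all(dim(omega_hat) == dim(omega_true))) stop("dimension mismatch")
    fn <- sqrt(sum((omega_hat - omega_true)^2))
  }
  list(sensitivity = sens, specificity = spec, fnorm = fn)
}
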