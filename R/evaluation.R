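# Segmentation and screening metrics: Dice overlap, parameter MAE, ROC/AUC
# and the Youden operating point.

#' Dice coefficient between two binary masks
#'
#' `2 TP / (2 TP + FP + FN)` from pixelwise comparison. Two empty masks
#' score 1.0 (perfect-agreement convention), so structures legitimately
#' absent from both prediction and reference do not poison means.
#'
#' @param pred_raster,truth_raster Binary matrices of equal dimensions.
#' @return Value in \[0, 1\].
#' @export
dice <- function(pred_raster, truth_raster) {
  if (!identical(dim(pred_raster), dim(truth_raster))) {
    abort_fourcv("shape", "masks have different dimensions")
  }
  p <- pred_raster > 0; t <- truth_raster > 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0) return(1.0)
  2 * tp / (2 * tp + fp + fn)
}

#' Mean Dice over paired mask sets for one structure
#'
#' Pairs with an empty prediction but a non-empty reference (the structure
#' could not be segmented) are excluded from the mean and counted in the
#' report rather than silently dropped.
#'
#' @param pred_sets,truth_sets Lists of `mask_set`s, paired by position.
#' @param structure One of [MASK_STRUCTURES].
#' @return List with `mean_dice`, `n_used`, `n_excluded`, `per_image`.
#' @export
mean_dice <- function(pred_sets, truth_sets, structure) {
  structure <- match.arg(structure, MASK_STRUCTURES)
  if (length(pred_sets) != length(truth_sets) || length(pred_sets) == 0) {
    abort_fourcv("empty_input", "need equal-length, non-empty mask-set lists")
  }
  excluded <- logical(length(pred_sets))
  vals <- rep(NA_real_, length(pred_sets))
  for (i in seq_along(pred_sets)) {
    p <- pred_sets[[i]]$masks[[structure]]
    t <- truth_sets[[i]]$masks[[structure]]
    if (sum(p) == 0 && sum(t) > 0) {
      excluded[i] <- TRUE
    } else {
      vals[i] <- dice(p, t)
    }
  }
  if (all(excluded)) abort_fourcv("empty_input", "all pairs excluded")
  list(mean_dice = mean(vals[!excluded]), n_used = sum(!excluded),
       n_excluded = sum(excluded), per_image = vals)
}

#' Mean absolute error between paired estimates and truths
#'
#' @param estimates,truths Equal-length numeric vectors, in the parameter's
#'   native units (percentage points for CTAR, degrees for the axis).
#' @return Non-negative scalar.
#' @export
mae <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    abort_fourcv("pairing", "estimate and truth vectors differ in length")
  }
  mean(abs(estimates - truths))
}

#' ROC curve with trapezoidal AUC
#'
#' Operating points are produced by sweeping thresholds over the distinct
#' score values (higher score = more suspicious). The trapezoidal AUC equals
#' the Mann-Whitney pair statistic (ties counted 1/2); that identity is the
#' package's cross-check oracle.
#'
#' @param scores Numeric suspicion scores.
#' @param labels Logical or 0/1 case labels (TRUE/1 = positive).
#' @return Object of class `roc_curve`: data frame `points` (threshold, fpr,
#'   tpr) and scalar `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort_fourcv("degenerate_labels", "need at least one positive and one negative label")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.3f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' AUC by exhaustive pair counting (Mann-Whitney statistic)
#'
#' Independent of the trapezoidal computation in [roc_curve()]; used as a
#' consistency oracle.
#'
#' @param scores,labels As in [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc_pair_statistic <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) {
    abort_fourcv("degenerate_labels", "need both classes")
  }
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

#' Youden operating point of an ROC curve
#'
#' The point maximising TPR - FPR; ties break toward the lower
#' false-positive rate.
#'
#' @param curve `roc_curve`.
#' @return One-row data frame (threshold, fpr, tpr, youden).
#' @export
youden_point <- function(curve) {
  pts <- curve$points
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  best <- best[which.min(pts$fpr[best])]
  out <- pts[best, , drop = FALSE]
  out$youden <- j[best]
  rownames(out) <- NULL
  out
}
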