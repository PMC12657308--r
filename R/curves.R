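#' ROC curve and trapezoidal AUROC
#'
#' Builds the threshold-annotated ROC polyline (one vertex per distinct
#' score, from the all-negative to the all-positive classification) and
#' integrates it by the trapezoid rule — which equals the Mann–Whitney
#' probability of correct ranking with ties counted 1/2. The DeLong
#' confidence interval is attached via pROC.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary truth labels (both classes required).
#' @param level Confidence level for the DeLong interval.
#' @param ci Compute the DeLong CI? Default `TRUE`.
#' @return A list of class `roc_curve`: `points` (threshold, fpr, tpr),
#'   `auroc`, `ci_low`, `ci_high`, `ci_method = "delong"`.
#' @export
roc_and_auc <- function(scores, labels, level = 0.95, ci = TRUE) {
  y <- as_binary(labels, "labels")
  if (length(unique(y)) < 2) {
    stop("both classes required for a ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  npos <- sum(y); nneg <- sum(!y)
  tpr <- vapply(thr, function(t) sum(scores[y] >= t) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!y] >= t) / nneg, numeric(1))
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  ci_pair <- c(NA_real_, NA_real_)
  if (ci) {
    r <- suppressMessages(pROC::roc(response = y, predictor = scores,
                                    quiet = TRUE, direction = "<",
                                    levels = c(FALSE, TRUE)))
    ci_pair <- as.numeric(pROC::ci.auc(r, method = "delong",
                                       conf.level = level))[c(1, 3)]
  }
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auroc = auroc, ci_low = ci_pair[1], ci_high = ci_pair[2],
                 ci_method = "delong"),
            class = "roc_curve")
}

#' Precision–recall curve and step-wise AUPRC
#'
#' Precision/recall at every distinct score threshold (score >= threshold
#' is positive). The area uses the step-wise rule
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over increasing recall — no linear
#' interpolation between PR points, which is known to be optimistic. The
#' confidence interval is a seeded stratified bootstrap (resampling
#' positives and negatives separately).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary truth labels (both classes required).
#' @param level Confidence level.
#' @param boot Number of bootstrap draws for the CI (0 disables it).
#' @param seed Bootstrap seed.
#' @return A list of class `pr_curve`: `points` (threshold, recall,
#'   precision), `auprc`, `ci_low`, `ci_high`,
#'   `ci_method = "stratified bootstrap"`.
#' @export
pr_and_auc <- function(scores, labels, level = 0.95, boot = 2000L,
                       seed = 1L) {
  y <- as_binary(labels, "labels")
  if (length(unique(y)) < 2) {
    stop("both classes required for a PR curve", call. = FALSE)
  }
  pts <- pr_points(scores, y)
  auprc <- auprc_step(pts)
  ci_pair <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(seed)
    pos <- which(y); neg <- which(!y)
    stat <- vapply(seq_len(boot), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
      auprc_step(pr_points(scores[i], y[i]))
    }, numeric(1))
    ci_pair <- unname(stats::quantile(stat,
                                      c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(list(points = pts, auprc = auprc,
                 ci_low = ci_pair[1], ci_high = ci_pair[2],
                 ci_method = "stratified bootstrap"),
            class = "pr_curve")
}

pr_points <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y)
  recall <- numeric(length(thr)); precision <- numeric(length(thr))
  for (k in seq_along(thr)) {
    called <- scores >= thr[k]
    tp <- sum(called & y)
    recall[k] <- tp / npos
    precision[k] <- tp / sum(called)
  }
  data.frame(threshold = thr, recall = recall, precision = precision)
}

# step-wise area: precision held at the value attained when recall first
# reaches each level (thresholds descending => recall non-decreasing)
auprc_step <- function(pts) {
  r <- c(0, pts$recall)
  sum(diff(r) * pts$precision)
}

#' Export a curve as CSV (threshold, x, y)
#'
#' @param curve A `roc_curve` or `pr_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  pts <- curve$points
  if (inherits(curve, "roc_curve")) {
    out <- data.frame(threshold = pts$threshold, x = pts$fpr, y = pts$tpr)
  } else {
    out <- data.frame(threshold = pts$threshold, x = pts$recall,
                      y = pts$precision)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
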