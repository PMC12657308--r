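#' Confusion matrix from predicted and true binary labels
#'
#' @param predicted,truth Equal-length binary (logical or 0/1) vectors.
#' @return A list of class `confusion_matrix` with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length", call. = FALSE)
  }
  p <- as_binary(predicted, "predicted")
  t <- as_binary(truth, "truth")
  cm(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop("`", what, "` must be logical or 0/1", call. = FALSE)
}

cm <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("negative confusion-matrix cell", call. = FALSE)
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp %d  fp %d  fn %d  tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Wilson score (or Clopper–Pearson) interval for a proportion
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param level Confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return Numeric `c(low, high)`, both in \[0, 1\].
#' @export
proportion_ci <- function(numerator, denominator, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (denominator <= 0 || numerator < 0 || numerator > denominator) {
    stop("need 0 <= numerator <= denominator, denominator > 0",
         call. = FALSE)
  }
  if (method == "clopper-pearson") {
    ci <- stats::binom.test(numerator, denominator,
                            conf.level = level)$conf.int
    return(c(low = ci[1], high = ci[2]))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- numerator / denominator
  n <- denominator
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Classification metrics with confidence intervals
#'
#' Sensitivity, specificity, PPV, NPV, F1 and accuracy from a confusion
#' matrix, each with a Wilson score interval on its defining count ratio
#' (F1 = 2tp / (2tp + fp + fn) is treated as such a ratio; the interval
#' is an approximation and carries the same method tag). A metric whose
#' denominator is zero is flagged `undefined` and reported as `NA` —
#' never silently coerced to 0.
#'
#' @param x A `confusion_matrix`.
#' @param level Confidence level for the intervals.
#' @param ci_method Passed to [proportion_ci()].
#' @return A data.frame of class `metric_set` with columns `metric`,
#'   `estimate`, `ci_low`, `ci_high`, `undefined`, and attributes
#'   `ci_method` and `confusion`.
#' @examples
#' classification_metrics(reconstruct_matrix_from_rates(0.793, 0.962, 29, 133))
#' @export
classification_metrics <- function(x, level = 0.95,
                                   ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(x, "confusion_matrix"))
  n <- x$tp + x$fp + x$fn + x$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  defs <- list(
    sensitivity = c(x$tp, x$tp + x$fn),
    specificity = c(x$tn, x$tn + x$fp),
    ppv         = c(x$tp, x$tp + x$fp),
    npv         = c(x$tn, x$tn + x$fn),
    f1          = c(2 * x$tp, 2 * x$tp + x$fp + x$fn),
    accuracy    = c(x$tp + x$tn, n)
  )
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]; den <- defs[[m]][2]
    if (den == 0) {
      data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, undefined = TRUE)
    } else {
      ci <- proportion_ci(num, den, level, ci_method)
      data.frame(metric = m, estimate = num / den, ci_low = ci[["low"]],
                 ci_high = ci[["high"]], undefined = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_method") <- ci_method
  attr(out, "confusion") <- x
  class(out) <- c("metric_set", class(out))
  out
}

#' Extract one metric's point estimate from a metric set
#'
#' @param metrics A `metric_set`.
#' @param name Metric name (`"sensitivity"`, ..., `"accuracy"`).
#' @return The point estimate (possibly `NA` if undefined).
#' @export
metric_value <- function(metrics, name) {
  metrics$estimate[match(name, metrics$metric)]
}

#' Reconstruct an integer confusion matrix from printed rates
#'
#' Bridges published sensitivity/specificity tables back to counts:
#' `tp = round(sens * n_pos)`, `tn = round(spec * n_neg)`, with `fn` and
#' `fp` as the complements. The attribute `roundtrip` reports the
#' recomputed rates next to the inputs so inconsistent printed grids are
#' visible rather than silently accepted.
#'
#' @param sensitivity,specificity Printed rates in \[0, 1\].
#' @param n_pos,n_neg Class sizes (> 0).
#' @return A `confusion_matrix` with attribute `roundtrip`.
#' @examples
#' reconstruct_matrix_from_rates(0.793, 0.962, 29, 133)  # tp 23, tn 128
#' @export
reconstruct_matrix_from_rates <- function(sensitivity, specificity,
                                          n_pos, n_neg) {
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be > 0", call. = FALSE)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  out <- cm(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  attr(out, "roundtrip") <- data.frame(
    rate = c("sensitivity", "specificity"),
    input = c(sensitivity, specificity),
    recomputed = c(tp / n_pos, tn / n_neg)
  )
  out
}

#' Cohen's kappa between two binary label vectors
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' the expected agreement from the marginal products. When the expected
#' agreement is 1 (both raters constant), kappa is undefined and `NA` is
#' returned with a warning.
#'
#' @param labels_a,labels_b Equal-length binary vectors.
#' @return Kappa in \[-1, 1\], or `NA` if undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  a <- as_binary(labels_a, "labels_a")
  b <- as_binary(labels_b, "labels_b")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("expected agreement is 1; kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Published rule-based classifier rates (gold-standard evaluation)
#'
#' Printed sensitivity/specificity (with the full published metric grid)
#' of the three rule-based advanced-CKD classifiers evaluated on a
#' manually chart-reviewed hospital cohort of 29 CKD and 133 non-CKD
#' patients. Shipped as reference inputs for the reconstruction bridge
#' ([reconstruct_matrix_from_rates()]) and the worked examples; the
#' underlying patient data are not redistributable.
#'
#' @return A data.frame with one row per classifier (`egfr_index`,
#'   `discharge_summary`, `icd10`) and the printed `sens`, `spec`, `ppv`,
#'   `npv`, `f1`, `acc`, plus `n_pos = 29`, `n_neg = 133`.
#' @export
reference_rule_metrics <- function() {
  data.frame(
    classifier = c("egfr_index", "discharge_summary", "icd10"),
    sens = c(0.793, 0.862, 0.931),
    spec = c(0.962, 0.684, 0.872),
    ppv  = c(0.821, 0.373, 0.614),
    npv  = c(0.955, 0.958, 0.983),
    f1   = c(0.807, 0.521, 0.740),
    acc  = c(0.932, 0.716, 0.883),
    n_pos = 29L, n_neg = 133L,
    stringsAsFactors = FALSE
  )
}
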