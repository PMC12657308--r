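#' Rule-based CKD call from the index-stay eGFR series
#'
#' Default aggregation `max_lt` flags a patient when every index-stay
#' eGFR — i.e. the maximum — is strictly below the threshold (60
#' mL/min/1.73 m² for advanced CKD). `any_lt` flags when any value dips
#' below, `all_lt` is an alias of `max_lt` kept for explicitness; all
#' three are shipped because published rule wordings are ambiguous about
#' which was used.
#'
#' @param egfr Numeric eGFR values of the index stay (>= 1 value).
#' @param threshold eGFR threshold, default 60.
#' @param aggregation `"max_lt"`, `"any_lt"` or `"all_lt"`.
#' @return Logical CKD call.
#' @export
rule_egfr_index <- function(egfr, threshold = 60,
                            aggregation = c("max_lt", "any_lt", "all_lt")) {
  aggregation <- match.arg(aggregation)
  if (!length(egfr)) stop("empty eGFR series", call. = FALSE)
  switch(aggregation,
         max_lt = max(egfr) < threshold,
         all_lt = all(egfr < threshold),
         any_lt = any(egfr < threshold))
}

#' Rule-based CKD call from ICD-10 billing codes
#'
#' @param codes Character vector of a patient's ICD-10 codes (possibly
#'   empty).
#' @param prefixes Code prefixes that count as advanced CKD; default
#'   N18.3/N18.4/N18.5/N18.9.
#' @return `TRUE` iff any code starts with a configured prefix.
#' @export
rule_icd10 <- function(codes, prefixes = c("N18.3", "N18.4", "N18.5", "N18.9")) {
  if (!length(codes)) return(FALSE)
  any(vapply(prefixes, function(p) any(startsWith(codes, p)), logical(1)))
}

#' Rule-based CKD call from the discharge-summary flag
#'
#' Identity passthrough of the binary CKD mention extracted from the
#' discharge summary; a missing flag is treated as `FALSE` with a
#' warning, never silently.
#'
#' @param flag Logical scalar or `NA`/`NULL`.
#' @return Logical CKD call.
#' @export
rule_discharge_summary <- function(flag) {
  if (is.null(flag) || length(flag) == 0 || is.na(flag)) {
    warning("missing discharge-summary flag treated as FALSE", call. = FALSE)
    return(FALSE)
  }
  isTRUE(as.logical(flag))
}

#' Random train/test split
#'
#' Splits indices into disjoint, exhaustive train (floor of
#' `fraction * n`) and test sets, reproducibly under `seed`; optional
#' stratification keeps class proportions in both parts.
#'
#' @param labels Binary label vector (length n >= 5).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify by label? Default `FALSE` (a plain random
#'   split).
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, fraction = 0.8, seed = 1L,
                             stratify = FALSE) {
  n <- length(labels)
  if (n < 5) stop("need at least 5 observations to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1 (both sets non-empty)",
         call. = FALSE)
  }
  set.seed(seed)
  if (stratify) {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, floor(fraction * length(idx))))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, floor(fraction * n)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a logistic CKD model on a feature profile
#'
#' Unpenalised maximum-likelihood logistic regression (the published HIB
#' models use 3–5 predictors, where plain ML is the appropriate choice).
#' Zero-variance columns are dropped with a warning. Complete or
#' quasi-complete separation is detected (glm's fitted-probability
#' warning) and flagged; with `separation = "ridge"` the model is refit
#' with a light ridge penalty instead, and the fallback is recorded in
#' the model metadata.
#'
#' @param features Data.frame of numeric predictors (a
#'   [build_feature_matrix()] output; a `patient_id` column is ignored).
#' @param labels Logical/0-1 outcome vector.
#' @param profile Profile name stored in the model.
#' @param separation `"flag"` (default) or `"ridge"`.
#' @param seed Seed recorded in the metadata (the fit itself is
#'   deterministic).
#' @return An object of class `hib_logistic`: feature names, intercept,
#'   coefficients, standard errors, decision `cutoff` (initialised to
#'   0.5; calibrate with [select_cutoff_youden()]), convergence and
#'   separation flags.
#' @export
fit_logistic <- function(features, labels, profile = "admissionHIB",
                         separation = c("flag", "ridge"), seed = NA_integer_) {
  separation <- match.arg(separation)
  x <- features[, setdiff(names(features), "patient_id"), drop = FALSE]
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; cannot fit", call. = FALSE)
  }
  if (any(!vapply(x, is.numeric, logical(1)))) {
    stop("all features must be numeric", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(x)))) {
    stop("features contain non-finite values", call. = FALSE)
  }
  keep <- vapply(x, function(v) stats::var(v) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(names(x)[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  dat <- cbind(.y = y, x)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("algorithm did not converge", conditionMessage(w))) {
        # reported via the `converged` field instead of console noise
        invokeRestart("muffleWarning")
      }
    }
  )
  used_ridge <- FALSE
  if (separated && separation == "ridge") {
    xm <- as.matrix(x)
    if (ncol(xm) < 2) {
      # glmnet needs >= 2 columns; pad with a zero column and drop it
      xm <- cbind(xm, .pad = 0)
    }
    g <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                        lambda = 1e-3, standardize = TRUE)
    co <- as.numeric(stats::coef(g))
    names(co) <- rownames(stats::coef(g))
    co <- co[names(co) != ".pad"]
    model <- list(intercept = co[1], coefficients = co[-1],
                  std_errors = rep(NA_real_, length(co) - 1))
    used_ridge <- TRUE
  } else {
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    model <- list(intercept = unname(co[1]), coefficients = co[-1],
                  std_errors = se[-1])
  }
  if (separated && separation == "flag") {
    warning("(quasi-)complete separation detected; coefficients flagged",
            call. = FALSE)
  }
  structure(list(
    profile = profile,
    feature_names = colnames(x),
    intercept = model$intercept,
    coefficients = stats::setNames(as.numeric(model$coefficients), colnames(x)),
    std_errors = stats::setNames(as.numeric(model$std_errors), colnames(x)),
    cutoff = 0.5,
    converged = if (used_ridge) TRUE else fit$converged,
    separation = separated,
    ridge_fallback = used_ridge,
    training = list(n = length(y), seed = seed)
  ), class = "hib_logistic")
}

#' @export
print.hib_logistic <- function(x, ...) {
  cat(sprintf("<hib_logistic> profile %s (n = %d%s)\n", x$profile,
              x$training$n,
              if (x$separation) ", separation flagged" else ""))
  cat(sprintf("  cutoff %.3f; intercept %.4f\n", x$cutoff, x$intercept))
  for (f in x$feature_names) {
    cat(sprintf("  %-28s %+ .4f\n", f, x$coefficients[[f]]))
  }
  invisible(x)
}

#' Youden-index cutoff selection
#'
#' Chooses the decision cutoff maximising J = sensitivity + specificity
#' − 1 under the "score >= cutoff is positive" convention. Candidates are
#' the midpoints between consecutive distinct scores plus the lowest
#' score (the all-positive classification); ties are resolved toward the
#' lowest such threshold. If every score is identical, J = 0 everywhere
#' and that score is returned with a warning.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary truth labels (both classes required).
#' @return The selected cutoff, with attribute `youden` (the achieved J).
#' @export
select_cutoff_youden <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) {
    stop("both classes required to calibrate a cutoff", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("all scores identical; Youden index is 0 everywhere",
            call. = FALSE)
    return(structure(u, youden = 0))
  }
  cand <- c(u[1], (u[-1] + u[-length(u)]) / 2)
  npos <- sum(y); nneg <- sum(!y)
  j <- vapply(cand, function(t) {
    sum(scores[y] >= t) / npos + sum(scores[!y] < t) / nneg - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]  # lowest threshold among ties
  structure(cand[best], youden = j[best])
}

#' Score and classify with a fitted logistic HIB model
#'
#' @param object A `hib_logistic` model.
#' @param features Feature data.frame containing every model feature
#'   (missing ones raise an error naming them).
#' @param ... Unused.
#' @return A data.frame with `score` (inverse-logit of the linear
#'   predictor) and `label` (`score >= cutoff`; a score exactly at the
#'   cutoff is positive).
#' @export
predict.hib_logistic <- function(object, features, ...) {
  missing <- setdiff(object$feature_names, names(features))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(features[, object$feature_names, drop = FALSE])
  lp <- object$intercept + drop(xm %*% object$coefficients)
  score <- stats::plogis(lp)
  data.frame(score = score, label = score >= object$cutoff)
}

#' Fit the reference random-forest labeler (historyCKD profile)
#'
#' The silver-standard labeler: a seeded probability forest on the full
#' historyCKD profile, mirroring the role of the validated random-forest
#' phenotyping algorithm that assigns CKD status where manual chart
#' review is infeasible. Deterministic given the seed.
#'
#' @param features historyCKD feature data.frame.
#' @param labels Binary outcome.
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 500).
#' @return An object of class `hib_forest` wrapping the ranger fit, with
#'   `cutoff` (default 0.5) and metadata.
#' @export
fit_reference_forest <- function(features, labels, seed = 1L,
                                 num_trees = 500L) {
  x <- features[, setdiff(names(features), "patient_id"), drop = FALSE]
  y <- factor(as.numeric(labels), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("labels contain a single class; cannot fit", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = x, y = y, probability = TRUE, num.trees = num_trees,
    seed = seed, num.threads = 1
  )
  structure(list(profile = "historyCKD", fit = fit,
                 feature_names = colnames(x), cutoff = 0.5,
                 training = list(n = length(y), seed = seed,
                                 num_trees = num_trees)),
            class = "hib_forest")
}

#' @export
predict.hib_forest <- function(object, features, ...) {
  missing <- setdiff(object$feature_names, names(features))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pr <- stats::predict(object$fit,
                       data = features[, object$feature_names, drop = FALSE],
                       num.threads = 1)$predictions
  score <- pr[, "1"]
  data.frame(score = score, label = score >= object$cutoff)
}

#' Serialise a logistic HIB model to a JSON manifest
#'
#' @param model A `hib_logistic`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    profile = model$profile, feature_names = model$feature_names,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    cutoff = as.numeric(model$cutoff),
    conventions = list(positive = "score >= cutoff"),
    training = model$training
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a logistic HIB model from its JSON manifest
#'
#' @param path Manifest path written by [write_model_json()].
#' @return A `hib_logistic` model.
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    profile = m$profile, feature_names = m$feature_names,
    intercept = m$intercept,
    coefficients = stats::setNames(as.numeric(unlist(m$coefficients)),
                                   names(m$coefficients)),
    std_errors = stats::setNames(rep(NA_real_, length(m$feature_names)),
                                 m$feature_names),
    cutoff = m$cutoff, converged = TRUE, separation = FALSE,
    ridge_fallback = FALSE, training = m$training
  ), class = "hib_logistic")
}

#' Published reference cutoffs of the HIB algorithms
#'
#' Decision cutoffs of the original logistic HIB models (0.586 for
#' historyHIB, 0.478 for admissionHIB), derived from the development
#' cohort's training data via the Youden index. Shipped for workflow
#' parity and documentation; every executable model in this package is
#' refit on synthetic data, since the development cohort itself is not
#' redistributable.
#'
#' @return Named numeric vector.
#' @export
reference_cutoffs <- function() {
  c(historyHIB = 0.586, admissionHIB = 0.478)
}
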