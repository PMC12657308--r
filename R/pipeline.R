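#' In-memory analysis tables from a generated bundle
#'
#' Adapter between the generator and the cohort builder when no disk
#' round-trip is wanted; the result is identical to flattening the
#' written bundle.
#'
#' @param bundle An `ehr_bundle` from [generate_cohort()].
#' @return An `ehr_tables` list.
#' @export
bundle_tables <- function(bundle) {
  assemble_tables(bundle$patients, bundle$stays, bundle$observations,
                  bundle$conditions, bundle$summaries,
                  extra_rejected = 0L, unknown_types = 0L)
}

#' Read an experiment configuration from YAML
#'
#' The file has sections `simulation` (arguments of
#' [simulation_config()]), `cohort` (`profile`, `history_start`), `model`
#' (`profiles`, `split_fraction`, `seed`, `stratify`) and `evaluation`
#' (`ci_level`, `bootstrap`). Missing entries fall back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return A list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  experiment_config(simulation = raw$simulation, cohort = raw$cohort,
                    model = raw$model, evaluation = raw$evaluation)
}

#' Assemble and validate an experiment configuration
#'
#' @param simulation Named list of [simulation_config()] arguments (or an
#'   already-built `sim_config`).
#' @param cohort List with `profile` ("gold"/"silver") and
#'   `history_start`.
#' @param model List with `profiles` (subset of admissionHIB, historyHIB,
#'   historyCKD), `split_fraction`, `seed`, `stratify`.
#' @param evaluation List with `ci_level` and `bootstrap` draws.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = list(), cohort = list(),
                              model = list(), evaluation = list()) {
  sim <- if (inherits(simulation, "sim_config")) simulation else {
    simulation <- simulation %||% list()
    if (!is.null(simulation$window_start)) {
      simulation$window_start <- as.Date(simulation$window_start)
    }
    if (!is.null(simulation$window_end)) {
      simulation$window_end <- as.Date(simulation$window_end)
    }
    do.call(simulation_config, simulation)
  }
  cohort <- utils::modifyList(
    list(profile = "gold", history_start = as.Date("2011-01-01")),
    cohort %||% list())
  cohort$history_start <- as.Date(cohort$history_start)
  model <- utils::modifyList(
    list(profiles = c("admissionHIB", "historyHIB"), split_fraction = 0.8,
         seed = sim$seed, stratify = FALSE), model %||% list())
  evaluation <- utils::modifyList(list(ci_level = 0.95, bootstrap = 500L),
                                  evaluation %||% list())
  structure(list(simulation = sim, cohort = cohort, model = model,
                 evaluation = evaluation),
            class = "experiment_config")
}

#' Run a full training experiment on a synthetic cohort
#'
#' Simulate, build the cohort (inclusion/exclusion under the configured
#' profile), assemble features for each requested model profile, split
#' 80/20, fit the logistic model on the training part, calibrate the
#' Youden cutoff on training scores only, and evaluate on the held-out
#' test part (metrics with confidence intervals, ROC and PR curves).
#' Everything is seeded, so a fixed configuration reproduces the report
#' exactly.
#'
#' @param config An `experiment_config` (or path to its YAML file).
#' @param output_dir Optional directory for artifacts (config snapshot,
#'   model manifests, metric JSON, curve CSVs, exclusion log).
#' @return A list of class `experiment_result`: `models`, `metrics`,
#'   `curves` (per profile), `split`, `cohort` (included ids, exclusions,
#'   flow counts), `labels` (test-set truth), and `config`.
#' @export
run_training_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$simulation
  bundle <- generate_cohort(sim)
  tables <- bundle_tables(bundle)
  linked <- link_stays(tables$stays, sim$window_start, sim$window_end,
                       config$cohort$history_start)
  tables$stays <- linked$stays
  inc <- apply_inclusion_criteria(tables, config$cohort$profile)
  truth <- bundle$truth
  labels_all <- stats::setNames(truth$ckd_true, truth$patient_id)
  y <- unname(labels_all[inc$included])
  if (length(unique(y)) < 2) {
    stop("stage fit: included cohort has a single CKD class; ",
         "cannot train (prevalence degenerate)", call. = FALSE)
  }
  split <- split_train_test(y, config$model$split_fraction,
                            seed = config$model$seed,
                            stratify = config$model$stratify)
  models <- list(); metrics <- list(); curves <- list()
  for (profile in config$model$profiles) {
    feats <- build_feature_matrix(tables, inc$included, profile)
    tr_x <- feats[split$train, , drop = FALSE]
    te_x <- feats[split$test, , drop = FALSE]
    fit <- if (profile == "historyCKD" &&
               isTRUE(config$model$forest_for_historyCKD)) {
      fit_reference_forest(tr_x, y[split$train], seed = config$model$seed)
    } else {
      fit_logistic(tr_x, y[split$train], profile = profile,
                   seed = config$model$seed)
    }
    train_scores <- predict(fit, tr_x)$score
    fit$cutoff <- as.numeric(select_cutoff_youden(train_scores,
                                                  y[split$train]))
    pred <- predict(fit, te_x)
    cmat <- confusion_matrix(pred$label, y[split$test])
    metrics[[profile]] <- classification_metrics(cmat,
                                                 config$evaluation$ci_level)
    curves[[profile]] <- list(
      roc = roc_and_auc(pred$score, y[split$test]),
      pr = pr_and_auc(pred$score, y[split$test],
                      boot = config$evaluation$bootstrap,
                      seed = config$model$seed)
    )
    models[[profile]] <- fit
  }
  flow <- c(screened = sim$n_patients,
            no_stay_in_window = nrow(linked$no_index),
            table(factor(inc$exclusions$rule,
                         levels = c("age", "min_stay", "ed_discharge",
                                    "missing_egfr"))),
            included = length(inc$included))
  result <- structure(list(
    models = models, metrics = metrics, curves = curves, split = split,
    cohort = list(included = inc$included, exclusions = inc$exclusions,
                  no_index = linked$no_index, flow = flow),
    labels = y, tables = tables, truth = truth, config = config
  ), class = "experiment_result")
  if (!is.null(output_dir)) write_experiment(result, output_dir)
  result
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(result$models)) {
    if (inherits(result$models[[p]], "hib_logistic")) {
      write_model_json(result$models[[p]],
                       file.path(dir, paste0("model-", p, ".json")))
    }
    utils::write.csv(result$metrics[[p]],
                     file.path(dir, paste0("metrics-", p, ".csv")),
                     row.names = FALSE)
    write_curve_csv(result$curves[[p]]$roc,
                    file.path(dir, paste0("roc-", p, ".csv")))
    write_curve_csv(result$curves[[p]]$pr,
                    file.path(dir, paste0("pr-", p, ".csv")))
  }
  utils::write.csv(result$cohort$exclusions,
                   file.path(dir, "exclusion-log.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(result$cohort$flow),
                       file.path(dir, "flow.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run a full gold-versus-silver validation experiment
#'
#' The package's end-to-end analogue of silver-standard validation: HIB
#' logistic models (admissionHIB, historyHIB) and the historyCKD forest
#' labeler are trained on a development-style cohort (high CKD
#' prevalence), then applied to an independent low-prevalence validation
#' cohort. There, every HIB model is scored twice — against the
#' generator's truth (the stand-in for manual chart review) and against
#' the forest's silver labels — and the two label sets are compared by
#' accuracy and Cohen's kappa. The forest's own held-out F1 on the
#' development cohort is reported so the fidelity of the silver standard
#' can be conditioned on labeler quality.
#'
#' @param seed Master seed; the two cohorts derive distinct sub-seeds.
#' @param n_train,n_validation Cohort sizes.
#' @param train_prevalence,validation_prevalence True CKD prevalences
#'   (defaults 0.48 development-style / 0.12 validation-style).
#' @param sim_args Named list of further [simulation_config()] overrides
#'   applied to both cohorts.
#' @return A list: `forest_test_f1`, per-profile `f1_truth`, `f1_silver`,
#'   `delta_f1`, and `agreement` (an `agreement_report` of truth vs
#'   silver on the validation cohort).
#' @export
run_silver_validation_experiment <- function(seed, n_train = 350,
                                             n_validation = 350,
                                             train_prevalence = 0.48,
                                             validation_prevalence = 0.12,
                                             sim_args = list()) {
  base <- utils::modifyList(
    list(stays_per_patient_rate = 2.5, creatinine_noise_cv = 0.2,
         aki_rate_nonckd = 0.25),
    sim_args)
  prep <- function(n, prev, sub_seed) {
    cfg <- do.call(simulation_config,
                   c(list(n_patients = n, ckd_prevalence = prev,
                          seed = sub_seed), base))
    b <- generate_cohort(cfg)
    t <- bundle_tables(b)
    l <- link_stays(t$stays, cfg$window_start, cfg$window_end)
    t$stays <- l$stays
    inc <- apply_inclusion_criteria(t, "gold")
    list(tables = t, included = inc$included,
         truth = stats::setNames(b$truth$ckd_true, b$truth$patient_id))
  }
  tr <- prep(n_train, train_prevalence, patient_seed(seed, 1L, 20L))
  va <- prep(n_validation, validation_prevalence, patient_seed(seed, 2L, 20L))
  y_tr <- unname(tr$truth[tr$included])
  split <- split_train_test(y_tr, 0.8, seed = seed)

  # historyCKD forest labeler, held-out F1 on the development cohort
  f_tr <- build_feature_matrix(tr$tables, tr$included, "historyCKD")
  forest <- fit_reference_forest(f_tr[split$train, ], y_tr[split$train],
                                 seed = seed)
  te_pred <- predict(forest, f_tr[split$test, ])
  forest_f1 <- metric_value(
    classification_metrics(confusion_matrix(te_pred$label, y_tr[split$test])),
    "f1")

  # silver labels on the validation cohort
  f_va_ckd <- build_feature_matrix(va$tables, va$included, "historyCKD")
  silver <- generate_silver_labels(forest, va$tables, va$included,
                                   features = f_va_ckd)$labels
  silver_lab <- stats::setNames(silver$label, silver$patient_id)
  gold_lab <- va$truth[va$included]
  agreement <- compare_gold_silver(gold_lab, silver_lab)

  profiles <- c("admissionHIB", "historyHIB")
  out <- list(forest_test_f1 = forest_f1, agreement = agreement)
  for (p in profiles) {
    ftr <- build_feature_matrix(tr$tables, tr$included, p)
    fit <- suppressWarnings(fit_logistic(ftr, y_tr, profile = p, seed = seed))
    fit$cutoff <- as.numeric(
      suppressWarnings(select_cutoff_youden(predict(fit, ftr)$score, y_tr)))
    fva <- build_feature_matrix(va$tables, va$included, p)
    pred <- predict(fit, fva)
    f1_of <- function(ref) metric_value(
      classification_metrics(confusion_matrix(pred$label, unname(ref))),
      "f1")
    res <- list(f1_truth = f1_of(gold_lab),
                f1_silver = f1_of(silver_lab[va$included]))
    res$delta_f1 <- abs(res$f1_truth - res$f1_silver)
    out[[p]] <- res
  }
  out
}

#' Assign silver-standard CKD labels with the reference forest
#'
#' Applies the historyCKD forest labeler to every included patient of a
#' validation cohort; patients whose historyCKD features cannot be
#' computed are excluded with a log entry (the missing-eGFR path), never
#' silently labelled.
#'
#' @param forest A `hib_forest` from [fit_reference_forest()].
#' @param tables `ehr_tables` with linked stays.
#' @param included Included patient ids.
#' @param features Optional precomputed historyCKD feature matrix (skips
#'   recomputation).
#' @return A list: `labels` (patient_id, score, label), `excluded`
#'   (patient_id, reason), `labeler` (profile/seed identity).
#' @export
generate_silver_labels <- function(forest, tables, included,
                                   features = NULL) {
  stopifnot(inherits(forest, "hib_forest"))
  if (!length(included)) {
    return(list(labels = data.frame(patient_id = character(),
                                    score = numeric(), label = logical()),
                excluded = data.frame(patient_id = character(),
                                      reason = character()),
                labeler = forest$training))
  }
  if (is.null(features)) {
    ok <- logical(length(included)); rows <- vector("list", length(included))
    for (k in seq_along(included)) {
      rows[[k]] <- tryCatch(
        build_feature_matrix(tables, included[k], "historyCKD"),
        error = function(e) conditionMessage(e))
      ok[k] <- is.data.frame(rows[[k]])
    }
    excluded <- data.frame(
      patient_id = included[!ok],
      reason = vapply(rows[!ok], identity, character(1)))
    features <- if (any(ok)) do.call(rbind, rows[ok]) else NULL
  } else {
    excluded <- data.frame(patient_id = character(), reason = character())
  }
  if (is.null(features) || !nrow(features)) {
    return(list(labels = data.frame(patient_id = character(),
                                    score = numeric(), label = logical()),
                excluded = excluded, labeler = forest$training))
  }
  pred <- predict(forest, features)
  list(labels = data.frame(patient_id = features$patient_id,
                           score = pred$score, label = pred$label,
                           stringsAsFactors = FALSE),
       excluded = excluded,
       labeler = c(list(profile = forest$profile), forest$training))
}

#' Gold-versus-silver agreement on the overlapping patients
#'
#' @param gold Named logical vector (names = patient ids) of
#'   gold-standard labels.
#' @param silver Named logical vector of silver-standard labels.
#' @param boot Bootstrap draws for the kappa CI (0 disables).
#' @param seed Bootstrap seed.
#' @return A list of class `agreement_report`: `n_overlap`, `accuracy`,
#'   `kappa`, `kappa_ci`, `crosstab`.
#' @export
compare_gold_silver <- function(gold, silver, boot = 0L, seed = 1L) {
  ids <- intersect(names(gold), names(silver))
  if (!length(ids)) stop("no overlapping patients between label sets",
                         call. = FALSE)
  g <- as.logical(gold[ids]); s <- as.logical(silver[ids])
  kap <- cohens_kappa(g, s)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(seed)
    draws <- vapply(seq_len(boot), function(b) {
      i <- sample.int(length(ids), replace = TRUE)
      suppressWarnings(cohens_kappa(g[i], s[i]))
    }, numeric(1))
    ci <- unname(stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(n_overlap = length(ids), accuracy = mean(g == s),
                 kappa = kap, kappa_ci = ci,
                 crosstab = table(gold = g, silver = s)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, accuracy %.3f, kappa %.3f\n",
              x$n_overlap, x$accuracy, x$kappa))
  print(x$crosstab)
  invisible(x)
}

#' Comorbidity group map (ICD-10 prefixes)
#'
#' Editable prefix table resolving the four comorbidity groups used in
#' cohort characterisation: cardiovascular disease (myocardial
#' infarction, heart failure, peripheral vascular and cerebrovascular
#' disease), diabetes mellitus, liver disease, malignancy.
#'
#' @return Named list of character prefix vectors.
#' @export
comorbidity_icd_map <- function() {
  list(
    cardiovascular = c("I21", "I22", "I50", "I73", "I60", "I61", "I62",
                       "I63", "I64", "I65", "I66", "I67", "I69"),
    diabetes = c("E10", "E11", "E12", "E13", "E14"),
    liver = c("K70", "K71", "K72", "K73", "K74", "K75", "K76", "K77"),
    malignancy = sprintf("C%02d", 0:97)
  )
}

#' Characterise a cohort by CKD label
#'
#' Produces the standard cohort table: per group (CKD / noCKD) the count
#' and percentage, age mean and SD, male count and percentage, admission
#' eGFR median and quartiles, comorbidity-group counts resolved from
#' ICD-10 prefixes, plus the age–label point-biserial correlation.
#'
#' @param tables `ehr_tables` with linked stays.
#' @param included Included patient ids.
#' @param labels Named logical vector of CKD labels covering `included`.
#' @param features Optional precomputed admissionHIB feature matrix.
#' @param icd_map Comorbidity prefix map, default [comorbidity_icd_map()].
#' @return A list of class `cohort_characteristics` with `n`, `groups`
#'   (a data.frame, rows = cohort/CKD/noCKD), and `age_ckd_correlation`.
#' @export
characterize_cohort <- function(tables, included, labels, features = NULL,
                                icd_map = comorbidity_icd_map()) {
  if (!all(included %in% names(labels))) {
    stop("labels must cover every included patient", call. = FALSE)
  }
  if (is.null(features)) {
    features <- build_feature_matrix(tables, included, "admissionHIB")
  }
  y <- as.logical(labels[features$patient_id])
  conds <- tables$conditions
  has_comorb <- function(ids, prefixes) {
    vapply(ids, function(pid) {
      codes <- conds$code[conds$patient_id == pid]
      length(codes) && any(vapply(prefixes,
                                  function(p) any(startsWith(codes, p)),
                                  logical(1)))
    }, logical(1))
  }
  one_group <- function(sel, name) {
    f <- features[sel, , drop = FALSE]
    q <- stats::quantile(f$egfr_admission, c(0.25, 0.5, 0.75), na.rm = TRUE)
    row <- data.frame(
      group = name, n = nrow(f),
      pct = 100 * nrow(f) / nrow(features),
      age_mean = mean(f$age), age_sd = stats::sd(f$age),
      male_n = sum(f$sex == 1), male_pct = 100 * mean(f$sex == 1),
      egfr_admission_median = q[[2]], egfr_q1 = q[[1]], egfr_q3 = q[[3]]
    )
    for (g in names(icd_map)) {
      hits <- sum(has_comorb(f$patient_id, icd_map[[g]]))
      row[[paste0(g, "_n")]] <- hits
      row[[paste0(g, "_pct")]] <- 100 * hits / max(1, nrow(f))
    }
    row
  }
  groups <- rbind(one_group(rep(TRUE, nrow(features)), "cohort"),
                  one_group(y, "CKD"),
                  one_group(!y, "noCKD"))
  r <- if (length(unique(y)) > 1 && stats::sd(features$age) > 0) {
    stats::cor(features$age, as.numeric(y))
  } else NA_real_
  structure(list(n = nrow(features), groups = groups,
                 age_ckd_correlation = r),
            class = "cohort_characteristics")
}

#' @export
print.cohort_characteristics <- function(x, ...) {
  cat(sprintf("<cohort_characteristics> n = %d, age-CKD r = %.3f\n",
              x$n, x$age_ckd_correlation))
  print(x$groups[, c("group", "n", "pct", "age_mean", "age_sd",
                     "egfr_admission_median")], row.names = FALSE)
  invisible(x)
}
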