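#' Summarise the index stay's eGFR series
#'
#' Computes the index-stay block of the historyCKD profile: mean eGFR,
#' measurement counts (total and strictly below 60 mL/min/1.73 m²), the
#' discharge eGFR (last value of the stay), and the index classifier
#' "maximum eGFR of the stay < 60". Thresholds are strict and values are
#' carried at full precision — no rounding before thresholding.
#'
#' @param egfr Numeric eGFR values of the index stay, in time order.
#' @param length_of_stay_days Stay length in days.
#' @return A list: `mean_egfr_index`, `egfr_count_index`,
#'   `egfr_count_lt60_index`, `egfr_discharge`, `index_classifier_max_lt60`,
#'   `length_of_stay`.
#' @export
summarize_index_stay <- function(egfr, length_of_stay_days) {
  if (!length(egfr)) {
    stop("index stay has no eGFR values (missing-eGFR exclusion applies)",
         call. = FALSE)
  }
  list(
    mean_egfr_index = mean(egfr),
    egfr_count_index = length(egfr),
    egfr_count_lt60_index = sum(egfr < 60),
    egfr_discharge = egfr[length(egfr)],
    index_classifier_max_lt60 = max(egfr) < 60,
    length_of_stay = length_of_stay_days
  )
}

#' Summarise the pre-index hospitalisation history
#'
#' Computes the history block shared by the historyHIB and historyCKD
#' profiles: the mean eGFR over all pre-index values since the history
#' start, and the three utilisation ratios — stays with at least one eGFR
#' per previous stay, measurements per measured stay, and sub-60
#' measurements per measured stay. All three ratios are defined as 0 when
#' their denominator is 0, and a patient without history gets
#' `mean_egfr_history = fallback_egfr` (the admission eGFR) together with
#' a `history_missing` indicator, so admission information stays dominant
#' for history-free patients.
#'
#' @param egfr_by_stay A list of numeric vectors, one per previous stay
#'   (possibly empty vectors for stays without measurements); `list()` for
#'   patients without previous stays.
#' @param fallback_egfr Value used for `mean_egfr_history` when no
#'   pre-index eGFR exists (conventionally the admission eGFR).
#' @return A list: `mean_egfr_history`, `history_missing`,
#'   `ratio_hosp_with_egfr`, `ratio_measurements_per_hosp`,
#'   `ratio_lt60_per_hosp`.
#' @export
summarize_history <- function(egfr_by_stay, fallback_egfr) {
  n_prev <- length(egfr_by_stay)
  n_meas_stays <- sum(vapply(egfr_by_stay, length, integer(1)) > 0)
  all_vals <- unlist(egfr_by_stay, use.names = FALSE)
  list(
    mean_egfr_history = if (length(all_vals)) mean(all_vals) else fallback_egfr,
    history_missing = length(all_vals) == 0,
    ratio_hosp_with_egfr = if (n_prev > 0) n_meas_stays / n_prev else 0,
    ratio_measurements_per_hosp =
      if (n_meas_stays > 0) length(all_vals) / n_meas_stays else 0,
    ratio_lt60_per_hosp =
      if (n_meas_stays > 0) sum(all_vals < 60) / n_meas_stays else 0
  )
}

#' Ordered feature names of each predictor profile
#'
#' @param profile `"admissionHIB"`, `"historyHIB"` or `"historyCKD"`.
#' @return Character vector of feature names in their documented order.
#' @export
profile_features <- function(profile = c("admissionHIB", "historyHIB",
                                         "historyCKD")) {
  profile <- match.arg(profile)
  admission <- c("age", "sex", "egfr_admission")
  history <- c(admission, "mean_egfr_history", "history_missing")
  switch(profile,
    admissionHIB = admission,
    historyHIB = history,
    historyCKD = c("age", "sex", "length_of_stay", "egfr_admission",
                   "egfr_discharge", "mean_egfr_index", "egfr_count_index",
                   "egfr_count_lt60_index", "aki_kdigo", "reverted_aki",
                   "mean_egfr_history", "ratio_hosp_with_egfr",
                   "ratio_measurements_per_hosp", "ratio_lt60_per_hosp",
                   "index_classifier_max_lt60")
  )
}

#' Build the feature matrix for a predictor profile
#'
#' Assembles one row per included patient with exactly the profile's
#' features in their documented order: admissionHIB uses only what is
#' known at admission (age, sex, admission eGFR); historyHIB adds the mean
#' pre-index eGFR (with the missing-history fallback and indicator);
#' historyCKD adds the full index-stay block — discharge and mean eGFR,
#' measurement counts, KDIGO AKI and reverted-AKI flags, utilisation
#' ratios and the max-eGFR-below-60 index classifier. eGFR is computed
#' per observation with CKD-EPI 2009 at the patient's age at the index
#' admission. Observations are sorted by timestamp first, so feature
#' extraction is invariant to input record order.
#'
#' @param tables An `ehr_tables` list with linked stays (`is_index`,
#'   `in_history` flags).
#' @param included Character vector of included patient ids (from
#'   [apply_inclusion_criteria()]).
#' @param profile Profile name, see [profile_features()].
#' @return A data.frame with `patient_id` plus the profile's features;
#'   logical features are returned as 0/1 numerics, sex as a
#'   male-indicator (`sex = 1` for male).
#' @export
build_feature_matrix <- function(tables, included,
                                 profile = c("admissionHIB", "historyHIB",
                                             "historyCKD")) {
  profile <- match.arg(profile)
  stays <- tables$stays
  obs <- tables$observations[order(tables$observations$time), , drop = FALSE]
  rows <- vector("list", length(included))
  for (k in seq_along(included)) {
    pid <- included[k]
    prow <- tables$patients[tables$patients$patient_id == pid, , drop = FALSE]
    idx <- stays[stays$patient_id == pid & stays$is_index, , drop = FALSE]
    if (nrow(idx) != 1) stop("patient ", pid, " has no unique index stay",
                             call. = FALSE)
    age <- age_at(prow$birth_date[1], idx$admission[1])
    sex <- prow$sex[1]
    iobs <- obs[obs$stay_id == idx$stay_id[1] & !is.na(obs$value), ,
                drop = FALSE]
    adm <- select_admission_observation(iobs)
    if (is.null(adm)) stop("patient ", pid, " has no admission creatinine",
                           call. = FALSE)
    egfr_idx <- compute_egfr(iobs$value, age, sex)
    feat <- list(
      patient_id = pid,
      age = age,
      sex = as.numeric(sex == "male"),
      egfr_admission = compute_egfr(adm$value, age, sex)
    )
    if (profile %in% c("historyHIB", "historyCKD")) {
      hstays <- stays[stays$patient_id == pid & stays$in_history, ,
                      drop = FALSE]
      egfr_by_stay <- lapply(hstays$stay_id, function(sid) {
        v <- obs$value[obs$stay_id == sid & !is.na(obs$value)]
        if (length(v)) compute_egfr(v, age, sex) else numeric(0)
      })
      h <- summarize_history(egfr_by_stay, feat$egfr_admission)
      feat$mean_egfr_history <- h$mean_egfr_history
      feat$history_missing <- as.numeric(h$history_missing)
      if (profile == "historyCKD") {
        los <- as.numeric(difftime(idx$discharge[1], idx$admission[1],
                                   units = "days"))
        s <- summarize_index_stay(egfr_idx, los)
        feat$length_of_stay <- s$length_of_stay
        feat$egfr_discharge <- s$egfr_discharge
        feat$mean_egfr_index <- s$mean_egfr_index
        feat$egfr_count_index <- s$egfr_count_index
        feat$egfr_count_lt60_index <- s$egfr_count_lt60_index
        feat$aki_kdigo <- as.numeric(detect_aki_kdigo(iobs$time, iobs$value))
        feat$reverted_aki <- as.numeric(detect_reverted_aki(iobs$time,
                                                            iobs$value))
        feat$ratio_hosp_with_egfr <- h$ratio_hosp_with_egfr
        feat$ratio_measurements_per_hosp <- h$ratio_measurements_per_hosp
        feat$ratio_lt60_per_hosp <- h$ratio_lt60_per_hosp
        feat$index_classifier_max_lt60 <- as.numeric(s$index_classifier_max_lt60)
      }
    }
    rows[[k]] <- as.data.frame(feat, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[, c("patient_id", profile_features(profile)), drop = FALSE]
}

#' Write a feature matrix with its provenance sidecar
#'
#' Writes the matrix as CSV with a profile-stamped header comment and a
#' JSON sidecar recording the profile, thresholds and conventions.
#'
#' @param features Output of [build_feature_matrix()].
#' @param path CSV path; the sidecar is written as `<path>.json`.
#' @param profile Profile name.
#' @param history_start History-window start recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, profile,
                                 history_start = as.Date("2011-01-01")) {
  utils::write.csv(features, path, row.names = FALSE)
  meta <- list(
    profile = profile,
    features = profile_features(profile),
    egfr_threshold = 60,
    thresholds = list(egfr_lt60 = "strict <", reverted_aki = "value < 0.66 x 7-day max",
                      kdigo = ">=0.3 mg/dL in 48 h or >=1.5 x 7-day min baseline"),
    history_start = as.character(history_start),
    zero_denominator_ratios = 0,
    missing_history = "mean_egfr_history = admission eGFR + indicator"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
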