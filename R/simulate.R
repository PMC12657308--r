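#' Configuration for the synthetic longitudinal EHR generator
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' hospital validation cohort: CKD prevalence 12 %, mean age ~63 years,
#' CKD baseline eGFR drawn from \[15, 50\] and non-CKD from \[65, 110\]
#' mL/min/1.73 m² (disjoint around the 60 threshold that defines advanced
#' CKD), ICD-10 coding with sensitivity 0.93 / specificity 0.87 and
#' discharge-summary flags with 0.86 / 0.68 — the error profile typical of
#' routine billing data and clinical text.
#'
#' @param n_patients Number of patients to generate (> 0).
#' @param ckd_prevalence Target marginal probability of true CKD, in \[0, 1\].
#' @param seed Integer master seed; each patient derives an own
#'   sub-stream from `(seed, patient index)` so generation is
#'   order-independent and byte-reproducible.
#' @param age_mean,age_sd Age distribution at the index admission, years
#'   (normal, truncated at 18).
#' @param male_fraction Probability of male sex.
#' @param stays_per_patient_rate Poisson mean of *previous* stays in the
#'   history window (total stays = 1 index + Poisson draw).
#' @param labs_per_stay_rate Mean creatinine measurements per stay
#'   (every stay gets at least one).
#' @param history_span Years before the index admission in which previous
#'   stays may fall.
#' @param aki_rate_ckd,aki_rate_nonckd Per-stay probability of a transient
#'   AKI episode for CKD / non-CKD patients.
#' @param aki_peak_multiplier Peak creatinine multiplier of an AKI episode
#'   (> 1); the episode is a piecewise-linear rise over `aki_rise_days`
#'   followed by a fall over `aki_fall_days`.
#' @param aki_rise_days,aki_fall_days Shape of the AKI excursion, days.
#' @param creatinine_noise_cv Coefficient of variation of multiplicative
#'   lognormal measurement/biological noise (0 = noiseless).
#' @param icd_sensitivity,icd_specificity Probability that a truly-CKD
#'   patient receives a CKD ICD-10 code / that a non-CKD patient receives
#'   none.
#' @param summary_sensitivity,summary_specificity Same, for the binary
#'   discharge-summary CKD mention.
#' @param target_egfr_ckd_range,target_egfr_nonckd_range Baseline-eGFR
#'   sampling intervals (mL/min/1.73 m²); must not overlap and the CKD
#'   upper bound must stay below 60.
#' @param age_ckd_effect Log-odds of CKD per year of age; drives the
#'   age–CKD point-biserial correlation (~0.09 gives r in the 0.30–0.45
#'   band at the default ages). The intercept is calibrated internally so
#'   the marginal prevalence still matches `ckd_prevalence`.
#' @param ed_fraction Fraction of patients converted to a single short
#'   emergency-department stay (exercises the ED-discharge exclusion).
#' @param stay_length_range Uniform stay-length interval, days.
#' @param window_start,window_end `Date`s bounding index admissions.
#' @param comorbidity_rates Named list of per-group `c(ckd, nonckd)`
#'   emission probabilities for comorbidity ICD-10 codes.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 1000,
                              ckd_prevalence = 0.12,
                              seed = 1L,
                              age_mean = 62.8,
                              age_sd = 15,
                              male_fraction = 0.58,
                              stays_per_patient_rate = 2,
                              labs_per_stay_rate = 4,
                              history_span = 7,
                              aki_rate_ckd = 0.20,
                              aki_rate_nonckd = 0.10,
                              aki_peak_multiplier = 2.5,
                              aki_rise_days = 2,
                              aki_fall_days = 3,
                              creatinine_noise_cv = 0.10,
                              icd_sensitivity = 0.93,
                              icd_specificity = 0.87,
                              summary_sensitivity = 0.86,
                              summary_specificity = 0.68,
                              target_egfr_ckd_range = c(15, 50),
                              target_egfr_nonckd_range = c(65, 110),
                              age_ckd_effect = 0.09,
                              ed_fraction = 0.05,
                              stay_length_range = c(3, 14),
                              window_start = as.Date("2018-01-01"),
                              window_end = as.Date("2020-04-30"),
                              comorbidity_rates = NULL) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("`n_patients` must be a positive count", call. = FALSE)
  }
  probs <- c(ckd_prevalence = ckd_prevalence,
             aki_rate_ckd = aki_rate_ckd, aki_rate_nonckd = aki_rate_nonckd,
             icd_sensitivity = icd_sensitivity, icd_specificity = icd_specificity,
             summary_sensitivity = summary_sensitivity,
             summary_specificity = summary_specificity,
             ed_fraction = ed_fraction, male_fraction = male_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (aki_peak_multiplier <= 1) {
    stop("`aki_peak_multiplier` must exceed 1", call. = FALSE)
  }
  if (creatinine_noise_cv < 0) stop("`creatinine_noise_cv` must be >= 0", call. = FALSE)
  r1 <- sort(target_egfr_ckd_range); r2 <- sort(target_egfr_nonckd_range)
  if (r1[2] >= 60) {
    stop("CKD baseline-eGFR range must stay below 60 mL/min/1.73 m²",
         call. = FALSE)
  }
  if (r1[2] >= r2[1]) {
    stop("CKD and non-CKD baseline-eGFR ranges must not overlap", call. = FALSE)
  }
  if (is.null(comorbidity_rates)) {
    # per-group c(P(code | CKD), P(code | noCKD)); defaults give the CKD
    # group a heavier cardiovascular/diabetes burden, as seen in hospital
    # validation cohorts
    comorbidity_rates <- list(
      cardiovascular = c(0.79, 0.43),
      diabetes       = c(0.45, 0.35),
      liver          = c(0.38, 0.29),
      malignancy     = c(0.07, 0.24)
    )
  }
  cfg <- list(
    n_patients = as.integer(n_patients), ckd_prevalence = ckd_prevalence,
    seed = as.integer(seed), age_mean = age_mean, age_sd = age_sd,
    male_fraction = male_fraction,
    stays_per_patient_rate = stays_per_patient_rate,
    labs_per_stay_rate = labs_per_stay_rate, history_span = history_span,
    aki_rate_ckd = aki_rate_ckd, aki_rate_nonckd = aki_rate_nonckd,
    aki_peak_multiplier = aki_peak_multiplier,
    aki_rise_days = aki_rise_days, aki_fall_days = aki_fall_days,
    creatinine_noise_cv = creatinine_noise_cv,
    icd_sensitivity = icd_sensitivity, icd_specificity = icd_specificity,
    summary_sensitivity = summary_sensitivity,
    summary_specificity = summary_specificity,
    target_egfr_ckd_range = r1, target_egfr_nonckd_range = r2,
    age_ckd_effect = age_ckd_effect, ed_fraction = ed_fraction,
    stay_length_range = stay_length_range,
    window_start = window_start, window_end = window_end,
    comorbidity_rates = comorbidity_rates
  )
  structure(cfg, class = "sim_config")
}

# deterministic per-patient sub-seed; order-independent across patients
patient_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919 + stream * 104729) %%
               2147483629)
}

# calibrate the CKD logit intercept so that the marginal prevalence over
# the realised ages matches the target
calibrate_ckd_intercept <- function(ages, prevalence, effect, age_mean) {
  if (prevalence <= 0 || prevalence >= 1 || effect == 0) return(NULL)
  f <- function(b0) mean(stats::plogis(b0 + effect * (ages - age_mean))) - prevalence
  stats::uniroot(f, interval = c(-50, 50), tol = 1e-10)$root
}

#' AKI creatinine multiplier profile
#'
#' Piecewise-linear excursion: 1 at onset, rising to `peak` over
#' `rise_days`, then falling back to 1 over `fall_days`. Used both by the
#' generator and by tests that construct KDIGO-positive / reverted-AKI
#' patterns deterministically.
#'
#' @param t_days Time since stay admission, days (vectorised).
#' @param onset_days Episode onset, days since admission.
#' @param peak Peak multiplier (> 1).
#' @param rise_days,fall_days Rise / fall durations, days.
#' @return Multiplier >= 1 at each `t_days`.
#' @export
aki_multiplier <- function(t_days, onset_days, peak, rise_days, fall_days) {
  dt <- t_days - onset_days
  up   <- 1 + (peak - 1) * pmax(0, pmin(1, dt / rise_days))
  down <- 1 + (peak - 1) * pmax(0, pmin(1, 1 - (dt - rise_days) / fall_days))
  ifelse(dt <= rise_days, up, down)
}

#' Simulate one stay's creatinine series
#'
#' Draws strictly increasing observation times within
#' \[admission, discharge) and values
#' `baseline creatinine x AKI profile x lognormal noise`, where the noise
#' has mean 1 and coefficient of variation `config$creatinine_noise_cv`.
#'
#' @param baseline_creatinine Patient's baseline serum creatinine, mg/dL.
#' @param stay_length_days Stay duration in days (>= its lab span).
#' @param n_labs Number of observations (>= 1).
#' @param aki Either `NULL` (no episode) or a list with `onset_days` and
#'   optionally `peak`, `rise_days`, `fall_days`.
#' @param config A [simulation_config()].
#' @return A data.frame with `t_days` (time since admission, strictly
#'   increasing) and `value` (mg/dL, all positive).
#' @export
simulate_creatinine_series <- function(baseline_creatinine, stay_length_days,
                                       n_labs, aki = NULL, config) {
  stopifnot(stay_length_days >= 1, n_labs >= 1, baseline_creatinine > 0)
  t_days <- sort(stats::runif(n_labs, 0, stay_length_days * 0.999))
  # enforce strict increase under ties (resolution: ~1 s)
  t_days <- t_days + seq(0, by = 2e-5, length.out = n_labs)
  mult <- rep(1, n_labs)
  if (!is.null(aki)) {
    mult <- aki_multiplier(
      t_days, aki$onset_days,
      peak = aki$peak %||% config$aki_peak_multiplier,
      rise_days = aki$rise_days %||% config$aki_rise_days,
      fall_days = aki$fall_days %||% config$aki_fall_days
    )
  }
  cv <- config$creatinine_noise_cv
  noise <- if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    stats::rlnorm(n_labs, meanlog = -s^2 / 2, sdlog = s)
  } else rep(1, n_labs)
  data.frame(t_days = t_days, value = baseline_creatinine * mult * noise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit ICD-10 condition codes and discharge-summary flags from truth
#'
#' Imperfect "documentation" of the true CKD status: a CKD patient
#' receives an advanced-CKD ICD-10 code (N18.3/N18.4/N18.5/N18.9) with
#' probability `icd_sensitivity`; a non-CKD patient receives one with
#' probability `1 - icd_specificity`. The binary discharge-summary CKD
#' mention behaves analogously with the summary error rates. Comorbidity
#' codes (cardiovascular, diabetes, liver, malignancy) are emitted with
#' class-conditional rates from `config$comorbidity_rates`. Draws are
#' independent across patients given truth.
#'
#' @param truth Truth-label data.frame with `patient_id` and `ckd_true`.
#' @param config A [simulation_config()].
#' @param seed Seed for this emission step (defaults to a stream derived
#'   from `config$seed`).
#' @return A list with `conditions` (patient_id, code, group) and
#'   `summaries` (patient_id, ckd_mentioned).
#' @export
emit_codes_and_summaries <- function(truth, config,
                                     seed = patient_seed(config$seed, 0L, 9L)) {
  set.seed(seed)
  n <- nrow(truth)
  ckd <- truth$ckd_true
  p_code <- ifelse(ckd, config$icd_sensitivity, 1 - config$icd_specificity)
  has_code <- stats::runif(n) < p_code
  ckd_codes <- c("N18.3", "N18.4", "N18.5", "N18.9")
  cond <- data.frame(
    patient_id = truth$patient_id[has_code],
    code = sample(ckd_codes, sum(has_code), replace = TRUE),
    group = "ckd",
    stringsAsFactors = FALSE
  )
  pool <- list(
    cardiovascular = c("I21.4", "I50.9", "I73.9", "I63.9"),
    diabetes       = c("E11.9", "E10.9", "E14.9"),
    liver          = c("K70.3", "K74.6", "K76.9"),
    malignancy     = c("C34.9", "C18.9", "C61")
  )
  for (g in names(config$comorbidity_rates)) {
    r <- config$comorbidity_rates[[g]]
    has <- stats::runif(n) < ifelse(ckd, r[1], r[2])
    if (any(has)) {
      cond <- rbind(cond, data.frame(
        patient_id = truth$patient_id[has],
        code = sample(pool[[g]], sum(has), replace = TRUE),
        group = g, stringsAsFactors = FALSE
      ))
    }
  }
  p_sum <- ifelse(ckd, config$summary_sensitivity, 1 - config$summary_specificity)
  summaries <- data.frame(
    patient_id = truth$patient_id,
    ckd_mentioned = stats::runif(n) < p_sum,
    stringsAsFactors = FALSE
  )
  list(conditions = cond[order(cond$patient_id, cond$code), , drop = FALSE],
       summaries = summaries)
}

#' Generate a synthetic longitudinal hospital cohort with known truth
#'
#' The generator's causal chain mirrors how advanced CKD manifests in
#' routine records: each patient gets an age-dependent true CKD status, a
#' baseline eGFR drawn from the class-specific interval, and the
#' corresponding baseline creatinine by closed-form inversion of CKD-EPI
#' 2009. Hospital stays (one index stay inside the evaluation window plus
#' a Poisson number of previous stays) carry creatinine series with
#' multiplicative lognormal noise and optional transient AKI excursions;
#' ICD-10 codes and discharge-summary flags document the truth with
#' configurable sensitivity/specificity. A per-patient random sub-stream
#' derived from `(seed, patient index)` makes output order-independent and
#' byte-reproducible.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ehr_bundle` with elements `patients`, `stays`,
#'   `observations`, `conditions`, `summaries` (flat data.frames), `truth`
#'   (patient_id, ckd_true, baseline_egfr), `aki_episodes`, and the
#'   `config` snapshot.
#' @examples
#' b <- generate_cohort(simulation_config(n_patients = 50, seed = 1))
#' mean(b$truth$ckd_true)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  # pass 1: demographics (own stream per patient)
  age <- numeric(n); sex <- character(n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i, 1L))
    age[i] <- max(18.5, stats::rnorm(1, config$age_mean, config$age_sd))
    sex[i] <- if (stats::runif(1) < config$male_fraction) "male" else "female"
  }

  # CKD assignment: age-dependent logit calibrated to the target prevalence
  b0 <- calibrate_ckd_intercept(age, config$ckd_prevalence,
                                config$age_ckd_effect, config$age_mean)
  p_ckd <- if (is.null(b0)) {
    rep(config$ckd_prevalence, n)
  } else {
    stats::plogis(b0 + config$age_ckd_effect * (age - config$age_mean))
  }

  pat_rows <- vector("list", n); stay_rows <- vector("list", n)
  obs_rows <- vector("list", n); aki_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  window_days <- as.numeric(config$window_end - config$window_start)
  origin <- as.POSIXct(paste(config$window_start, "00:00:00"), tz = "UTC")

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i, 2L))
    ckd <- stats::runif(1) < p_ckd[i]
    rng <- if (ckd) config$target_egfr_ckd_range else config$target_egfr_nonckd_range
    baseline_egfr <- stats::runif(1, rng[1], rng[2])
    baseline_scr <- invert_egfr_to_creatinine(baseline_egfr, age[i], sex[i])

    is_ed <- stats::runif(1) < config$ed_fraction
    n_prev <- if (is_ed) 0L else stats::rpois(1, config$stays_per_patient_rate)
    index_adm_day <- stats::runif(1, 0, window_days)

    # previous-stay admissions: uniform over the history span before index
    prev_adm <- sort(stats::runif(n_prev,
                                  -config$history_span * 365.25,
                                  index_adm_day - 30))
    adm_days <- c(prev_adm, index_adm_day)
    n_stays <- n_prev + 1L
    durations <- if (is_ed) {
      stats::runif(1, 1, 5)  # short ED stays; some also fail the 3-day rule
    } else {
      stats::runif(n_stays, config$stay_length_range[1], config$stay_length_range[2])
    }
    # clip so consecutive stays never overlap
    if (n_stays > 1) {
      gaps <- diff(adm_days)
      durations[seq_len(n_stays - 1)] <-
        pmin(durations[seq_len(n_stays - 1)], gaps - 1)
      durations <- pmax(durations, 1)
    }

    stay_ids <- sprintf("%s-S%02d", ids[i], seq_len(n_stays))
    aki_rate <- if (ckd) config$aki_rate_ckd else config$aki_rate_nonckd
    p_obs <- vector("list", n_stays); p_aki <- list()
    for (s in seq_len(n_stays)) {
      n_labs <- 1L + stats::rpois(1, max(0, config$labs_per_stay_rate - 1))
      aki <- NULL
      if (stats::runif(1) < aki_rate) {
        aki <- list(onset_days = stats::runif(1, 0, 0.4 * durations[s]))
        p_aki[[length(p_aki) + 1]] <- data.frame(
          patient_id = ids[i], stay_id = stay_ids[s],
          onset_days = aki$onset_days,
          duration_days = config$aki_rise_days + config$aki_fall_days
        )
      }
      ser <- simulate_creatinine_series(baseline_scr, durations[s], n_labs,
                                        aki, config)
      p_obs[[s]] <- data.frame(
        patient_id = ids[i], stay_id = stay_ids[s],
        time = origin + (adm_days[s] + ser$t_days) * 86400,
        value = ser$value, stringsAsFactors = FALSE
      )
    }

    pat_rows[[i]] <- data.frame(
      patient_id = ids[i], sex = sex[i],
      birth_date = as.Date(origin) + round(index_adm_day) - round(age[i] * 365.25),
      stringsAsFactors = FALSE
    )
    stay_rows[[i]] <- data.frame(
      stay_id = stay_ids, patient_id = ids[i],
      admission = origin + adm_days * 86400,
      discharge = origin + (adm_days + durations) * 86400,
      department = if (is_ed) "emergency" else "general",
      stringsAsFactors = FALSE
    )
    obs_rows[[i]] <- do.call(rbind, p_obs)
    if (length(p_aki)) aki_rows[[i]] <- do.call(rbind, p_aki)
    truth_rows[[i]] <- data.frame(
      patient_id = ids[i], ckd_true = ckd, baseline_egfr = baseline_egfr,
      age_at_index = age[i], stringsAsFactors = FALSE
    )
  }

  truth <- do.call(rbind, truth_rows)
  docs <- emit_codes_and_summaries(truth, config)
  bundle <- list(
    patients = do.call(rbind, pat_rows),
    stays = do.call(rbind, stay_rows),
    observations = do.call(rbind, obs_rows),
    conditions = docs$conditions,
    summaries = docs$summaries,
    truth = truth[, c("patient_id", "ckd_true", "baseline_egfr", "age_at_index")],
    aki_episodes = if (any(!vapply(aki_rows, is.null, logical(1)))) {
      do.call(rbind, aki_rows[!vapply(aki_rows, is.null, logical(1))])
    } else {
      data.frame(patient_id = character(), stay_id = character(),
                 onset_days = numeric(), duration_days = numeric())
    },
    config = config
  )
  rownames(bundle$observations) <- NULL
  rownames(bundle$stays) <- NULL
  structure(bundle, class = "ehr_bundle")
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>",
      sprintf("  patients:     %d (CKD prevalence %.3f)",
              nrow(x$patients), mean(x$truth$ckd_true)),
      sprintf("  stays:        %d", nrow(x$stays)),
      sprintf("  observations: %d creatinine values", nrow(x$observations)),
      sprintf("  conditions:   %d ICD-10 codes", nrow(x$conditions)),
      sep = "\n")
  invisible(x)
}

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")

#' Write a bundle to disk as flat CSV tables or NDJSON resources
#'
#' CSV: one file per table (`patients.csv`, `stays.csv`,
#' `observations.csv`, `conditions.csv`, `summaries.csv`, `truth.csv`).
#' NDJSON: a single `bundle.ndjson` with one resource per line
#' (`resourceType` in Patient / Encounter / Observation / Condition plus
#' a DocumentReference-like summary flag), timestamps ISO-8601 UTC; truth
#' is always written separately as `truth.csv`.
#'
#' @param bundle An `ehr_bundle`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"ndjson"`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "ndjson")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle$truth[, c("patient_id", "ckd_true", "baseline_egfr")]
  utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  if (format == "csv") {
    tabs <- list(patients = bundle$patients, stays = bundle$stays,
                 observations = bundle$observations,
                 conditions = bundle$conditions, summaries = bundle$summaries)
    for (nm in names(tabs)) {
      t <- tabs[[nm]]
      for (cl in names(t)) {
        if (inherits(t[[cl]], "POSIXct")) t[[cl]] <- iso8601(t[[cl]])
      }
      utils::write.csv(t, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  } else {
    con <- file(file.path(dir, "bundle.ndjson"), "w")
    on.exit(close(con))
    emit <- function(df) {
      for (k in seq_len(nrow(df))) {
        writeLines(jsonlite::toJSON(as.list(df[k, , drop = FALSE]),
                                    auto_unbox = TRUE, digits = NA), con)
      }
    }
    p <- bundle$patients
    emit(data.frame(resourceType = "Patient", id = p$patient_id,
                    sex = p$sex, birthDate = as.character(p$birth_date)))
    s <- bundle$stays
    emit(data.frame(resourceType = "Encounter", id = s$stay_id,
                    patient = s$patient_id, admission = iso8601(s$admission),
                    discharge = iso8601(s$discharge), department = s$department))
    o <- bundle$observations
    emit(data.frame(resourceType = "Observation", patient = o$patient_id,
                    encounter = o$stay_id, time = iso8601(o$time),
                    value = o$value, unit = "mg/dL"))
    cdf <- bundle$conditions
    emit(data.frame(resourceType = "Condition", patient = cdf$patient_id,
                    code = cdf$code))
    sm <- bundle$summaries
    emit(data.frame(resourceType = "DocumentReference", patient = sm$patient_id,
                    ckdMentioned = sm$ckd_mentioned))
  }
  invisible(dir)
}
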