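parse_iso <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
}

#' Flatten a raw record bundle into linked analysis tables
#'
#' Reads either the NDJSON dialect (one resource per line, `resourceType`
#' in Patient / Encounter / Observation / Condition / DocumentReference)
#' or the flat CSV dialect written by [write_bundle()], and returns the
#' five analysis tables. Unknown resource types are ignored but counted;
#' records with malformed timestamps or non-positive lab values are
#' rejected at record level and listed in the log; observations that
#' reference a patient or stay that does not exist are reported as
#' orphans, never silently dropped.
#'
#' @param input A directory containing `bundle.ndjson` or the CSV tables,
#'   a path to an `.ndjson` file, or a character vector of NDJSON lines.
#' @param creatinine_unit `"mg/dL"` (default) or `"umol/L"`; µmol/L values
#'   are converted by division by 88.4 at ingestion.
#' @return A list of class `ehr_tables`: `patients`, `stays`,
#'   `observations`, `conditions`, `summaries`, and `log` (a list with
#'   `unknown_types`, `rejected`, `orphans`).
#' @export
flatten_bundle <- function(input, creatinine_unit = c("mg/dL", "umol/L")) {
  creatinine_unit <- match.arg(creatinine_unit)
  if (length(input) == 1 && dir.exists(input)) {
    nd <- file.path(input, "bundle.ndjson")
    if (file.exists(nd)) {
      lines <- readLines(nd)
    } else {
      return(flatten_csv_dir(input, creatinine_unit))
    }
  } else if (length(input) == 1 && file.exists(input)) {
    lines <- readLines(input)
  } else {
    lines <- input
  }
  recs <- lapply(lines[nzchar(lines)], function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad_json <- sum(vapply(recs, is.null, logical(1)))
  recs <- Filter(Negate(is.null), recs)
  type <- vapply(recs, function(r) r$resourceType %||% "<none>", character(1))
  known <- c("Patient", "Encounter", "Observation", "Condition",
             "DocumentReference")
  unknown <- sum(!type %in% known)

  grab <- function(tt, fields) {
    rows <- recs[type == tt]
    if (!length(rows)) {
      return(stats::setNames(
        as.data.frame(replicate(length(fields), character(0),
                                simplify = FALSE)), fields))
    }
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(lapply(stats::setNames(fields, fields),
                           function(f) r[[f]] %||% NA),
                    stringsAsFactors = FALSE)
    }))
  }

  pats <- grab("Patient", c("id", "sex", "birthDate"))
  patients <- data.frame(patient_id = as.character(pats$id),
                         sex = as.character(pats$sex),
                         birth_date = as.Date(pats$birthDate),
                         stringsAsFactors = FALSE)

  enc <- grab("Encounter", c("id", "patient", "admission", "discharge",
                             "department"))
  stays <- data.frame(stay_id = as.character(enc$id),
                      patient_id = as.character(enc$patient),
                      admission = parse_iso(enc$admission),
                      discharge = parse_iso(enc$discharge),
                      department = as.character(enc$department),
                      stringsAsFactors = FALSE)

  obs <- grab("Observation", c("patient", "encounter", "time", "value"))
  observations <- data.frame(patient_id = as.character(obs$patient),
                             stay_id = as.character(obs$encounter),
                             time = parse_iso(obs$time),
                             value = suppressWarnings(as.numeric(obs$value)),
                             stringsAsFactors = FALSE)
  if (creatinine_unit == "umol/L") {
    observations$value <- observations$value / 88.4
  }

  cnd <- grab("Condition", c("patient", "code"))
  conditions <- data.frame(patient_id = as.character(cnd$patient),
                           code = as.character(cnd$code),
                           stringsAsFactors = FALSE)

  doc <- grab("DocumentReference", c("patient", "ckdMentioned"))
  summaries <- data.frame(patient_id = as.character(doc$patient),
                          ckd_mentioned = as.logical(doc$ckdMentioned),
                          stringsAsFactors = FALSE)

  assemble_tables(patients, stays, observations, conditions, summaries,
                  extra_rejected = bad_json + unknown,
                  unknown_types = unknown)
}

flatten_csv_dir <- function(dir, creatinine_unit) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table: ", f, call. = FALSE)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  patients <- rd("patients"); patients$birth_date <- as.Date(patients$birth_date)
  stays <- rd("stays")
  stays$admission <- parse_iso(stays$admission)
  stays$discharge <- parse_iso(stays$discharge)
  observations <- rd("observations")
  observations$time <- parse_iso(observations$time)
  observations$value <- suppressWarnings(as.numeric(observations$value))
  if (creatinine_unit == "umol/L") observations$value <- observations$value / 88.4
  summaries <- rd("summaries")
  summaries$ckd_mentioned <- as.logical(summaries$ckd_mentioned)
  assemble_tables(patients, stays, observations, rd("conditions"), summaries,
                  extra_rejected = 0L, unknown_types = 0L)
}

# shared referential/validity checks for both dialects
assemble_tables <- function(patients, stays, observations, conditions,
                            summaries, extra_rejected, unknown_types) {
  rejected <- list()
  bad_stay <- is.na(stays$admission) | is.na(stays$discharge) |
    stays$admission >= stays$discharge
  if (any(bad_stay)) {
    rejected$stays <- data.frame(table = "stays", id = stays$stay_id[bad_stay],
                                 reason = "malformed or inverted interval")
    stays <- stays[!bad_stay, , drop = FALSE]
  }
  bad_obs <- is.na(observations$time) | is.na(observations$value) |
    observations$value <= 0
  if (any(bad_obs)) {
    rejected$obs <- data.frame(
      table = "observations",
      id = paste(observations$patient_id[bad_obs],
                 observations$stay_id[bad_obs]),
      reason = "malformed timestamp or non-positive value")
    observations <- observations[!bad_obs, , drop = FALSE]
  }
  orphan <- !(observations$stay_id %in% stays$stay_id) |
    !(observations$patient_id %in% patients$patient_id)
  orphans <- observations[orphan, , drop = FALSE]
  observations <- observations[!orphan, , drop = FALSE]
  structure(list(
    patients = patients, stays = stays, observations = observations,
    conditions = conditions, summaries = summaries,
    log = list(unknown_types = unknown_types,
               rejected = if (length(rejected)) do.call(rbind, rejected)
                          else data.frame(table = character(),
                                          id = character(),
                                          reason = character()),
               rejected_lines = extra_rejected,
               orphans = orphans)
  ), class = "ehr_tables")
}

#' Link stays per patient and flag the index stay and its history
#'
#' The index stay is the first stay (by admission, default policy) whose
#' admission falls inside the evaluation window; `"longest"` picks the
#' longest in-window stay instead. Previous stays are those discharged
#' before the index admission and admitted on or after `history_start`.
#' Patients without any in-window stay are dropped and logged.
#'
#' @param stays Stay table (`stay_id`, `patient_id`, `admission`,
#'   `discharge`, `department`).
#' @param window_start,window_end `Date`s bounding index-stay admissions.
#' @param history_start `Date`; earlier stays are ignored.
#' @param policy `"first_in_window"` (default) or `"longest"`.
#' @return A list: `stays` (input rows plus logical `is_index` and
#'   `in_history`) and `no_index` (patients with no in-window stay).
#' @export
link_stays <- function(stays, window_start, window_end,
                       history_start = as.Date("2011-01-01"),
                       policy = c("first_in_window", "longest")) {
  policy <- match.arg(policy)
  ws <- as.POSIXct(paste(window_start, "00:00:00"), tz = "UTC")
  we <- as.POSIXct(paste(window_end, "23:59:59"), tz = "UTC")
  hs <- as.POSIXct(paste(history_start, "00:00:00"), tz = "UTC")
  stays <- stays[order(stays$patient_id, stays$admission), , drop = FALSE]
  stays$is_index <- FALSE
  stays$in_history <- FALSE
  no_index <- character(0)
  for (pid in unique(stays$patient_id)) {
    idx <- which(stays$patient_id == pid)
    inw <- idx[stays$admission[idx] >= ws & stays$admission[idx] <= we]
    if (!length(inw)) {
      no_index <- c(no_index, pid)
      next
    }
    pick <- if (policy == "first_in_window") {
      inw[which.min(stays$admission[inw])]
    } else {
      inw[which.max(as.numeric(stays$discharge[inw]) -
                    as.numeric(stays$admission[inw]))]
    }
    stays$is_index[pick] <- TRUE
    stays$in_history[idx] <- stays$discharge[idx] < stays$admission[pick] &
      stays$admission[idx] >= hs
  }
  list(stays = stays,
       no_index = data.frame(patient_id = no_index,
                             rule = rep("no_stay_in_window", length(no_index))))
}

#' Select the admission creatinine of one stay
#'
#' The admission value is the earliest non-missing creatinine of the
#' stay; ties on the timestamp are broken by stable input order. An empty
#' or all-missing series signals the missing-eGFR exclusion.
#'
#' @param observations Observation rows of one stay (`time`, `value`).
#' @return The selected row, or `NULL` if no non-missing value exists.
#' @export
select_admission_observation <- function(observations) {
  ok <- which(!is.na(observations$value))
  if (!length(ok)) return(NULL)
  sel <- ok[order(observations$time[ok])][1]
  observations[sel, , drop = FALSE]
}

age_at <- function(birth_date, when) {
  as.numeric(difftime(as.Date(when), as.Date(birth_date), units = "days")) / 365.25
}

#' Apply cohort inclusion/exclusion criteria
#'
#' The gold profile enforces, in fixed order: age > 18 years at index
#' admission, minimum index-stay length of three days (>= 72 h on
#' half-open \[admission, discharge) intervals), no direct discharge from
#' the emergency department, and a computable admission eGFR. The silver
#' profile enforces only the age and missing-eGFR rules. Each excluded
#' patient is logged once with the first rule that failed, so the flow
#' counts are reproducible; included + excluded always partitions the
#' input.
#'
#' @param tables An `ehr_tables` list (or equivalent) whose `stays` carry
#'   `is_index` flags from [link_stays()].
#' @param profile `"gold"` or `"silver"`.
#' @param min_stay_hours Minimum index-stay length for the gold profile,
#'   hours; default 72 ("minimum hospital stay of three days" on
#'   half-open intervals).
#' @return A list: `included` (patient ids), `exclusions` (patient_id,
#'   rule, detail), `index_stays` (index-stay rows of included patients).
#' @export
apply_inclusion_criteria <- function(tables, profile = c("gold", "silver"),
                                     min_stay_hours = 72) {
  profile <- match.arg(profile)
  stays <- tables$stays
  idx <- stays[stays$is_index, , drop = FALSE]
  included <- character(0)
  excl <- list()
  fail <- function(pid, rule, detail) {
    excl[[length(excl) + 1]] <<- data.frame(patient_id = pid, rule = rule,
                                            detail = detail,
                                            stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(idx))) {
    pid <- idx$patient_id[k]
    prow <- tables$patients[tables$patients$patient_id == pid, , drop = FALSE]
    age <- age_at(prow$birth_date[1], idx$admission[k])
    if (!(age > 18)) { fail(pid, "age", sprintf("age %.1f <= 18", age)); next }
    los_h <- as.numeric(difftime(idx$discharge[k], idx$admission[k],
                                 units = "hours"))
    if (profile == "gold" && los_h < min_stay_hours) {
      fail(pid, "min_stay",
           sprintf("stay %.1f h < %.0f h", los_h, min_stay_hours)); next
    }
    if (profile == "gold" && identical(idx$department[k], "emergency")) {
      fail(pid, "ed_discharge", "direct discharge from emergency department")
      next
    }
    sobs <- tables$observations[tables$observations$stay_id == idx$stay_id[k], ,
                                drop = FALSE]
    if (is.null(select_admission_observation(sobs))) {
      fail(pid, "missing_egfr", "no non-missing creatinine in index stay")
      next
    }
    included <- c(included, pid)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), rule = character(),
               detail = character())
  list(included = included, exclusions = exclusions,
       index_stays = idx[idx$patient_id %in% included, , drop = FALSE])
}
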