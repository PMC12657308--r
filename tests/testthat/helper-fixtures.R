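# Shared fixtures and independent oracles, all built in code.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Five-patient fixture exercising every gold-profile exclusion rule:
# one minor, one 2-day stay, one ED-only, one without creatinine, one clean.
make_exclusion_fixture <- function() {
  patients <- data.frame(
    patient_id = c("minor", "short", "ed", "nolab", "clean"),
    sex = c("male", "female", "male", "female", "male"),
    birth_date = c(as.Date("2002-06-01"),  # 16.6 y at admission
                   rep(as.Date("1960-01-01"), 4)),
    stringsAsFactors = FALSE
  )
  adm <- ts_utc("2019-01-01 08:00:00")
  stays <- data.frame(
    stay_id = paste0(patients$patient_id, "-S1"),
    patient_id = patients$patient_id,
    admission = adm,
    discharge = adm + c(5, 2, 5, 5, 5) * 86400,
    department = c("general", "general", "emergency", "general", "general"),
    is_index = TRUE, in_history = FALSE,
    stringsAsFactors = FALSE
  )
  observations <- data.frame(
    patient_id = c("minor", "short", "ed", "clean"),
    stay_id = paste0(c("minor", "short", "ed", "clean"), "-S1"),
    time = adm + 3600,
    value = c(1.0, 1.1, 0.9, 1.2),
    stringsAsFactors = FALSE
  )
  list(patients = patients, stays = stays, observations = observations,
       conditions = data.frame(patient_id = character(), code = character()),
       summaries = data.frame(patient_id = character(),
                              ckd_mentioned = logical()))
}

# O(n^2) Mann-Whitney probability of correct ranking, ties counted 1/2.
auroc_pairwise_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden search over every distinct classification achievable
# with the "score >= threshold is positive" rule; returns the maximal J.
youden_bruteforce_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  cand <- c(sort(unique(scores)), Inf)
  max(vapply(cand, function(t) {
    mean(scores[y] >= t) + mean(scores[!y] < t) - 1
  }, numeric(1)))
}

# Step-wise AUPRC from first principles: walk thresholds from high to
# low, accumulate precision at each new recall level.
auprc_step_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & y)
    recall <- tp / sum(y)
    precision <- tp / sum(called)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Small generated cohort shared by several expensive-ish tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(simulation_config(n_patients = 120, seed = 42))
    }
    cache
  }
})
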