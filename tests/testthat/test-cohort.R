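test_that("NDJSON and CSV dialects round-trip with exact row counts", {
  b <- small_cohort()
  for (fmt in c("ndjson", "csv")) {
    d <- file.path(tempdir(), paste0("rt-", fmt))
    write_bundle(b, d, fmt)
    t <- flatten_bundle(d)
    expect_equal(nrow(t$patients), nrow(b$patients))
    expect_equal(nrow(t$stays), nrow(b$stays))
    expect_equal(nrow(t$observations), nrow(b$observations))
    expect_equal(nrow(t$conditions), nrow(b$conditions))
    expect_equal(sort(t$patients$patient_id), sort(b$patients$patient_id))
    expect_equal(sum(t$observations$value), sum(b$observations$value),
                 tolerance = 1e-9)
  }
})

ndjson_line <- function(...) {
  jsonlite::toJSON(list(...), auto_unbox = TRUE)
}

test_that("flattening conserves counts on a hand-built 3/5/12 bundle", {
  lines <- c(
    sapply(1:3, function(i) ndjson_line(
      resourceType = "Patient", id = paste0("p", i), sex = "male",
      birthDate = "1950-01-01")),
    sapply(1:5, function(i) ndjson_line(
      resourceType = "Encounter", id = paste0("s", i),
      patient = paste0("p", (i - 1) %% 3 + 1),
      admission = "2019-01-01T08:00:00Z",
      discharge = "2019-01-06T08:00:00Z", department = "general")),
    sapply(1:12, function(i) ndjson_line(
      resourceType = "Observation", patient = paste0("p", (i - 1) %% 3 + 1),
      encounter = paste0("s", (i - 1) %% 3 + 1),
      time = sprintf("2019-01-0%dT10:00:00Z", (i - 1) %% 5 + 1),
      value = 1 + i / 10, unit = "mg/dL"))
  )
  t <- flatten_bundle(lines)
  expect_equal(nrow(t$patients), 3)
  expect_equal(nrow(t$stays), 5)
  expect_equal(nrow(t$observations), 12)
  expect_equal(nrow(t$log$orphans), 0)
})

test_that("empty input yields empty tables without error", {
  t <- flatten_bundle(character(0))
  expect_equal(nrow(t$patients), 0)
  expect_equal(nrow(t$observations), 0)
})

test_that("orphans are reported and bad records rejected, never dropped silently", {
  lines <- c(
    ndjson_line(resourceType = "Patient", id = "p1", sex = "female",
                birthDate = "1955-05-05"),
    ndjson_line(resourceType = "Encounter", id = "s1", patient = "p1",
                admission = "2019-01-01T08:00:00Z",
                discharge = "2019-01-05T08:00:00Z", department = "general"),
    ndjson_line(resourceType = "Observation", patient = "p1",
                encounter = "ghost-stay", time = "2019-01-02T08:00:00Z",
                value = 1.1),
    ndjson_line(resourceType = "Observation", patient = "p1",
                encounter = "s1", time = "not-a-time", value = 1.2),
    ndjson_line(resourceType = "Observation", patient = "p1",
                encounter = "s1", time = "2019-01-02T09:00:00Z",
                value = -4),
    ndjson_line(resourceType = "MedicationRequest", id = "m1")
  )
  t <- flatten_bundle(lines)
  expect_equal(nrow(t$log$orphans), 1)
  expect_equal(t$log$orphans$stay_id, "ghost-stay")
  expect_equal(nrow(t$log$rejected), 2)
  expect_equal(t$log$unknown_types, 1)
  expect_equal(nrow(t$observations), 0)
})

test_that("index and history stays follow the window and cutoff rules", {
  mk <- function(adm) {
    data.frame(stay_id = paste0("s", seq_along(adm)), patient_id = "p1",
               admission = ts_utc(paste(adm, "08:00:00")),
               discharge = ts_utc(paste(adm, "08:00:00")) + 5 * 86400,
               department = "general", stringsAsFactors = FALSE)
  }
  l <- link_stays(mk(c("2012-03-01", "2019-06-01", "2020-01-01")),
                  as.Date("2018-01-01"), as.Date("2020-04-30"))
  expect_equal(l$stays$stay_id[l$stays$is_index], "s2")
  expect_equal(l$stays$stay_id[l$stays$in_history], "s1")
  # single in-window stay: index with empty history
  l2 <- link_stays(mk("2019-01-01"), as.Date("2018-01-01"),
                   as.Date("2020-04-30"))
  expect_true(l2$stays$is_index)
  expect_false(any(l2$stays$in_history))
  # admission before the history start is not history
  l3 <- link_stays(mk(c("2010-06-01", "2019-01-01")), as.Date("2018-01-01"),
                   as.Date("2020-04-30"),
                   history_start = as.Date("2011-01-01"))
  expect_false(any(l3$stays$in_history))
  # no stay in window: excluded and logged
  l4 <- link_stays(mk("2012-01-01"), as.Date("2018-01-01"),
                   as.Date("2020-04-30"))
  expect_equal(l4$no_index$patient_id, "p1")
  # longest-stay policy picks the longer of two in-window stays
  st <- mk(c("2018-02-01", "2019-02-01"))
  st$discharge[2] <- st$admission[2] + 12 * 86400
  l5 <- link_stays(st, as.Date("2018-01-01"), as.Date("2020-04-30"),
                   policy = "longest")
  expect_equal(l5$stays$stay_id[l5$stays$is_index], "s2")
})

test_that("gold and silver profiles apply their distinct criteria", {
  fx <- make_exclusion_fixture()
  gold <- apply_inclusion_criteria(fx, "gold")
  expect_equal(gold$included, "clean")
  expect_equal(nrow(gold$exclusions), 4)
  expect_setequal(gold$exclusions$rule,
                  c("age", "min_stay", "ed_discharge", "missing_egfr"))
  silver <- apply_inclusion_criteria(fx, "silver")
  expect_setequal(silver$included, c("short", "ed", "clean"))
  expect_setequal(silver$exclusions$rule, c("age", "missing_egfr"))
  expect_error(apply_inclusion_criteria(fx, "bronze"))
})

test_that("criteria partition the input, are idempotent and monotone in min stay", {
  fx <- make_exclusion_fixture()
  res <- apply_inclusion_criteria(fx, "gold")
  expect_equal(length(res$included) + nrow(res$exclusions),
               sum(fx$stays$is_index))
  expect_equal(anyDuplicated(res$exclusions$patient_id), 0)
  # idempotence: re-applying to the already-included cohort changes nothing
  fx2 <- fx
  keep <- fx$stays$patient_id %in% res$included
  fx2$stays <- fx$stays[keep, , drop = FALSE]
  fx2$patients <- fx$patients[fx$patients$patient_id %in% res$included, ,
                              drop = FALSE]
  res2 <- apply_inclusion_criteria(fx2, "gold")
  expect_identical(sort(res2$included), sort(res$included))
  expect_equal(nrow(res2$exclusions), 0)
  # relaxing the minimum stay never shrinks the included set
  sizes <- vapply(c(96, 72, 48, 24, 0), function(h) {
    length(apply_inclusion_criteria(fx, "gold", min_stay_hours = h)$included)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("the admission observation is the earliest non-missing value", {
  t0 <- ts_utc("2019-01-01 00:00:00")
  obs <- data.frame(time = t0 + c(2, 6) * 3600, value = c(1.4, 1.1))
  expect_equal(select_admission_observation(obs)$value, 1.4)
  expect_equal(select_admission_observation(obs[2, ])$value, 1.1)
  obs$value[1] <- NA
  expect_equal(select_admission_observation(obs)$value, 1.1)
  expect_null(select_admission_observation(obs[integer(0), ]))
  # tie on the timestamp: stable input order wins
  tie <- data.frame(time = rep(t0, 2), value = c(2.2, 3.3))
  expect_equal(select_admission_observation(tie)$value, 2.2)
})
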