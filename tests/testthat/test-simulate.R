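test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_patients = 0), "n_patients")
  expect_error(simulation_config(ckd_prevalence = 1.2), "probabilities")
  expect_error(simulation_config(icd_sensitivity = -0.1), "probabilities")
  expect_error(simulation_config(aki_peak_multiplier = 0.9), "exceed 1")
  expect_error(simulation_config(target_egfr_ckd_range = c(15, 65)),
               "below 60")
  expect_error(simulation_config(target_egfr_ckd_range = c(15, 55),
                                 target_egfr_nonckd_range = c(50, 110)),
               "overlap")
})

test_that("empirical prevalence stays inside the binomial 95 % bound", {
  # pooled over five fixed seeds so no single tail draw decides the check
  ckd <- unlist(lapply(1:5, function(s) {
    b <- generate_cohort(simulation_config(n_patients = 400,
                                           ckd_prevalence = 0.12, seed = s))
    expect_equal(nrow(b$truth), 400)
    # CKD truth implies a baseline eGFR below 60, non-CKD above
    expect_true(all(b$truth$baseline_egfr[b$truth$ckd_true] < 60))
    expect_true(all(b$truth$baseline_egfr[!b$truth$ckd_true] >= 60))
    b$truth$ckd_true
  }))
  half <- 1.96 * sqrt(0.12 * 0.88 / length(ckd))
  expect_lt(abs(mean(ckd) - 0.12), half)
})

test_that("degenerate prevalence 0 yields an all-negative cohort", {
  b <- generate_cohort(simulation_config(n_patients = 10,
                                         ckd_prevalence = 0, seed = 7))
  expect_true(all(!b$truth$ckd_true))
})

test_that("generation is deterministic: same config, same bytes", {
  cfg <- simulation_config(n_patients = 40, seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$observations, b2$observations)
  expect_identical(b1$truth, b2$truth)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_bundle(b1, d1, "ndjson"); write_bundle(b2, d2, "ndjson")
  expect_identical(readLines(file.path(d1, "bundle.ndjson")),
                   readLines(file.path(d2, "bundle.ndjson")))
})

test_that("every patient has an index-window stay with >= 1 observation", {
  b <- small_cohort()
  expect_true(all(b$patients$patient_id %in% b$stays$patient_id))
  obs_per_stay <- table(factor(b$observations$stay_id,
                               levels = b$stays$stay_id))
  expect_true(all(obs_per_stay >= 1))
  expect_true(all(b$observations$value > 0))
  # timestamps strictly increasing within each stay
  for (sid in sample(b$stays$stay_id, 25)) {
    tt <- b$observations$time[b$observations$stay_id == sid]
    if (length(tt) > 1) expect_true(all(diff(as.numeric(tt)) > 0))
  }
})

test_that("noiseless series reproduce the baseline eGFR exactly", {
  cfg <- simulation_config(creatinine_noise_cv = 0)
  scr <- invert_egfr_to_creatinine(40, 60, "female")
  ser <- with_seed <- {
    set.seed(1)
    simulate_creatinine_series(scr, 7, 5, aki = NULL, config = cfg)
  }
  expect_equal(compute_egfr(ser$value, 60, "female"), rep(40, 5),
               tolerance = 1e-12)
})

test_that("noiseless disjoint ranges never trip the eGFR index rule", {
  b <- generate_cohort(simulation_config(
    n_patients = 150, ckd_prevalence = 0, seed = 3,
    creatinine_noise_cv = 0, aki_rate_nonckd = 0,
    target_egfr_nonckd_range = c(75, 110)))
  t <- bundle_tables(b)
  l <- link_stays(t$stays, b$config$window_start, b$config$window_end)
  t$stays <- l$stays
  inc <- apply_inclusion_criteria(t, "gold")
  flagged <- vapply(inc$included, function(pid) {
    idx <- t$stays$stay_id[t$stays$patient_id == pid & t$stays$is_index]
    age <- b$truth$age_at_index[b$truth$patient_id == pid]
    sex <- t$patients$sex[t$patients$patient_id == pid]
    v <- t$observations$value[t$observations$stay_id == idx]
    rule_egfr_index(compute_egfr(v, age, sex))
  }, logical(1))
  expect_true(length(flagged) > 100)
  expect_true(!any(flagged))
})

test_that("coding and summary error rates are recovered within binomial bounds", {
  cfg <- simulation_config(n_patients = 2000, icd_sensitivity = 0.93,
                           icd_specificity = 0.87,
                           summary_sensitivity = 0.86,
                           summary_specificity = 0.68, seed = 2)
  set.seed(2)
  truth <- data.frame(patient_id = sprintf("P%05d", 1:2000),
                      ckd_true = runif(2000) < 0.5)
  docs <- emit_codes_and_summaries(truth, cfg)
  has_ckd_code <- truth$patient_id %in%
    docs$conditions$patient_id[docs$conditions$group == "ckd"]
  bound <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)
  n1 <- sum(truth$ckd_true); n0 <- sum(!truth$ckd_true)
  expect_lt(abs(mean(has_ckd_code[truth$ckd_true]) - 0.93), bound(0.93, n1))
  expect_lt(abs(mean(!has_ckd_code[!truth$ckd_true]) - 0.87), bound(0.87, n0))
  sm <- docs$summaries$ckd_mentioned[match(truth$patient_id,
                                           docs$summaries$patient_id)]
  expect_lt(abs(mean(sm[truth$ckd_true]) - 0.86), bound(0.86, n1))
  expect_lt(abs(mean(!sm[!truth$ckd_true]) - 0.68), bound(0.68, n0))
})

test_that("a perfect coder reproduces truth exactly", {
  cfg <- simulation_config(icd_sensitivity = 1, icd_specificity = 1,
                           summary_sensitivity = 1, summary_specificity = 1)
  truth <- data.frame(patient_id = sprintf("P%03d", 1:50),
                      ckd_true = rep(c(TRUE, FALSE), 25))
  docs <- emit_codes_and_summaries(truth, cfg)
  coded <- truth$patient_id %in%
    docs$conditions$patient_id[docs$conditions$group == "ckd"]
  expect_identical(coded, truth$ckd_true)
  expect_identical(docs$summaries$ckd_mentioned[
    match(truth$patient_id, docs$summaries$patient_id)], truth$ckd_true)
})

test_that("an age_ckd_effect setting reproduces the age-CKD correlation band", {
  b <- generate_cohort(simulation_config(n_patients = 800, seed = 6,
                                         age_ckd_effect = 0.09))
  r <- cor(b$truth$age_at_index, as.numeric(b$truth$ckd_true))
  expect_gt(r, 0.30)
  expect_lt(r, 0.45)
})
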