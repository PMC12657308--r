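test_that("eGFR index rule honours its aggregation variants", {
  expect_true(rule_egfr_index(c(45, 52, 58)))                 # max 58 < 60
  expect_false(rule_egfr_index(c(45, 62)))
  expect_true(rule_egfr_index(c(45, 62), aggregation = "any_lt"))
  expect_false(rule_egfr_index(60))                           # strict <
  expect_false(rule_egfr_index(60, aggregation = "any_lt"))
  expect_false(rule_egfr_index(60, aggregation = "all_lt"))
  expect_error(rule_egfr_index(numeric(0)), "empty")
})

test_that("ICD-10 rule matches configured prefixes only", {
  expect_true(rule_icd10(c("N18.4", "I10")))
  expect_false(rule_icd10("I10"))
  expect_false(rule_icd10(character(0)))
  expect_true(rule_icd10("N18.2", prefixes = "N18"))
  expect_false(rule_icd10("N18.2"))  # default set targets advanced stages
})

test_that("discharge-summary rule passes flags through and logs missing ones", {
  expect_true(rule_discharge_summary(TRUE))
  expect_false(rule_discharge_summary(FALSE))
  expect_warning(out <- rule_discharge_summary(NA), "missing")
  expect_false(out)
})

test_that("train/test split is disjoint, exhaustive, seeded and guarded", {
  y <- rep(c(TRUE, FALSE), 50)
  s <- split_train_test(y, 0.8, seed = 4)
  expect_length(s$train, 80)
  expect_length(s$test, 20)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_identical(s, split_train_test(y, 0.8, seed = 4))
  expect_false(identical(s$train, split_train_test(y, 0.8, seed = 5)$train))
  expect_error(split_train_test(y, 1.0), "strictly between")
  expect_error(split_train_test(y[1:4]), "at least 5")
  st <- split_train_test(y, 0.8, seed = 4, stratify = TRUE)
  expect_equal(mean(y[st$train]), 0.5)
})

test_that("logistic fit recovers known coefficients within 3 standard errors", {
  set.seed(101)
  n <- 5000
  x <- data.frame(age = rnorm(n, 63, 12), sex = rbinom(n, 1, 0.5),
                  egfr_admission = rnorm(n, 75, 25))
  beta <- c(age = 0.04, sex = -0.3, egfr_admission = -0.08)
  eta <- -1 + as.matrix(x) %*% beta
  y <- runif(n) < plogis(eta)
  fit <- fit_logistic(x, y)
  for (f in names(beta)) {
    expect_lt(abs(fit$coefficients[[f]] - beta[[f]]), 3 * fit$std_errors[[f]])
  }
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("labels independent of features give near-zero slopes", {
  set.seed(202)
  n <- 3000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- runif(n) < 0.3
  fit <- fit_logistic(x, y)
  for (f in c("a", "b")) {
    expect_lt(abs(fit$coefficients[[f]]), 3 * fit$std_errors[[f]])
  }
})

test_that("degenerate fits are guarded: one class, zero variance, separation", {
  x <- data.frame(a = rnorm(50), flat = 1)
  expect_error(fit_logistic(x, rep(TRUE, 50)), "single class")
  expect_warning(fit <- fit_logistic(x, rep(c(TRUE, FALSE), 25)),
                 "zero-variance")
  expect_false("flat" %in% fit$feature_names)
  # perfectly separated feature
  xs <- data.frame(v = c(rnorm(25, -5), rnorm(25, 5)))
  ys <- rep(c(FALSE, TRUE), each = 25)
  expect_warning(fs <- fit_logistic(xs, ys), "separation")
  expect_true(fs$separation)
  fr <- suppressWarnings(fit_logistic(xs, ys, separation = "ridge"))
  expect_true(fr$ridge_fallback)
  expect_true(all(is.finite(fr$coefficients)))
  expect_true(all(abs(fr$coefficients) < 50))
})

test_that("Youden cutoff matches brute force and its conventions", {
  # perfect separation: midpoint of the optimal gap
  cut <- select_cutoff_youden(c(0.1, 0.2, 0.8, 0.9),
                              c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.numeric(cut), 0.5)
  expect_equal(attr(cut, "youden"), 1)
  # hand-constructed overlap set, oracle by exhaustive search
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.32, 0.9)
  lb <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  cut2 <- select_cutoff_youden(sc, lb)
  expect_equal(attr(cut2, "youden"), youden_bruteforce_oracle(sc, lb))
  # uninformative scores
  expect_warning(cut3 <- select_cutoff_youden(rep(0.4, 6),
                                              c(TRUE, FALSE, TRUE, FALSE,
                                                TRUE, FALSE)), "identical")
  expect_equal(as.numeric(cut3), 0.4)
  expect_error(select_cutoff_youden(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Youden selection equals exhaustive search on random instances", {
  set.seed(303)
  for (i in 1:100) {
    n <- sample(6:60, 1)
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    lb <- runif(n) < 0.4
    if (length(unique(lb)) < 2) next
    cut <- suppressWarnings(select_cutoff_youden(sc, lb))
    expect_equal(attr(cut, "youden"), youden_bruteforce_oracle(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("prediction is the inverse-logit with >=-cutoff labelling", {
  m <- structure(list(profile = "admissionHIB", feature_names = c("a", "b"),
                      intercept = 0, coefficients = c(a = 0, b = 0),
                      std_errors = c(a = NA, b = NA), cutoff = 0.5,
                      converged = TRUE, separation = FALSE,
                      ridge_fallback = FALSE, training = list(n = 0)),
                 class = "hib_logistic")
  x <- data.frame(a = c(-3, 10), b = c(2, 2))
  expect_equal(predict(m, x)$score, c(0.5, 0.5))
  expect_true(all(predict(m, x)$label))  # score == cutoff is positive
  m$coefficients <- c(a = 0.7, b = -1.2)
  m$intercept <- 0.3
  expect_equal(predict(m, x)$score,
               plogis(0.3 + 0.7 * x$a - 1.2 * x$b), tolerance = 1e-12)
  expect_error(predict(m, data.frame(a = 1)), "missing feature.*b")
})

test_that("logistic score is monotone in each feature with its sign", {
  set.seed(404)
  x <- data.frame(u = rnorm(400), v = rnorm(400))
  y <- runif(400) < plogis(1.5 * x$u - 2 * x$v)
  fit <- fit_logistic(x, y)
  grid <- data.frame(u = seq(-3, 3, length.out = 20), v = 0)
  s_u <- predict(fit, grid)$score
  expect_true(all(diff(s_u) * sign(fit$coefficients[["u"]]) > 0))
  grid2 <- data.frame(u = 0, v = seq(-3, 3, length.out = 20))
  s_v <- predict(fit, grid2)$score
  expect_true(all(diff(s_v) * sign(fit$coefficients[["v"]]) > 0))
})

test_that("model JSON manifests round-trip", {
  set.seed(77)
  x <- data.frame(a = rnorm(200), b = rnorm(200))
  y <- runif(200) < plogis(x$a)
  fit <- fit_logistic(x, y, profile = "admissionHIB", seed = 77)
  fit$cutoff <- 0.42
  path <- file.path(tempdir(), "model.json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$cutoff, 0.42)
  expect_equal(predict(back, x)$score, predict(fit, x)$score,
               tolerance = 1e-12)
})

test_that("the forest labeler is deterministic and separates separable data", {
  set.seed(55)
  n <- 300
  x <- data.frame(egfr = c(rnorm(n / 2, 35, 6), rnorm(n / 2, 90, 10)),
                  age = rnorm(n, 65, 10))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  f1 <- fit_reference_forest(x, y, seed = 9)
  f2 <- fit_reference_forest(x, y, seed = 9)
  p1 <- predict(f1, x); p2 <- predict(f2, x)
  expect_identical(p1$score, p2$score)
  cmat <- confusion_matrix(p1$label, y)
  m <- classification_metrics(cmat)
  expect_equal(metric_value(m, "sensitivity"), 1)
  expect_equal(metric_value(m, "ppv"), 1)
  # label-shuffled training: held-out accuracy collapses to the base rate
  set.seed(56)
  ysh <- sample(y)
  idx <- split_train_test(ysh, 0.8, seed = 3)
  fsh <- fit_reference_forest(x[idx$train, ], ysh[idx$train], seed = 9)
  acc <- mean(predict(fsh, x[idx$test, ])$label == ysh[idx$test])
  expect_lt(abs(acc - 0.5), 0.2)
  expect_equal(unname(reference_cutoffs()["historyHIB"]), 0.586)
})
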