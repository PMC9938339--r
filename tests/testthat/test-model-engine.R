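test_that("model definitions load from JSON with invariants enforced", {
  m <- load_model_definition(extdata_model("toy_stroke.json"))
  expect_s3_class(m, "survalid_model")
  expect_length(m$predictors, 3)
  expect_equal(m$baseline_survival, 0.9)
  expect_equal(m$outcome_fraction, 1)

  mq <- load_model_definition(extdata_model("toy_composite_qrisk_like.json"))
  expect_equal(mq$outcome_fraction, 0.366)
  expect_equal(mq$clinical_threshold, 0.10)
  mp <- load_model_definition(extdata_model("toy_composite_pce_like.json"))
  expect_equal(mp$outcome_fraction, 0.289)

  # schema violations name the offending field
  bad <- tempfile(fileext = ".json")
  writeLines('{"name":"x","baseline_survival":0.9,
    "predictors":[{"name":"age","transform":"identity","coefficient":0.1}]}', bad)
  expect_error(load_model_definition(bad), "mean")
  writeLines('{"name":"x","baseline_survival":1.4,
    "predictors":[{"name":"age","transform":"identity","coefficient":0.1,"mean":0}]}', bad)
  expect_error(load_model_definition(bad), "baseline_survival")
})

test_that("prognostic index is the transformed dot product", {
  m1 <- risk_model("one", list(
    list(name = "x", transform = "identity", coefficient = 2, mean = 0)),
    baseline_survival = 0.9)
  expect_equal(compute_prognostic_index(m1, list(x = 3)), 6)
  expect_equal(compute_prognostic_index(m1, list(x = 0)), 0)

  # independent hand computation for a 3-predictor row:
  # 0.05*72 + 0.8*log(140) + 0.4*1 = 7.953963...
  m3 <- toy_model_3pred()
  row <- list(age = 72, sbp = 140, smoker = 1)
  expect_equal(compute_prognostic_index(m3, row),
               0.05 * 72 + 0.8 * log(140) + 0.4 * 1)
  expect_error(compute_prognostic_index(m3, list(age = 72, smoker = 1)),
               "sbp")
})

test_that("centring subtracts the published mean contribution", {
  m3 <- toy_model_3pred()
  pi <- compute_prognostic_index(m3, list(age = 72, sbp = 140, smoker = 1))
  expect_equal(centre_prognostic_index(m3, pi),
               pi - (0.05 * 68 + 0.8 * 5 + 0.4 * 0.2))
  m0 <- risk_model("zmeans", list(
    list(name = "x", transform = "identity", coefficient = 2, mean = 0)),
    baseline_survival = 0.9)
  expect_equal(centre_prognostic_index(m0, 6), 6)
})

test_that("predicted probability follows 1 - S0^exp(CPI)", {
  m <- risk_model("p", list(
    list(name = "x", transform = "identity", coefficient = 1, mean = 0)),
    baseline_survival = 0.9)
  expect_equal(predict_event_probability(m, 0), 1 - 0.9)
  expect_equal(predict_event_probability(m, log(2)), 1 - 0.81)
  m1 <- risk_model("s1", list(
    list(name = "x", transform = "identity", coefficient = 1, mean = 0)),
    baseline_survival = 1)
  expect_equal(predict_event_probability(m1, c(-3, 0, 5)), c(0, 0, 0))
  # extreme CPI saturates with a warning, never reaching 1
  expect_warning(p <- predict_event_probability(m, 800), "saturate")
  expect_lt(p, 1)
})

test_that("probability is strictly increasing in CPI and scaling shrinks it", {
  m <- risk_model("mono", list(
    list(name = "x", transform = "identity", coefficient = 1, mean = 0)),
    baseline_survival = 0.85, outcome_fraction = 0.366)
  cpi <- seq(-4, 4, length.out = 200)
  p <- predict_event_probability(m, cpi)
  expect_true(all(diff(p) > 0))
  expect_true(all(scale_to_outcome(m, p) <= p))
  expect_true(all(diff(scale_to_outcome(m, p)) > 0))
  expect_equal(scale_to_outcome(m, 0.10), 0.0366)
  mp <- risk_model("pce-frac", list(
    list(name = "x", transform = "identity", coefficient = 1, mean = 0)),
    baseline_survival = 0.85, outcome_fraction = 0.289)
  expect_equal(scale_to_outcome(mp, 0.10), 0.0289)
  mid <- risk_model("idfrac", list(
    list(name = "x", transform = "identity", coefficient = 1, mean = 0)),
    baseline_survival = 0.85)
  expect_equal(scale_to_outcome(mid, p), p)
})

test_that("zero coefficients give every subject P = 1 - S0 exactly", {
  m <- risk_model("null-model", list(
    list(name = "age", transform = "identity", coefficient = 0, mean = 68),
    list(name = "smoker", transform = "indicator", coefficient = 0, mean = 0.2)),
    baseline_survival = 0.88)
  cohort <- tibble::tibble(
    id = as.character(1:20), time = runif(20, 1, 10),
    event = rep(0L, 20), age = runif(20, 60, 79),
    smoker = rbinom(20, 1, 0.3))
  sc <- score_cohort(cohort, m)
  expect_equal(sc$probability, rep(1 - 0.88, 20))
  expect_equal(sc$pi, rep(0, 20))
})

test_that("eligibility filtering matches set algebra and is idempotent", {
  m <- risk_model("elig", list(
    list(name = "age", transform = "identity", coefficient = 0.1, mean = 68)),
    baseline_survival = 0.9,
    eligibility = list(
      list(covariate = "prior_stroke"),
      list(covariate = "statin_use"),
      list(covariate = "chd")))
  set.seed(42)
  n <- 500
  cohort <- tibble::tibble(
    id = as.character(seq_len(n)), time = runif(n, 0.5, 10),
    event = sample(0:2, n, TRUE), age = runif(n, 60, 79),
    prior_stroke = rbinom(n, 1, 0.1) == 1,
    statin_use = rbinom(n, 1, 0.15) == 1,
    chd = rbinom(n, 1, 0.2) == 1)
  kept <- suppressMessages(apply_eligibility(cohort, m))
  expect_equal(nrow(kept),
               sum(!(cohort$prior_stroke | cohort$statin_use | cohort$chd)))
  again <- suppressMessages(apply_eligibility(kept, m))
  expect_identical(lapply(again, identity), lapply(kept, identity)) # same rows; metadata may differ
  counts <- attr(kept, "exclusions")
  expect_equal(counts$excluded[counts$predicate == "prior_stroke"],
               sum(cohort$prior_stroke))
  m_bad <- risk_model("elig2", m$predictors, baseline_survival = 0.9,
                      eligibility = list(list(covariate = "absent_flag")))
  expect_error(apply_eligibility(cohort, m_bad), "absent_flag")
})

test_that("complete-case filter drops and reports missingness, idempotently", {
  m3 <- toy_model_3pred()
  set.seed(7)
  n <- 100
  cohort <- tibble::tibble(
    id = as.character(seq_len(n)), time = runif(n, 0.5, 10),
    event = sample(0:1, n, TRUE), age = runif(n, 60, 79),
    sbp = rnorm(n, 150, 20), smoker = rbinom(n, 1, 0.2))
  miss_rows <- sample(n, 8)
  cohort$sbp[miss_rows] <- NA
  filtered <- suppressMessages(complete_case_filter(cohort, m3))
  expect_equal(nrow(filtered), 92)
  expect_equal(attr(filtered, "missing_fraction"), 0.08)
  mtab <- attr(filtered, "missingness")
  expect_equal(mtab$n_missing[mtab$covariate == "sbp"], 8L)
  expect_equal(mtab$n_missing[mtab$covariate == "age"], 0L)
  again <- suppressMessages(complete_case_filter(filtered, m3))
  expect_identical(lapply(again, identity), lapply(filtered, identity))
  # > 15% missing warns
  cohort$sbp[sample(setdiff(seq_len(n), miss_rows), 12)] <- NA
  expect_warning(suppressMessages(complete_case_filter(cohort, m3)),
                 "15%")
  # fully observed cohort passes through silently
  cohort2 <- cohort; cohort2$sbp <- rnorm(n, 150, 20)
  expect_equal(nrow(complete_case_filter(cohort2, m3)), n)
})

test_that("onehot and product transforms evaluate correctly", {
  m <- risk_model("trans", list(
    list(name = "ethnicity", transform = list(type = "onehot", level = "b"),
         coefficient = 0.5, mean = 0.2),
    list(name = "age_x_smoker",
         transform = list(type = "product", terms = c("age", "smoker")),
         coefficient = 0.01, mean = 10)),
    baseline_survival = 0.9)
  expect_setequal(model_covariates(m), c("ethnicity", "age", "smoker"))
  pi <- compute_prognostic_index(m, list(ethnicity = "b", age = 70, smoker = 1))
  expect_equal(pi, 0.5 * 1 + 0.01 * 70)
  pi2 <- compute_prognostic_index(m, list(ethnicity = "a", age = 70, smoker = 0))
  expect_equal(pi2, 0)
})

test_that("horizon capping censors events beyond the window", {
  cohort <- tibble::tibble(
    id = c("a", "b", "c"), time = c(4, 11.5, 12),
    event = c(1L, 1L, 2L), age = c(65, 70, 75))
  capped <- cap_horizon(cohort, 10)
  expect_equal(capped$time, c(4, 10, 10))
  expect_equal(capped$event, c(1L, 0L, 0L))
})
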