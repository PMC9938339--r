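test_that("calibration slope recovers the generating attenuation", {
  # validation data generated from the model's own PI: slope near 1;
  # from half the CPI: slope near 0.5 (moderate n, loose unit-test band)
  mk <- function(mult, seed) {
    cfg <- scenario_config(
      n = 8000, seed = seed,
      covariates = list(marker = list(dist = "normal", mean = 0, sd = 1)),
      stroke_model = list(baseline_rate = 0.02, shape = 1,
                          coefficients = c(marker = 1),
                          centring = c(marker = 0)),
      death_model = NULL, dropout_fraction = 0,
      slope_multiplier = mult)
    coh <- generate_cohort(cfg)
    sc <- score_cohort(coh, scenario_model(cfg))
    dplyr::mutate(coh, cpi = sc$cpi, event01 = as.integer(event == 1))
  }
  s1 <- calibration_slope(mk(1, 41), cpi, time, event01)
  expect_equal(s1$slope, 1, tolerance = 0.1)
  expect_gt(s1$p_vs_1, 0.01)
  s05 <- calibration_slope(mk(2, 42), cpi, time, event01)
  expect_equal(s05$slope, 0.5, tolerance = 0.1)
  expect_lt(s05$p_vs_1, 0.001)
})

test_that("mean calibration is the predicted/observed ratio with the right reference", {
  # predictions all equal to the observed KM risk: ratio exactly 1
  d <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6), event = c(1L, 0L, 1L, 0L, 0L, 0L))
  obs <- suppressWarnings(km_risk_at(
    kaplan_meier(dplyr::mutate(d, event = as.integer(event == 1))), 10))
  d$pred <- obs
  mc <- suppressWarnings(mean_calibration(d, pred, time, event, reference = "km"))
  expect_equal(mc$ratio, 1)
  # doubling predictions doubles the ratio
  d$pred <- 2 * obs
  expect_equal(suppressWarnings(mean_calibration(d, pred, time, event))$ratio, 2)
  # CIF reference gives a ratio at least the KM one when competing events exist
  set.seed(8)
  n <- 600
  t <- rexp(n, 0.12)
  code <- sample(0:2, n, TRUE, prob = c(0.2, 0.3, 0.5))
  dd <- tibble::tibble(time = pmin(t, 10), event = ifelse(t > 10, 0L, code),
                       pred = runif(n, 0, 0.3))
  dd$time <- pmax(dd$time, 1e-6)
  r_km <- mean_calibration(dd, pred, time, event, reference = "km")$ratio
  r_cif <- mean_calibration(dd, pred, time, event, reference = "cif")$ratio
  expect_gte(r_cif, r_km)
  # zero observed risk is an error
  suppressWarnings(expect_error(mean_calibration(
    tibble::tibble(time = 1:3, event = c(0L, 0L, 0L), pred = 0.1), pred,
    time, event), "undefined"))
})

test_that("decile bins partition the sample and reproduce the mean", {
  set.seed(15)
  n <- 487 # deliberately not divisible by 10
  d <- tibble::tibble(
    time = rexp(n, 0.1), event = sample(0:2, n, TRUE, prob = c(.5, .3, .2)),
    pred = runif(n, 0, 0.4))
  d$time <- pmin(pmax(d$time, 1e-6), 10)
  dt <- suppressWarnings(decile_calibration(d, pred, time, event))
  expect_equal(sum(dt$n), n)
  expect_lte(diff(range(dt$n)), 1)
  # weighted mean of bin means equals the global mean exactly
  expect_equal(sum(dt$n * dt$mean_predicted) / n, mean(d$pred),
               tolerance = 1e-12)
  # bins are ordered in prediction
  expect_true(all(diff(dt$mean_predicted) > 0))
  # per-bin observed risk agrees with the loop oracle on the same split
  ord_bin <- survalid:::prediction_bins(d$pred, 10)
  for (b in c(1, 5, 10)) {
    sel <- ord_bin == b
    expect_equal(dt$observed_risk[b],
                 if (sum(d$event[sel] == 1) == 0) 0 else
                   oracle_km_risk(d$time[sel], as.integer(d$event[sel] == 1), 10),
    tolerance = 1e-12)
  }
  # n_bins = 1 reduces to the mean-calibration numerator and denominator
  one <- decile_calibration(d, pred, time, event, n_bins = 1)
  mc <- mean_calibration(d, pred, time, event)
  expect_equal(one$mean_predicted, mc$mean_predicted)
  expect_equal(one$observed_risk, mc$observed_risk)
})

test_that("a generator with an inflated top tail shows top-decile overestimation only", {
  cfg <- make_miscalibrated_truth(
    scenario_config(n = 20000, seed = 55, death_model = NULL,
                    dropout_fraction = 0.05),
    top_tail_inflation = 0.55)
  coh <- generate_cohort(cfg)
  sc <- score_cohort(coh, scenario_model(cfg))
  dat <- dplyr::bind_cols(coh[c("time", "event")], sc["scaled_probability"])
  dt <- decile_calibration(dat, scaled_probability, time, event)
  rel <- dt$mean_predicted / dt$observed_risk
  # bottom deciles roughly calibrated, top decile clearly over-predicted
  expect_lt(max(abs(rel[1:6] - 1)), 0.25)
  expect_gt(rel[10], 1.3)
})

test_that("age-group calibration matches hand KM/CIF computation per band", {
  # 12-subject fixture spanning two bands
  d <- tibble::tibble(
    age = c(62, 63, 64, 61, 65, 60, 72, 74, 76, 71, 73, 78),
    time = c(2, 4, 10, 10, 3, 10, 1, 2, 10, 5, 10, 4),
    event = c(1L, 0L, 0L, 0L, 2L, 0L, 1L, 2L, 0L, 1L, 0L, 2L),
    pred = rep(c(0.1, 0.2), each = 6))
  at <- age_group_calibration(d, pred, age, time, event, breaks = 65)
  expect_equal(nrow(at), 2)
  young <- d[d$age <= 65, ]
  old <- d[d$age > 65, ]
  expect_equal(at$km_risk[1],
               oracle_km_risk(young$time, as.integer(young$event == 1), 10))
  expect_equal(at$cif_risk[1], oracle_cif(young$time, young$event, 10, 1))
  expect_equal(at$km_risk[2],
               oracle_km_risk(old$time, as.integer(old$event == 1), 10))
  expect_equal(at$cif_risk[2], oracle_cif(old$time, old$event, 10, 1))
  expect_equal(at$mean_predicted, c(0.1, 0.2))
  expect_equal(at$n_competing, c(1L, 2L))
  # single band reduces to whole-sample summaries
  expect_warning(
    all_band <- age_group_calibration(d, pred, age, time, event, breaks = 100),
    "Empty age band")
  expect_equal(all_band$km_risk[1],
               oracle_km_risk(d$time, as.integer(d$event == 1), 10))
})

test_that("KM-CIF gap widens with age when competing mortality rises with age", {
  cfg <- scenario_config(n = 20000, seed = 66)
  coh <- generate_cohort(cfg)
  sc <- score_cohort(coh, scenario_model(cfg))
  dat <- dplyr::bind_cols(coh[c("time", "event", "age")],
                          sc["scaled_probability"])
  at <- age_group_calibration(dat, scaled_probability, age, time, event)
  gap <- at$km_risk - at$cif_risk
  expect_true(all(diff(gap) > 0))
  # flattening the age gradient of competing mortality shrinks every gap
  cfg_flat <- cfg
  cfg_flat$death_model$coefficients["age"] <- 0
  coh2 <- generate_cohort(cfg_flat)
  sc2 <- score_cohort(coh2, scenario_model(cfg_flat))
  dat2 <- dplyr::bind_cols(coh2[c("time", "event", "age")],
                           sc2["scaled_probability"])
  at2 <- age_group_calibration(dat2, scaled_probability, age, time, event)
  gap2 <- at2$km_risk - at2$cif_risk
  expect_lt(max(diff(gap2)), max(diff(gap)))
})
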