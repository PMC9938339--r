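test_that("generation is deterministic and structurally valid", {
  cfg <- scenario_config(n = 500, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(as.data.frame(cohort_truth(a)), as.data.frame(cohort_truth(b)))
  expect_true(all(a$time > 0 & a$time <= 10))
  expect_true(all(a$event %in% 0:2))
  expect_true(all(a$age >= 60 & a$age <= 79))
  # a different seed changes the draw
  c2 <- generate_cohort(cfg, seed = 14)
  expect_false(identical(a$time, c2$time))
})

test_that("zero hazards leave everyone administratively censored", {
  cfg <- scenario_config(
    n = 50, seed = 1,
    covariates = list(),
    stroke_model = list(baseline_rate = 0, shape = 1,
                        coefficients = stats::setNames(numeric(0), character(0)),
                        centring = stats::setNames(numeric(0), character(0))),
    death_model = NULL, dropout_fraction = 0)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$event == 0L))
  expect_true(all(coh$time == 10))
})

test_that("default scenario lands in the published event-mix magnitudes", {
  coh <- generate_cohort(scenario_config(n = 4000, seed = 3))
  frac <- as.numeric(table(factor(coh$event, 0:2)) / nrow(coh))
  expect_gt(frac[2], 0.08); expect_lt(frac[2], 0.12) # stroke outcomes
  expect_gt(frac[3], 0.20); expect_lt(frac[3], 0.28) # competing deaths
  # competing deaths roughly 2-3x strokes
  expect_gt(frac[3] / frac[2], 1.8)
})

test_that("closed-form CIF matches the analytic constant-hazard result", {
  cfg <- scenario_config(
    n = 10, seed = 1, covariates = list(),
    stroke_model = list(baseline_rate = 0.05, shape = 1,
                        coefficients = stats::setNames(numeric(0), character(0)),
                        centring = stats::setNames(numeric(0), character(0))),
    death_model = list(baseline_rate = 0.05, shape = 1,
                       coefficients = stats::setNames(numeric(0), character(0)),
                       centring = stats::setNames(numeric(0), character(0))),
    dropout_fraction = 0)
  cif <- true_cumulative_incidence(cfg, tibble::tibble(age = 68), 10)
  expect_equal(cif, 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  # no competition reduces to 1 - exp(-Lambda)
  cfg2 <- cfg; cfg2$death_model <- NULL
  expect_equal(true_cumulative_incidence(cfg2, tibble::tibble(age = 68), 10),
               1 - exp(-0.5), tolerance = 1e-12)
})

test_that("Weibull quadrature agrees with Monte Carlo", {
  cfg <- scenario_config(
    n = 200000, seed = 17, covariates = list(),
    stroke_model = list(baseline_rate = 0.01, shape = 1.5,
                        coefficients = stats::setNames(numeric(0), character(0)),
                        centring = stats::setNames(numeric(0), character(0))),
    death_model = list(baseline_rate = 0.02, shape = 1.2,
                       coefficients = stats::setNames(numeric(0), character(0)),
                       centring = stats::setNames(numeric(0), character(0))),
    dropout_fraction = 0)
  cif <- true_cumulative_incidence(cfg, tibble::tibble(age = 68), 10)
  coh <- generate_cohort(cfg)
  emp <- mean(coh$event == 1)
  se <- sqrt(cif * (1 - cif) / nrow(coh))
  expect_lt(abs(emp - cif), 3 * se)
})

test_that("latent truth is consistent with observed outcomes", {
  cfg <- scenario_config(n = 3000, seed = 29, dropout_fraction = 0)
  coh <- generate_cohort(cfg)
  tr <- cohort_truth(coh)
  # with administrative censoring only, observed events = latent cause by 10y
  expect_equal(coh$event, tr$true_status_10y)
  # empirical cause-1 incidence matches the mean analytic CIF
  expect_lt(abs(mean(coh$event == 1) - mean(tr$true_cif10)),
            3 * sqrt(mean(tr$true_cif10) / nrow(coh)))
})

test_that("miscalibration knobs reproduce their designed failure modes", {
  base <- scenario_config(n = 12000, seed = 47, death_model = NULL,
                          dropout_fraction = 0.05)
  m <- scenario_model(base)
  run <- function(cfg) {
    coh <- generate_cohort(cfg)
    sc <- score_cohort(coh, m)
    dplyr::bind_cols(coh[c("time", "event")], sc[c("cpi", "scaled_probability")],
                     event01 = as.integer(coh$event == 1))
  }
  # identity knobs: slope ~ 1, ratio ~ 1
  d0 <- run(base)
  expect_equal(calibration_slope(d0, cpi, time, event01)$slope, 1,
               tolerance = 0.1)
  expect_equal(mean_calibration(d0, scaled_probability, time, event)$ratio, 1,
               tolerance = 0.05)
  # baseline inflation: evaluated model over-predicts by the factor
  d_inf <- run(make_miscalibrated_truth(base, baseline_inflation = 1.24))
  expect_equal(mean_calibration(d_inf, scaled_probability, time, event)$ratio,
               1.24, tolerance = 0.08)
  # slope multiplier 2: fitted slope ~ 0.5
  d_att <- run(make_miscalibrated_truth(base, slope_multiplier = 2))
  expect_equal(calibration_slope(d_att, cpi, time, event01)$slope, 0.5,
               tolerance = 0.15)
})

test_that("cohort and truth export to separate CSV files", {
  coh <- generate_cohort(scenario_config(n = 50, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths[["cohort"]])
  expect_equal(nrow(back), 50)
  expect_false("true_cif10" %in% names(back))
  truth <- utils::read.csv(paths[["truth"]])
  expect_true("true_cif10" %in% names(truth))
})
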