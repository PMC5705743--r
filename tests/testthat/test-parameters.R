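test_that("annual/quarterly conversion satisfies the compounding identity", {
  expect_equal(annual_to_quarterly(0), 0)
  expect_equal(annual_to_quarterly(1), 1)
  expect_equal(annual_to_quarterly(0.04), 1 - 0.96^0.25)
  expect_equal(round(annual_to_quarterly(0.04), 6), 0.010154)
  for (p in c(0.001, 0.02, 0.07, 0.3, 0.9)) {
    q <- annual_to_quarterly(p)
    expect_equal(1 - (1 - q)^4, p, tolerance = 1e-12)
    expect_equal(quarterly_to_annual(q), p, tolerance = 1e-12)
  }
  expect_error(annual_to_quarterly(1.2), "\\[0, 1\\]")
  expect_error(annual_to_quarterly(-0.1), "\\[0, 1\\]")
})

test_that("every reference event-rate cell reproduces its annual rate from 4 quarters", {
  for (device in c("ICD", "CRT-D")) {
    p <- reference_parameters(device, "legacy")
    for (tab in list(p$events$infection_annual, p$events$complication_annual)) {
      q <- annual_to_quarterly(tab)
      expect_true(all(abs((1 - (1 - q)^4) - tab) < 1e-12))
    }
  }
})

test_that("lognormal range fit pins the median and the closed-form log-sd", {
  s <- fit_lognormal_from_range(100, 50, 200, 0.95)
  expect_equal(s$sdlog, log(2) / qnorm(0.975), tolerance = 1e-12)
  expect_equal(exp(s$meanlog), 100)
  # battery-change outpatient range: median equals the configured central
  s2 <- fit_lognormal_from_range(24054, 24054, 25289)
  expect_equal(exp(s2$meanlog), 24054)
  # degenerate range is a point mass
  s3 <- fit_lognormal_from_range(100, 100, 100)
  expect_identical(s3$family, "point")
  expect_equal(cost_draw(s3, 5), rep(100, 5))
  expect_error(fit_lognormal_from_range(-1, 1, 2), "positive")
})

test_that("all reference lognormal cells have median within 0.1% of their central", {
  p <- reference_parameters("ICD", "legacy")
  for (cat in names(p$costs)) {
    for (st in names(p$costs[[cat]])) {
      for (cmp in names(p$costs[[cat]][[st]])) {
        for (band in names(p$costs[[cat]][[st]][[cmp]])) {
          s <- p$costs[[cat]][[st]][[cmp]][[band]]
          med <- switch(s$family,
                        lognormal = exp(s$meanlog),
                        s$central)
          expect_lt(abs(med - s$central) / s$central, 0.001)
        }
      }
    }
  }
})

test_that("scaled-beta fit keeps support on the range with mean at central", {
  s <- fit_beta_from_range(1023, 896, 1150, 4)
  expect_equal(cost_mean(s), 1023)
  set.seed(1)
  x <- cost_draw(s, 5000)
  expect_true(all(x >= 896 & x <= 1150))
  expect_equal(mean(x), 1023, tolerance = 0.01)
  # central on a range endpoint collapses to a point mass
  expect_identical(fit_beta_from_range(896, 896, 1150)$family, "point")
  expect_error(fit_beta_from_range(100, 150, 200), "low <= central")
})

test_that("battery calibration hits all four target medians within one quarter", {
  for (m in c(30, 52, 22, 40)) {
    spec <- calibrate_battery_hazard(m, 5)
    expect_lte(abs(battery_median(spec) - m), 1)
    expect_true(all(spec$hazard >= 0 & spec$hazard <= 1))
    expect_equal(spec$hazard[1], 0)          # no depletion at placement
    expect_equal(spec$hazard[2], 0)          # ... nor after one quarter
    expect_equal(spec$hazard[spec$cap + 1], 1)
  }
  expect_error(calibrate_battery_hazard(1), ">= 2")
})

test_that("a very large battery shape concentrates depletion at the median", {
  spec <- calibrate_battery_hazard(24, 80)
  s <- battery_survival(spec)
  # all depletion mass within one quarter of the median
  expect_gt(s[23], 0.99)    # P(T > 22): almost nothing depletes before 23
  expect_lt(s[26], 0.01)    # P(T > 25): almost everything has depleted by 25
})

test_that("battery quantiles are monotone in longevity (shared draw)", {
  legacy <- calibrate_battery_hazard(30, 5)
  extended <- calibrate_battery_hazard(52, 5)
  u <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(battery_quantile(extended, u) >= battery_quantile(legacy, u)))
})

test_that("reference parameter sets carry the stated reference values", {
  p <- reference_parameters("ICD", "legacy")
  expect_equal(unname(p$mortality$operative),
               c(0.017, 0.034, 0.002))       # primary, revision, battery change
  expect_equal(p$horizon_quarters, 60L)
  expect_equal(p$n_patients, 20000L)
  expect_equal(p$discount_rate_annual, 0.03)
  expect_equal(sum(p$population$case_mix), 1)
  expect_equal(unname(p$population$inpatient_share$generator_change), rep(0, 3))
  expect_equal(p$battery$median_quarters, 30)
  expect_equal(reference_parameters("CRT-D", "extended")$battery$median_quarters, 40)
  # zero-discount configuration is valid
  expect_s3_class(reference_parameters("ICD", "legacy", discount_rate_annual = 0),
                  "cied_parameters")
})

test_that("serialisation round-trips bitwise", {
  p <- reference_parameters("CRT-D", "extended", n_patients = 123L, seed = 99L)
  f <- tempfile(fileext = ".yaml")
  write_parameters(p, f)
  expect_identical(load_parameters(f), p)
})

test_that("validation rejects malformed configurations with named errors", {
  p <- reference_parameters("ICD", "legacy")
  bad <- p; bad$population$case_mix <- c(low = 0.3, mid = 0.3, high = 0.3)
  expect_error(validate_parameters(bad), "case_mix")
  bad <- p; bad$events$infection_annual[1, 1] <- 1.4
  expect_error(validate_parameters(bad), "infection_annual")
  bad <- p; bad$costs$follow_up$any$combined$low$low <- 1e6
  expect_error(validate_parameters(bad), "low <= central")
  bad <- p; bad$population$inpatient_share$generator_change[1] <- 0.5
  expect_error(validate_parameters(bad), "outpatient")
  cfg <- yaml::yaml.load(write_parameters(p))
  cfg$mortality <- NULL
  expect_error(load_parameters(cfg), "mortality")
})
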