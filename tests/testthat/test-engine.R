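test_that("discount factors follow the quarterly present-value formula", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(4, 0.03), 1 / 1.03)
  expect_equal(discount_factor(37, 0), 1)
  expect_equal(discount_factor(10, 0.06), 1.06^(-2.5))
  expect_error(discount_factor(-1, 0.03), ">= 0")
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("stepping a dead patient is a contract violation", {
  p <- small_params()
  st <- new_patient_state(75, "mid")
  st$alive <- FALSE
  expect_error(step_patient(st, p, runif(10)), "contract violation")
})

test_that("event-free limit: full horizon of maintenance, no battery change", {
  p <- quiet_params(battery_median = 70)   # median beyond the 60-quarter horizon
  tr <- simulate_patient(p, event_seed = 3L, keep_events = TRUE)
  expect_equal(unname(tr$counts["battery_change"]), 0)
  expect_equal(unname(tr$counts["revision"]), 0)
  expect_equal(tr$ly, 15)
  expect_true(is.na(tr$death_cycle))
  # implant cycle then 59 maintenance cycles
  expect_equal(sum(tr$events$kind == "maintenance"), 59)
  expect_equal(sum(tr$events$kind == "primary_implant"), 1)
})

test_that("certain operative death at implant ends the trajectory at cycle 0", {
  p <- quiet_params()
  p$mortality$operative[] <- c(1, 1, 1)
  tr <- simulate_patient(p, event_seed = 5L, keep_events = TRUE)
  expect_equal(tr$ly, 0)
  expect_equal(tr$death_cycle, 0L)
  expect_identical(tr$death_kind, "operative_death")
  expect_equal(nrow(tr$events), 2L)  # the implant and the operative death
  expect_true(all(tr$events$cycle == 0))
})

test_that("battery changes are gated, outpatient, and cluster at the median", {
  p <- small_params(n = 300L, seed = 11L)
  p$mortality$base_rate <- 1e-12   # isolate the depletion process
  p$mortality$operative[] <- 0
  p$events$infection_annual[] <- 0
  p$events$complication_annual[] <- 0
  p$events$revision_other_annual[] <- 0
  cp <- ciedsim:::compile_parameters(p)
  first_change <- rep(NA_integer_, 300)
  for (i in 1:300) {
    tr <- simulate_patient(p, event_seed = 1000L + i, compiled = cp,
                           keep_events = TRUE)
    ev <- tr$events
    bc <- ev[ev$kind == "battery_change", , drop = FALSE]
    if (nrow(bc)) {
      first_change[i] <- bc$cycle[1]
      expect_true(all(bc$setting == "outpatient"))
      expect_true(all(bc$cycle >= 2))  # implant cycle plus >= 1 maintenance cycle
    }
  }
  # with no mortality, every patient reaches depletion (median 30 < horizon)
  expect_true(all(!is.na(first_change)))
  med <- median(first_change)
  expect_lte(abs(med - 30), 1)
})

test_that("cohort runs are reproducible and respect discount monotonicity", {
  p0 <- small_params(n = 400L, seed = 21L, discount_rate_annual = 0)
  p3 <- small_params(n = 400L, seed = 21L, discount_rate_annual = 0.03)
  p6 <- small_params(n = 400L, seed = 21L, discount_rate_annual = 0.06)
  c3a <- run_cohort(p3)
  c3b <- run_cohort(p3)
  expect_identical(c3a$patients, c3b$patients)
  c0 <- run_cohort(p0); c6 <- run_cohort(p6)
  # same seed => identical event histories; only discounting differs
  expect_identical(c0$patients$battery_change, c3a$patients$battery_change)
  expect_true(all(c0$patients$cost_disc >= c3a$patients$cost_disc))
  expect_true(all(c3a$patients$cost_disc >= c6$patients$cost_disc))
  expect_true(all(c0$patients$ly_disc >= c3a$patients$ly_disc))
  expect_true(all(c3a$patients$ly_disc >= c6$patients$ly_disc))
  # trajectory invariants
  expect_true(all(c3a$patients$cost_disc <= c3a$patients$cost_undisc + 1e-9))
  expect_true(all(c3a$patients$ly <= 15 + 1e-12))
})

test_that("no costs, events or life years accrue after death", {
  p <- small_params(n = 1L, seed = 31L)
  p$mortality$base_rate <- 1.5   # very high mortality to exercise death paths
  for (s in 1:40) {
    tr <- simulate_patient(p, event_seed = s, keep_events = TRUE)
    if (!is.na(tr$death_cycle)) {
      expect_true(all(tr$events$cycle <= tr$death_cycle))
      expect_equal(tr$ly, 0.25 * tr$death_cycle)
    }
  }
})

test_that("paired runs with common random numbers: extended battery dominates", {
  leg <- run_cohort(small_params("ICD", "legacy", n = 1500L, seed = 77L))
  ext <- run_cohort(small_params("ICD", "extended", n = 1500L, seed = 77L))
  pl <- leg$patients; pe <- ext$patients
  # entry covariates are shared patient by patient
  expect_identical(pl$cci, pe$cci)
  # among patients with identical death cycles the depletion-quantile draws
  # are shared, so the extended battery can never produce more changes
  same_death <- which(
    (is.na(pl$death_cycle) & is.na(pe$death_cycle)) |
      (!is.na(pl$death_cycle) & !is.na(pe$death_cycle) &
         pl$death_cycle == pe$death_cycle))
  expect_gt(length(same_death), 1000)
  expect_true(all(pe$battery_change[same_death] <= pl$battery_change[same_death]))
  # cohort-level dominance
  expect_lt(mean(pe$battery_change), mean(pl$battery_change))
  expect_gte(100 * mean(pe$battery_change == 0), 100 * mean(pl$battery_change == 0))
})

test_that("state-occupancy proportions are conserved across the cohort", {
  p <- small_params(n = 200L, seed = 41L)
  cp <- ciedsim:::compile_parameters(p)
  # across a cohort, at every cycle each patient is in exactly one state:
  # alive (A/B/C/D) or dead; reconstruct occupancy from trajectories
  alive_at <- matrix(0L, nrow = 200, ncol = 61)
  for (i in 1:200) {
    tr <- simulate_patient(p, event_seed = 5000L + i, compiled = cp)
    # a patient occupies exactly one state at the start of every cycle up to
    # and including the death cycle
    last <- if (is.na(tr$death_cycle)) 60L else tr$death_cycle + 1L
    alive_at[i, seq_len(last)] <- 1L
  }
  occ_alive <- colMeans(alive_at)
  expect_true(all(occ_alive >= 0 & occ_alive <= 1))
  expect_equal(occ_alive[1], 1)  # everyone enters at the implant state
})
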