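test_that("expanded-chain transition matrices are row-stochastic with an absorbing dead state", {
  p <- small_params(n = 10L)
  ch <- build_expanded_chain(p)
  for (cyc in c(0L, 7L, 40L)) {
    M <- transition_matrix(ch, cyc, cci = 2L, entry_age = 74.5)
    expect_equal(max(abs(Matrix::rowSums(M) - 1)), 0, tolerance = 1e-9)
    dead <- ch$ix$dead
    expect_equal(as.numeric(M[dead, dead]), 1)
    expect_equal(sum(M[dead, ] != 0), 1)
  }
})

test_that("a battery cap beyond the tunnel depth is a configuration error", {
  p <- small_params()
  p$battery <- calibrate_battery_hazard(250, 5)
  expect_error(build_expanded_chain(p), "tunnel depth")
})

test_that("with all hazards zero the maintenance state self-loops to the horizon", {
  # near-deterministic battery life far beyond the horizon
  p <- quiet_params(battery_median = 70, shape = 100)
  ch <- build_expanded_chain(p)
  ex <- expected_outcomes(ch, p)
  expect_lt(unname(ex$counts["battery_change"]), 1e-6)
  expect_lt(unname(ex$counts["revision"]), 1e-6)
  expect_equal(ex$ly, 15, tolerance = 1e-6)
})

test_that("mortality-only expected life years equal the survival-curve sum", {
  p <- quiet_params()
  p$mortality$base_rate <- 0.12   # mortality on, all events still off
  ex <- expected_outcomes(build_expanded_chain(p), p)
  # independent closed form: LY = 0.25 * sum over cycles of P(alive through
  # that cycle), mixing over the entry-age grid and case mix
  grid <- entry_age_grid(p$population$entry_age$mean, p$population$entry_age$sd,
                         p$population$entry_age$lower, p$population$entry_age$upper)
  ly <- 0; ly_disc <- 0
  df <- discount_factor(0:59, p$discount_rate_annual)
  for (ci in 1:3) {
    for (ai in seq_along(grid$age)) {
      w <- unname(p$population$case_mix[ci]) * grid$weight[ai]
      if (w < 1e-12) next
      S <- 1
      for (cyc in 0:59) {
        q <- mortality_quarterly_prob(p$mortality, grid$age[ai] + 0.25 * cyc, ci)
        S <- S * (1 - q)
        ly <- ly + w * 0.25 * S
        ly_disc <- ly_disc + w * 0.25 * S * df[cyc + 1]
      }
    }
  }
  expect_equal(ex$ly, ly, tolerance = 1e-9)
  expect_equal(ex$ly_disc, ly_disc, tolerance = 1e-9)
})

test_that("certain death at implant leaves only the implant cost", {
  p <- quiet_params()
  p$mortality$operative["primary_implant"] <- 1
  p$mortality$operative["revision"] <- 1
  ex <- expected_outcomes(build_expanded_chain(p), p)
  expect_equal(ex$ly, 0, tolerance = 1e-12)
  cp <- ciedsim:::compile_parameters(p)
  expected_cost <- sum(vapply(1:3, function(ci) {
    pin <- cp$p_inpat_primary[[ci]]
    p$population$case_mix[ci] *
      (pin * (cost_mean(cp$costs$primary_in$inst[[ci]]) +
                cost_mean(cp$costs$primary_in$prof[[ci]])) +
         (1 - pin) * (cost_mean(cp$costs$primary_out$inst[[ci]]) +
                        cost_mean(cp$costs$primary_out$prof[[ci]])))
  }, 0))
  expect_equal(ex$cost_disc, expected_cost, tolerance = 1e-9)
})

test_that("undiscounted outcomes dominate discounted outcomes on the same chain", {
  p3 <- small_params(n = 10L, discount_rate_annual = 0.03)
  p0 <- small_params(n = 10L, discount_rate_annual = 0)
  ex3 <- expected_outcomes(build_expanded_chain(p3), p3)
  ex0 <- expected_outcomes(build_expanded_chain(p0), p0)
  expect_gt(ex0$cost_disc, ex3$cost_disc)
  expect_gt(ex0$ly_disc, ex3$ly_disc)
  expect_equal(ex0$cost_disc, ex0$cost_undisc, tolerance = 1e-9)
  # event counts are untouched by the discount rate
  expect_equal(ex0$counts, ex3$counts, tolerance = 1e-12)
})

test_that("engine means match oracle expectations within 3 SE (reference ICD)", {
  p <- small_params("ICD", "legacy", n = 4000L, seed = 5L)
  z <- oracle_engine_z(p, n = 4000L)
  expect_true(all(abs(z) < 3), info = paste(names(z), round(z, 2), collapse = "; "))
})
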