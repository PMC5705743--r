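codes <- load_code_dictionary()

hand_claims <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(beneficiary_id = r$id, service_date = as.Date(r$date),
               setting = r$setting %||% "outpatient",
               component = r$component %||% "institutional",
               procedure_codes = paste(r$proc %||% character(0), collapse = ";"),
               diagnosis_codes = paste(r$dx %||% character(0), collapse = ";"),
               paid_amount = r$paid %||% 100,
               price_month = format(as.Date(r$date), "%Y-%m"),
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

hand_beneficiaries <- function(ids, birth = "1935-06-01", enroll = "2002-01-01",
                               in_states = TRUE, hmo = FALSE) {
  data.frame(beneficiary_id = ids, birth_date = as.Date(birth),
             enrollment_start = as.Date(enroll),
             enrollment_end = as.Date("2014-12-31"),
             in_50_states = in_states, hmo = hmo, death_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

test_that("cohort identification applies every exclusion rule", {
  bens <- rbind(
    hand_beneficiaries("OK1"),
    hand_beneficiaries("DIRTY"),                       # implant already in 2003
    hand_beneficiaries("YOUNG", birth = "1945-01-01"), # 60 at index
    hand_beneficiaries("OUT", in_states = FALSE),
    hand_beneficiaries("HMO", hmo = TRUE),
    hand_beneficiaries("LATE", enroll = "2003-06-01"))
  cl <- hand_claims(
    list(id = "OK1", date = "2005-03-01", proc = "33249"),
    list(id = "DIRTY", date = "2003-05-01", proc = "33249"),
    list(id = "DIRTY", date = "2005-04-01", proc = "33249"),
    list(id = "YOUNG", date = "2005-03-01", proc = "33249"),
    list(id = "OUT", date = "2005-03-01", proc = "33249"),
    list(id = "HMO", date = "2005-03-01", proc = "33249"),
    list(id = "LATE", date = "2005-03-01", proc = "33249"))
  cohort <- identify_cohort(bens, cl, codes)
  expect_identical(cohort$beneficiary_id, "OK1")
  expect_identical(cohort$device, "ICD")
  # the same records in a different row order give the same cohort
  cohort2 <- identify_cohort(bens, cl[rev(seq_len(nrow(cl))), ], codes)
  expect_identical(cohort2, cohort)
})

test_that("the concurrent pacing-lead code marks a CRT-D index implant", {
  bens <- hand_beneficiaries(c("A", "B"))
  cl <- hand_claims(
    list(id = "A", date = "2006-01-10", proc = c("33249", "33225")),
    list(id = "B", date = "2006-01-10", proc = "33249"))
  cohort <- identify_cohort(bens, cl, codes)
  expect_identical(cohort$device[cohort$beneficiary_id == "A"], "CRT-D")
  expect_identical(cohort$device[cohort$beneficiary_id == "B"], "ICD")
})

test_that("Charlson scoring sums condition weights and counts each condition once", {
  bens <- hand_beneficiaries("A")
  cl <- hand_claims(
    list(id = "A", date = "2006-01-10", proc = "33249"),
    # two weight-1 conditions and one weight-2 condition -> score 4, band mid
    list(id = "A", date = "2005-06-01", dx = "428"),
    list(id = "A", date = "2005-07-01", dx = "496"),
    list(id = "A", date = "2005-08-01", dx = "585"),
    # the same condition coded on many claims counts once
    list(id = "A", date = "2005-09-01", dx = "428"),
    list(id = "A", date = "2005-10-01", dx = "428"),
    list(id = "A", date = "2005-11-01", dx = "428"))
  cohort <- compute_cci(cl, identify_cohort(bens, cl, codes), codes)
  expect_equal(cohort$cci_score, 4L)
  expect_identical(cohort$cci_band, "mid")
  # naive per-claim summation would give a different (wrong) score
  ch <- codes$charlson
  naive <- sum(ch$weight[match(c("428", "496", "585", "428", "428", "428"), ch$code)])
  expect_gt(naive, cohort$cci_score)

  # no qualifying diagnoses -> score 0, band low
  bens0 <- hand_beneficiaries("Z")
  cl0 <- hand_claims(list(id = "Z", date = "2006-01-10", proc = "33249"))
  c0 <- compute_cci(cl0, identify_cohort(bens0, cl0, codes), codes)
  expect_equal(c0$cci_score, 0L)
  expect_identical(c0$cci_band, "low")
})

test_that("infection attribution needs diagnosis plus procedure on one record, within a year", {
  bens <- hand_beneficiaries(c("A", "B", "C"))
  cl <- hand_claims(
    list(id = "A", date = "2006-01-10", proc = "33249"),
    # device-infection diagnosis without any revision procedure: not an event
    list(id = "A", date = "2006-03-01", dx = "996.61"),
    list(id = "B", date = "2006-01-10", proc = "33249"),
    # sepsis diagnosis plus pocket revision on the same record: an event
    list(id = "B", date = "2006-04-01", dx = "038.9", proc = "33222"),
    list(id = "C", date = "2006-01-10", proc = "33249"),
    # qualifying record five quarters after the implant: not attributed
    list(id = "C", date = "2007-05-01", dx = "996.61", proc = "33222"))
  cohort <- identify_cohort(bens, cl, codes)
  infs <- identify_infections(cl, cohort, codes)
  expect_equal(nrow(infs), 1L)
  expect_identical(infs$beneficiary_id, "B")
  expect_identical(infs$attributed_to, "primary_implant")
})

test_that("cost inflation follows the price index exactly", {
  bens <- hand_beneficiaries("A")
  cl <- hand_claims(
    list(id = "A", date = "2006-01-10", proc = "33249", paid = 100))
  cohort <- identify_cohort(bens, cl, codes)
  flat <- derive_quarterly_costs(cl, cohort, price_index_series(0))
  expect_equal(unname(flat$index_quarter_median["institutional"]), 100)
  # index doubling: a claim at half the target price level inflates 2x
  pi2 <- price_index_series(0)
  pi2$index[pi2$month == "2006-01"] <- 0.5
  doubled <- derive_quarterly_costs(cl, cohort, pi2)
  expect_equal(unname(doubled$index_quarter_median["institutional"]), 200)
  # a missing service month is an error naming the month
  short <- price_index_series(0, from = "2010-01")
  expect_error(derive_quarterly_costs(cl, cohort, short), "2006-01")
})

test_that("generation is reproducible and respects a zero infection rate", {
  spec <- claims_generation_spec(60, annual_infection_rate = 0)
  g1 <- generate_claims(spec, seed = 5)
  g2 <- generate_claims(spec, seed = 5)
  expect_identical(g1, g2)
  cohort <- identify_cohort(g1$beneficiaries, g1$claims)
  expect_equal(nrow(identify_infections(g1$claims, cohort)), 0L)
  expect_equal(sum(g1$ground_truth$n_infections), 0L)
})

test_that("derivation recovers generated rates and costs (round trip)", {
  spec <- claims_generation_spec(600, annual_infection_rate = 0.05)
  g <- generate_claims(spec, seed = 31, price_index = price_index_series(0.03))
  cohort <- identify_cohort(g$beneficiaries, g$claims)
  truth <- g$ground_truth[match(cohort$beneficiary_id,
                                g$ground_truth$beneficiary_id), ]
  # cohort identification and CCI agree with ground truth exactly
  expect_setequal(cohort$beneficiary_id,
                  g$ground_truth$beneficiary_id[g$ground_truth$eligible])
  expect_identical(cohort$device, truth$device)
  cc <- compute_cci(g$claims, cohort)
  expect_identical(cc$cci_score, as.integer(truth$cci_score))

  # infection rate after primary implant within the binomial 95% CI
  rates <- derive_event_rates(g$claims, cohort)
  truth_rate <- mean(truth$infected_after_primary)
  ci <- truth_rate + c(-1, 1) * 1.96 *
    sqrt(truth_rate * (1 - truth_rate) / nrow(cohort))
  expect_gte(rates$infection_first_year_rate, ci[1])
  expect_lte(rates$infection_first_year_rate, ci[2])

  # inflated cost medians recover the configured 2016-level centrals
  costs <- derive_quarterly_costs(g$claims, cohort,
                                  price_index = price_index_series(0.03))
  expect_lt(abs(costs$maintenance_median - spec$cost_maintenance) /
              spec$cost_maintenance, 0.05)
  expect_lt(abs(costs$index_quarter_median[["institutional"]] -
                  spec$cost_implant_institutional) /
              spec$cost_implant_institutional, 0.05)

  # a derived parameter set is valid and carries the derived rate
  params <- derive_parameters(g$claims, cohort,
                              price_index = price_index_series(0.03))
  expect_s3_class(params, "cied_parameters")
  expect_equal(unname(params$events$infection_annual[, "primary_implant"]),
               rep(rates$infection_first_year_rate, 3))
})
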