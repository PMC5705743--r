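# Synthetic administrative-claims generator. Emulates the structure of a 5%
# Medicare Limited Data Set extract -- longitudinal per-beneficiary
# institutional and professional claim lines with CPT/ICD-9 codes, service
# dates, settings and paid amounts -- with a known ground truth, so the
# claims-derivation rules can be tested end to end without restricted data.

#' Load a code dictionary
#'
#' @param path YAML dictionary; defaults to the packaged representative
#'   dictionary.
#' @return A list with `procedures`, `diagnoses` and `charlson` groups.
#' @export
load_code_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_dictionary.yaml",
                                package = "ciedsim", mustWork = TRUE)
  dict <- yaml::read_yaml(path)
  dict$charlson <- do.call(rbind, lapply(dict$charlson, as.data.frame))
  dict
}

#' Default generation parameters for the synthetic-claims module
#'
#' The defaults emulate the derivation cohort: entry ages around 74.6 (SD
#' 6.1), implants spread over 2004-2013 within a 2003-2014 enrollment
#' window, ~30% CRT-D, a 3% first-year infection risk and 5% first-year
#' complication risk after each procedure, generator replacement with a
#' 30-quarter median, and small fractions of beneficiaries constructed to
#' violate each cohort-entry rule so the exclusion filters are exercised.
#'
#' @param n_beneficiaries Cohort size to generate.
#' @param ... Overrides of any default field.
#' @return A named list of generation parameters.
#' @export
claims_generation_spec <- function(n_beneficiaries = 1000L, ...) {
  spec <- list(
    n_beneficiaries = as.integer(n_beneficiaries),
    crtd_share = 0.30,
    age_mean = 74.6, age_sd = 6.1,
    p_under65 = 0.04, p_out_of_state = 0.03, p_hmo = 0.03,
    p_dirty_2003 = 0.03, p_late_enrollment = 0.02,
    inpatient_share = 0.56,
    annual_infection_rate = 0.03,
    annual_complication_rate = 0.05,
    battery_median_quarters = 30, battery_shape = 5,
    annual_death_rate = 0.08,
    p_stray_infection_dx = 0.10,   # infection diagnosis without a procedure
    condition_prevalence = c(congestive_heart_failure = 0.65,
                             myocardial_infarction = 0.25,
                             diabetes = 0.30,
                             diabetes_with_complications = 0.12,
                             chronic_pulmonary_disease = 0.25,
                             renal_disease = 0.20,
                             cerebrovascular_disease = 0.15,
                             malignancy = 0.10,
                             metastatic_solid_tumor = 0.03,
                             dementia = 0.07),
    cost_implant_institutional = 50000, cost_implant_professional = 1300,
    cost_generator_change = 24500, cost_revision = 20000,
    cost_infection_claim = 30000, cost_complication_claim = 1000,
    cost_maintenance = 114, cost_comorbidity_claim = 150,
    cost_sdlog = 0.2,
    study_start = as.Date("2004-01-01"), study_end = as.Date("2014-12-31")
  )
  utils::modifyList(spec, list(...))
}

#' A monthly medical-care price index series
#'
#' @param annual_growth Annual growth rate of the index (0 gives the flat
#'   default used in tests).
#' @param from,to Month range (inclusive), as `"YYYY-MM"`.
#' @return Data frame with `month` (`"YYYY-MM"`) and `index`.
#' @export
price_index_series <- function(annual_growth = 0, from = "2002-01", to = "2016-12") {
  months <- seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")), by = "month")
  k <- seq_along(months) - 1L
  data.frame(month = format(months, "%Y-%m"),
             index = (1 + annual_growth)^(k / 12))
}

claim_row <- function(id, date, setting, component, proc, dx, paid) {
  data.frame(beneficiary_id = id, service_date = date, setting = setting,
             component = component,
             procedure_codes = paste(proc, collapse = ";"),
             diagnosis_codes = paste(dx, collapse = ";"),
             paid_amount = paid,
             price_month = format(date, "%Y-%m"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic claims extract with known ground truth
#'
#' @param spec Generation parameters from [claims_generation_spec()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param price_index Monthly price index used to state paid amounts at
#'   their historical price level (defaults to a flat series, i.e. amounts
#'   already at the January 2016 level).
#' @param codes Code dictionary (defaults to the packaged one).
#' @return A list with `beneficiaries`, `claims` and `ground_truth` data
#'   frames.
#' @export
generate_claims <- function(spec = claims_generation_spec(), seed = 1L,
                            price_index = price_index_series(),
                            codes = load_code_dictionary()) {
  set.seed(seed)
  n <- spec$n_beneficiaries
  battery <- calibrate_battery_hazard(spec$battery_median_quarters,
                                      spec$battery_shape)
  idx_2016 <- price_index$index[price_index$month == "2016-01"]
  deflate <- function(amount, date) {
    m <- format(date, "%Y-%m")
    i <- price_index$index[match(m, price_index$month)]
    amount * i / idx_2016
  }
  rcost <- function(central, date) {
    deflate(stats::rlnorm(1, log(central), spec$cost_sdlog), date)
  }
  charlson <- codes$charlson
  cond_codes <- split(charlson$code, charlson$condition)
  cond_weight <- vapply(split(charlson$weight, charlson$condition), `[`, 0, 1)

  ben_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  claim_acc <- vector("list", n)

  for (i in seq_len(n)) {
    id <- sprintf("SYN%06d", i)
    index_date <- spec$study_start +
      floor(stats::runif(1, 0, as.numeric(as.Date("2013-12-31") - spec$study_start)))
    # exclusion flags (mutually exclusive by draw order, mostly)
    u <- stats::runif(5)
    under65 <- u[1] < spec$p_under65
    out_of_state <- u[2] < spec$p_out_of_state
    hmo <- u[3] < spec$p_hmo
    dirty_2003 <- u[4] < spec$p_dirty_2003
    late_enrollment <- u[5] < spec$p_late_enrollment
    age_at_index <- if (under65) stats::runif(1, 58, 64.9) else
      max(66, stats::rnorm(1, spec$age_mean, spec$age_sd))
    birth_date <- index_date - round(age_at_index * 365.25)
    enrollment_start <- if (late_enrollment) as.Date("2003-07-01") else as.Date("2002-01-01")
    device <- if (stats::runif(1) < spec$crtd_share) "CRT-D" else "ICD"
    death_offset_days <- stats::rexp(1, spec$annual_death_rate) * 365.25
    death_date <- index_date + round(death_offset_days)
    if (death_date > spec$study_end) death_date <- as.Date(NA)
    follow_end <- min(death_date, spec$study_end, na.rm = TRUE)

    cl <- list()
    # pre-index comorbidity claims (conditions may be coded repeatedly)
    conds <- names(spec$condition_prevalence)[
      stats::runif(length(spec$condition_prevalence)) < spec$condition_prevalence]
    conds <- intersect(conds, names(cond_codes))
    for (cond in conds) {
      for (k in seq_len(1L + stats::rpois(1, 1.0))) {
        d <- index_date - sample.int(360L, 1L)
        cl[[length(cl) + 1L]] <- claim_row(id, d, "outpatient", "professional",
                                           character(0),
                                           sample(cond_codes[[cond]], 1L),
                                           rcost(spec$cost_comorbidity_claim, d))
      }
    }
    cci_score <- sum(cond_weight[conds])

    if (dirty_2003) {
      d <- as.Date("2003-06-15")
      cl[[length(cl) + 1L]] <- claim_row(id, d, "inpatient", "institutional",
                                         codes$procedures$primary_implant, character(0),
                                         rcost(spec$cost_implant_institutional, d))
    }

    # index implant claim (institutional + professional lines)
    setting <- if (stats::runif(1) < spec$inpatient_share) "inpatient" else "outpatient"
    proc <- c(codes$procedures$primary_implant,
              if (device == "CRT-D") codes$procedures$crtd_pacing_lead)
    cl[[length(cl) + 1L]] <- claim_row(id, index_date, setting, "institutional",
                                       proc, character(0),
                                       rcost(spec$cost_implant_institutional, index_date))
    cl[[length(cl) + 1L]] <- claim_row(id, index_date, setting, "professional",
                                       proc, character(0),
                                       rcost(spec$cost_implant_professional, index_date))

    # generator changes driven by the battery law, while alive and in study
    gen_dates <- as.Date(character(0))
    t_gen <- battery_quantile(battery, stats::runif(1))
    last_gen <- index_date
    while (TRUE) {
      d <- last_gen + round(t_gen * 91.3125)
      if (d > follow_end) break
      gen_dates <- c(gen_dates, d)
      cl[[length(cl) + 1L]] <- claim_row(id, d, "outpatient", "institutional",
                                         sample(codes$procedures$generator_change, 1L),
                                         character(0),
                                         rcost(spec$cost_generator_change, d))
      last_gen <- d
      t_gen <- battery_quantile(battery, stats::runif(1))
    }

    # first-year infections after each device procedure: diagnosis plus a
    # revision-type procedure on the same claim record
    infection_dates <- as.Date(character(0))
    infected_after_primary <- FALSE
    proc_dates <- c(index_date, gen_dates)
    class(proc_dates) <- "Date"
    for (p_date in as.list(proc_dates)) {
      if (stats::runif(1) < spec$annual_infection_rate) {
        d <- p_date + sample.int(360L, 1L)
        if (d <= follow_end) {
          infection_dates <- c(infection_dates, d)
          if (p_date == index_date) infected_after_primary <- TRUE
          dx <- sample(c(codes$diagnoses$device_infection,
                         codes$diagnoses$infection_related), 1L)
          proc_inf <- sample(c(codes$procedures$lead_revision,
                               codes$procedures$pocket_revision,
                               codes$procedures$generator_removal), 1L)
          cl[[length(cl) + 1L]] <- claim_row(id, d, "inpatient", "institutional",
                                             proc_inf, dx,
                                             rcost(spec$cost_infection_claim, d))
        }
      }
      if (stats::runif(1) < spec$annual_complication_rate) {
        d <- p_date + sample.int(360L, 1L)
        if (d <= follow_end) {
          cl[[length(cl) + 1L]] <- claim_row(id, d, "outpatient", "institutional",
                                             character(0),
                                             sample(codes$diagnoses$complication, 1L),
                                             rcost(spec$cost_complication_claim, d))
        }
      }
    }

    # stray infection-type diagnosis without any procedure: must not count
    if (stats::runif(1) < spec$p_stray_infection_dx) {
      d <- index_date + sample.int(720L, 1L)
      if (d <= follow_end) {
        cl[[length(cl) + 1L]] <- claim_row(id, d, "outpatient", "professional",
                                           character(0),
                                           sample(codes$diagnoses$infection_related, 1L),
                                           rcost(200, d))
      }
    }

    # quarterly device-monitoring claims
    q <- 1L
    repeat {
      d <- index_date + round(q * 91.3125)
      if (d > follow_end) break
      cl[[length(cl) + 1L]] <- claim_row(id, d, "outpatient", "professional",
                                         sample(codes$procedures$maintenance, 1L),
                                         character(0),
                                         rcost(spec$cost_maintenance, d))
      q <- q + 1L
    }

    claim_acc[[i]] <- do.call(rbind, cl)
    ben_rows[[i]] <- data.frame(
      beneficiary_id = id, birth_date = birth_date,
      enrollment_start = enrollment_start, enrollment_end = spec$study_end,
      in_50_states = !out_of_state, hmo = hmo, death_date = death_date,
      stringsAsFactors = FALSE)
    excl <- if (under65) "under_65" else if (out_of_state) "out_of_state"
      else if (hmo) "hmo" else if (dirty_2003) "procedure_in_2003"
      else if (late_enrollment) "late_enrollment" else NA_character_
    truth_rows[[i]] <- data.frame(
      beneficiary_id = id, eligible = is.na(excl), exclusion_reason = excl,
      device = device, index_date = index_date, age_at_index = age_at_index,
      cci_score = cci_score,
      cci_band = c("low", "mid", "high")[findInterval(cci_score, c(0, 3, 5))],
      n_generator_changes = length(gen_dates),
      n_infections = length(infection_dates),
      infected_after_primary = infected_after_primary,
      death_date = death_date, stringsAsFactors = FALSE)
  }

  claims <- do.call(rbind, claim_acc)
  claims <- claims[order(claims$beneficiary_id, claims$service_date), ]
  rownames(claims) <- NULL
  list(beneficiaries = do.call(rbind, ben_rows),
       claims = claims,
       ground_truth = do.call(rbind, truth_rows))
}
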