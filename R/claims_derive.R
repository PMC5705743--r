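# Claims-derivation rules: cohort identification, Charlson comorbidity
# index, infection attribution, quarterly cost aggregation with price-index
# inflation, and event-rate derivation. These mirror the rules used to
# derive the model parameters from administrative claims.

has_code <- function(code_field, codes) {
  if (!length(codes)) return(rep(FALSE, length(code_field)))
  vapply(strsplit(code_field, ";", fixed = TRUE),
         function(x) any(x %in% codes), TRUE)
}

# one record per (beneficiary, date): institutional and professional lines
# of one encounter share codes and dates
claim_records <- function(claims) {
  key <- paste(claims$beneficiary_id, claims$service_date)
  agg <- claims[!duplicated(key), c("beneficiary_id", "service_date")]
  codes_by <- split(seq_len(nrow(claims)), key)
  agg <- claims[match(names(codes_by), key), c("beneficiary_id", "service_date")]
  agg$procedure_codes <- vapply(codes_by, function(ix)
    paste(unique(unlist(strsplit(claims$procedure_codes[ix], ";", fixed = TRUE))),
          collapse = ";"), "")
  agg$diagnosis_codes <- vapply(codes_by, function(ix)
    paste(unique(unlist(strsplit(claims$diagnosis_codes[ix], ";", fixed = TRUE))),
          collapse = ";"), "")
  rownames(agg) <- NULL
  agg[order(agg$beneficiary_id, agg$service_date), ]
}

#' Identify the implant cohort from claims
#'
#' Applies the cohort-entry rules: the index event is the first
#' primary-implant-coded claim (CPT 33249) in the study window; the device
#' is CRT-D when the concurrent pacing-lead code (CPT 33225) appears on the
#' same claim record. Beneficiaries are excluded when younger than 65 at
#' index, residing outside the 50 states, HMO-enrolled, not enrolled from
#' January 1 2003, or with any study procedure during 2003 (the clean-period
#' rule for first implants).
#'
#' @param beneficiaries,claims Data frames from [generate_claims()] (or with
#'   the same column schema).
#' @param codes Code dictionary.
#' @param study_start,study_end Index-event window.
#' @return Data frame: `beneficiary_id`, `index_date`, `device`,
#'   `age_at_index`.
#' @export
identify_cohort <- function(beneficiaries, claims, codes = load_code_dictionary(),
                            study_start = as.Date("2004-01-01"),
                            study_end = as.Date("2014-12-31")) {
  rec <- claim_records(claims)
  rec$is_implant <- has_code(rec$procedure_codes, codes$procedures$primary_implant)
  study_codes <- unlist(codes$procedures[c("primary_implant", "generator_change",
                                           "lead_revision", "pocket_revision",
                                           "generator_removal")])
  rec$is_study_proc <- has_code(rec$procedure_codes, study_codes)

  out <- lapply(split(rec, rec$beneficiary_id), function(r) {
    idx <- r$is_implant & r$service_date >= study_start & r$service_date <= study_end
    if (!any(idx)) return(NULL)
    first <- which(idx)[1]
    dirty_2003 <- any(r$is_study_proc &
                        r$service_date >= as.Date("2003-01-01") &
                        r$service_date < study_start)
    if (dirty_2003) return(NULL)
    # not a first implant if any earlier study procedure exists
    if (any(r$is_study_proc & r$service_date < r$service_date[first])) return(NULL)
    data.frame(beneficiary_id = r$beneficiary_id[1],
               index_date = r$service_date[first],
               device = if (has_code(r$procedure_codes[first],
                                     codes$procedures$crtd_pacing_lead))
                 "CRT-D" else "ICD",
               stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, out)
  if (is.null(cohort)) {
    return(data.frame(beneficiary_id = character(0), index_date = as.Date(character(0)),
                      device = character(0), age_at_index = numeric(0)))
  }
  rownames(cohort) <- NULL
  b <- beneficiaries[match(cohort$beneficiary_id, beneficiaries$beneficiary_id), ]
  cohort$age_at_index <- as.numeric(cohort$index_date - b$birth_date) / 365.25
  keep <- cohort$age_at_index >= 65 &
    b$in_50_states & !b$hmo &
    b$enrollment_start <= as.Date("2003-01-01")
  cohort <- cohort[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

#' Compute the Charlson comorbidity index from pre-index claims
#'
#' Compiles diagnosis codes from the one-year pre-implant window, maps them
#' to Charlson conditions (each condition counted once regardless of how
#' many claims carry it) and sums the weights; the score is banded as 0-2
#' (low), 3-4 (mid) and 5+ (high).
#'
#' @param claims Claims data frame.
#' @param cohort Result of [identify_cohort()].
#' @param codes Code dictionary with a `charlson` table.
#' @return `cohort` with `cci_score` and `cci_band` columns appended.
#' @export
compute_cci <- function(claims, cohort, codes = load_code_dictionary()) {
  ch <- codes$charlson
  score <- vapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$beneficiary_id[i]
    idx <- cohort$index_date[i]
    cc <- claims[claims$beneficiary_id == id &
                   claims$service_date >= idx - 365 &
                   claims$service_date < idx, , drop = FALSE]
    dx <- unique(unlist(strsplit(cc$diagnosis_codes, ";", fixed = TRUE)))
    conds <- unique(ch$condition[ch$code %in% dx])
    sum(vapply(conds, function(cd) max(ch$weight[ch$condition == cd]), 0))
  }, 0)
  cohort$cci_score <- as.integer(score)
  cohort$cci_band <- c("low", "mid", "high")[findInterval(score, c(0, 3, 5))]
  cohort
}

#' Identify device-procedure-related infections
#'
#' An infection event is a claim record carrying a qualifying diagnosis
#' (device infection 996.61 or an infection-related diagnosis: fever,
#' bacteremia, endocarditis, cellulitis, sepsis) together with a generator
#' removal, system/lead revision or pocket revision procedure on the same
#' record. Events are attributed to the most recent prior device procedure
#' (implant, generator change or revision) and only when they fall within
#' the first year (four quarters) after it.
#'
#' @param claims Claims data frame.
#' @param cohort Result of [identify_cohort()].
#' @param codes Code dictionary.
#' @return Data frame of attributed infections: `beneficiary_id`, `date`,
#'   `attributed_to` (`primary_implant`/`generator_change`/`revision`) and
#'   `quarters_since_procedure`.
#' @export
identify_infections <- function(claims, cohort, codes = load_code_dictionary()) {
  rec <- claim_records(claims)
  rec <- rec[rec$beneficiary_id %in% cohort$beneficiary_id, ]
  inf_dx <- c(codes$diagnoses$device_infection, codes$diagnoses$infection_related)
  rev_proc <- unlist(codes$procedures[c("generator_removal", "lead_revision",
                                        "pocket_revision")])
  rec$is_infection <- has_code(rec$diagnosis_codes, inf_dx) &
    has_code(rec$procedure_codes, rev_proc)
  rec$is_gen_change <- has_code(rec$procedure_codes, codes$procedures$generator_change)
  rec$is_implant <- has_code(rec$procedure_codes, codes$procedures$primary_implant)
  rec$is_revision <- has_code(rec$procedure_codes, rev_proc)

  out <- lapply(split(rec, rec$beneficiary_id), function(r) {
    id <- r$beneficiary_id[1]
    idx <- cohort$index_date[cohort$beneficiary_id == id]
    r <- r[r$service_date >= idx, , drop = FALSE]
    infs <- which(r$is_infection)
    if (!length(infs)) return(NULL)
    rows <- lapply(infs, function(k) {
      prior <- which((r$is_implant | r$is_gen_change | r$is_revision) &
                       r$service_date < r$service_date[k])
      # the infection claim itself carries a revision procedure; attribute to
      # the latest *other* device procedure before it
      if (!length(prior)) return(NULL)
      p <- prior[length(prior)]
      gap_q <- as.numeric(r$service_date[k] - r$service_date[p]) / 91.3125
      if (gap_q > 4) return(NULL)   # first-year attribution only
      data.frame(beneficiary_id = id, date = r$service_date[k],
                 attributed_to = if (r$is_implant[p]) "primary_implant"
                 else if (r$is_gen_change[p]) "generator_change" else "revision",
                 quarters_since_procedure = gap_q,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(beneficiary_id = character(0), date = as.Date(character(0)),
                      attributed_to = character(0),
                      quarters_since_procedure = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Aggregate claims into inflation-adjusted quarterly costs
#'
#' Inflates every paid amount from its service-month price level to the
#' target month using the supplied monthly price index, anchors calendar
#' quarters at each beneficiary's index date (quarter 0 starts at the index
#' date), and aggregates costs by (beneficiary, quarter, component).
#' Zero-cost patient-quarters are excluded from the distribution summaries.
#' Maintenance costs are restricted to claims carrying the monitoring
#' procedure codes.
#'
#' @param claims Claims data frame.
#' @param cohort Result of [identify_cohort()].
#' @param price_index Monthly series from [price_index_series()].
#' @param target_month Price level to state costs in (default `"2016-01"`).
#' @param codes Code dictionary.
#' @return A list: `quarterly` (beneficiary x quarter x component costs),
#'   `index_quarter_median` (median quarter-0 cost by component),
#'   `maintenance_median` (median monitoring-claim cost) and
#'   `infection_claim_median`.
#' @export
derive_quarterly_costs <- function(claims, cohort,
                                   price_index = price_index_series(),
                                   target_month = "2016-01",
                                   codes = load_code_dictionary()) {
  cl <- claims[claims$beneficiary_id %in% cohort$beneficiary_id, , drop = FALSE]
  m <- match(cl$price_month, price_index$month)
  if (anyNA(m)) {
    stop("price index is missing month(s): ",
         paste(unique(cl$price_month[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  t_idx <- price_index$index[price_index$month == target_month]
  if (!length(t_idx)) stop("price index is missing month(s): ", target_month, call. = FALSE)
  cl$cost_2016 <- cl$paid_amount * t_idx / price_index$index[m]
  idx <- cohort$index_date[match(cl$beneficiary_id, cohort$beneficiary_id)]
  cl$quarter <- as.integer(floor(as.numeric(cl$service_date - idx) / 91.3125))
  cl <- cl[cl$quarter >= 0, , drop = FALSE]

  quarterly <- stats::aggregate(cost_2016 ~ beneficiary_id + quarter + component,
                                data = cl, FUN = sum)
  quarterly <- quarterly[quarterly$cost_2016 > 0, , drop = FALSE]

  q0 <- quarterly[quarterly$quarter == 0, , drop = FALSE]
  index_quarter_median <- vapply(split(q0$cost_2016, q0$component), stats::median, 0)

  maint <- cl[has_code(cl$procedure_codes, codes$procedures$maintenance), , drop = FALSE]
  inf_dx <- c(codes$diagnoses$device_infection, codes$diagnoses$infection_related)
  rev_proc <- unlist(codes$procedures[c("generator_removal", "lead_revision",
                                        "pocket_revision")])
  infc <- cl[has_code(cl$diagnosis_codes, inf_dx) &
               has_code(cl$procedure_codes, rev_proc), , drop = FALSE]
  list(quarterly = quarterly,
       index_quarter_median = index_quarter_median,
       maintenance_median = stats::median(maint$cost_2016),
       infection_claim_median = stats::median(infc$cost_2016))
}

#' Derive model event rates from claims
#'
#' Computes the proportion of cohort members with an attributed infection in
#' the first year after primary implant, the per-beneficiary generator-change
#' count, and the observed median quarters from implant to first generator
#' change.
#'
#' @inheritParams identify_infections
#' @return A list: `infection_first_year_rate`, `mean_generator_changes`,
#'   `median_quarters_to_generator_change` and the `n` of the cohort.
#' @export
derive_event_rates <- function(claims, cohort, codes = load_code_dictionary()) {
  infs <- identify_infections(claims, cohort, codes)
  primary_inf <- infs[infs$attributed_to == "primary_implant", , drop = FALSE]
  rec <- claim_records(claims)
  rec <- rec[rec$beneficiary_id %in% cohort$beneficiary_id, ]
  rec$is_gen <- has_code(rec$procedure_codes, codes$procedures$generator_change)
  idx <- cohort$index_date[match(rec$beneficiary_id, cohort$beneficiary_id)]
  gen <- rec[rec$is_gen & rec$service_date >= idx, , drop = FALSE]
  first_gen <- tapply(as.numeric(gen$service_date), gen$beneficiary_id, min)
  idx_first <- cohort$index_date[match(names(first_gen), cohort$beneficiary_id)]
  q_first <- (first_gen - as.numeric(idx_first)) / 91.3125
  list(
    n = nrow(cohort),
    infection_first_year_rate = length(unique(primary_inf$beneficiary_id)) / nrow(cohort),
    mean_generator_changes = nrow(gen) / nrow(cohort),
    median_quarters_to_generator_change =
      if (length(q_first)) stats::median(q_first) else NA_real_
  )
}

#' Derive a model parameter configuration from claims
#'
#' Assembles a parameter set for the engine by starting from the reference
#' configuration for the requested device and overriding the quantities the
#' claims support: the first-year infection rate after primary implant
#' (applied uniformly across Charlson bands) and the maintenance- and
#' infection-cost centrals.
#'
#' @inheritParams derive_quarterly_costs
#' @param device Device population for the emitted configuration.
#' @param battery Battery-longevity class for the emitted configuration.
#' @return A validated `cied_parameters` object carrying a
#'   `derivation` attribute with the raw derived quantities.
#' @export
derive_parameters <- function(claims, cohort, device = "ICD", battery = "legacy",
                              price_index = price_index_series(),
                              codes = load_code_dictionary()) {
  rates <- derive_event_rates(claims, cohort, codes)
  costs <- derive_quarterly_costs(claims, cohort, price_index, codes = codes)
  p <- reference_parameters(device, battery)
  p$events$infection_annual[, "primary_implant"] <-
    rep(rates$infection_first_year_rate, 3)
  fu <- costs$maintenance_median
  if (is.finite(fu)) {
    rng <- .ref_cost_ranges$follow_up$any$combined
    p$costs$follow_up$any$combined <- lapply(
      stats::setNames(nm = .cci_levels),
      function(b) fit_lognormal_from_range(fu, min(fu, rng[1]), max(fu, rng[2])))
  }
  validate_parameters(p)
  attr(p, "derivation") <- c(rates, costs[c("index_quarter_median",
                                            "maintenance_median",
                                            "infection_claim_median")])
  p
}
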