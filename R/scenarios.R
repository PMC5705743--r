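#' Shift the Charlson case mix toward sicker or healthier
#'
#' The sicker shift moves `amount` of probability mass from the lowest
#' occupied band one band up; the healthier shift moves it from the middle
#' band down to the lowest. The mass moved is capped at what the source band
#' holds, so the result remains a distribution.
#'
#' @param mix Named probabilities for bands `low`, `mid`, `high`.
#' @param direction `"sicker"` or `"healthier"`.
#' @param amount Probability mass to move (default 0.15).
#' @return The shifted case mix.
#' @export
shift_case_mix <- function(mix, direction = c("sicker", "healthier"),
                           amount = 0.15) {
  direction <- match.arg(direction)
  mix <- mix[c("low", "mid", "high")]
  if (direction == "sicker") {
    from <- which(mix > 0)[1]
    to <- min(from + 1L, 3L)
  } else {
    from <- 2L
    to <- 1L
  }
  moved <- min(amount, mix[[from]])
  mix[[from]] <- mix[[from]] - moved
  mix[[to]] <- mix[[to]] + moved
  mix
}

new_scenario_bundle <- function(name, device, battery, overrides = list()) {
  structure(list(name = name, device = device, battery = battery,
                 overrides = overrides),
            class = "cied_scenario")
}

#' @export
print.cied_scenario <- function(x, ...) {
  ov <- if (length(x$overrides))
    paste(names(x$overrides), collapse = ", ") else "none"
  cat(sprintf("<cied_scenario> %s (%s, %s battery; overrides: %s)\n",
              x$name, x$device, x$battery, ov))
  invisible(x)
}

#' The four reference scenarios
#'
#' `{ICD, CRT-D} x {legacy, extended}` at a 3% annual discount rate. The two
#' battery classes of a device share the same master seed so they can be
#' compared with common random numbers.
#'
#' @param n_patients Cohort size per scenario (reference 20000).
#' @param seed Master seed shared by the paired runs.
#' @return A list of 4 `cied_scenario` bundles.
#' @export
reference_suite <- function(n_patients = 20000L, seed = 1L) {
  bundles <- list()
  for (device in c("ICD", "CRT-D")) {
    for (battery in c("legacy", "extended")) {
      bundles[[paste(gsub("-", "", device), battery, sep = "_")]] <-
        new_scenario_bundle(
          name = paste(device, battery, sep = ", "),
          device = device, battery = battery,
          overrides = list(n_patients = n_patients, seed = seed,
                           discount_rate_annual = 0.03))
    }
  }
  bundles
}

#' Sensitivity scenarios around a base bundle
#'
#' Returns bundles for: a sicker case mix, a healthier case mix, a shift of
#' 20 percentage points of primary-implant and revision procedures to the
#' outpatient setting, and discount rates of 0% and 6%.
#'
#' @param base A `cied_scenario` (typically from [reference_suite()]).
#' @param cci_shift_amount Case-mix mass moved by the CCI shifts.
#' @param outpatient_shift_pp Percentage points moved to outpatient.
#' @return A named list of `cied_scenario` bundles.
#' @export
sensitivity_suite <- function(base, cci_shift_amount = 0.15,
                              outpatient_shift_pp = 20) {
  stopifnot(inherits(base, "cied_scenario"))
  mk <- function(suffix, extra) {
    new_scenario_bundle(paste(base$name, suffix, sep = ", "),
                        base$device, base$battery,
                        utils::modifyList(base$overrides, extra))
  }
  list(
    sicker = mk("sicker case mix",
                list(case_mix_shift = list(direction = "sicker",
                                           amount = cci_shift_amount))),
    healthier = mk("healthier case mix",
                   list(case_mix_shift = list(direction = "healthier",
                                              amount = cci_shift_amount))),
    outpatient = mk(sprintf("+%d pp outpatient", outpatient_shift_pp),
                    list(outpatient_shift_pp = outpatient_shift_pp)),
    discount0 = mk("0% discount", list(discount_rate_annual = 0)),
    discount6 = mk("6% discount", list(discount_rate_annual = 0.06))
  )
}

#' Materialise the parameter set of a scenario bundle
#'
#' @param bundle A `cied_scenario`.
#' @return A validated `cied_parameters` object with overrides applied.
#' @export
scenario_parameters <- function(bundle) {
  stopifnot(inherits(bundle, "cied_scenario"))
  ov <- bundle$overrides
  p <- reference_parameters(
    device = bundle$device, battery = bundle$battery,
    discount_rate_annual = ov$discount_rate_annual %||% 0.03,
    n_patients = ov$n_patients %||% 20000L,
    seed = ov$seed %||% 1L)
  if (!is.null(ov$case_mix_shift)) {
    p$population$case_mix <- shift_case_mix(p$population$case_mix,
                                            ov$case_mix_shift$direction,
                                            ov$case_mix_shift$amount %||% 0.15)
  }
  if (!is.null(ov$outpatient_shift_pp)) {
    shift <- ov$outpatient_shift_pp / 100
    for (proc in c("primary_implant", "revision")) {
      share <- p$population$inpatient_share[[proc]] - shift
      if (any(share < 0)) {
        warning("outpatient share clamped to 1 for ", proc, call. = FALSE)
        share <- pmax(share, 0)
      }
      p$population$inpatient_share[[proc]] <- share
    }
  }
  validate_parameters(p)
  p
}

#' Run one scenario bundle
#'
#' @param bundle A `cied_scenario`.
#' @param n Optional override of the cohort size.
#' @return A list with the bundle, the materialised parameters, the
#'   simulated `cied_cohort` and its `cied_summary`.
#' @export
run_scenario <- function(bundle, n = NULL) {
  params <- scenario_parameters(bundle)
  cohort <- run_cohort(params, n = n)
  list(bundle = bundle, params = params, cohort = cohort,
       summary = summarize_cohort(cohort))
}

#' Run a suite of scenario bundles with paired comparisons
#'
#' Runs every bundle and, for each device with both battery classes present,
#' a legacy-versus-extended comparison under common random numbers.
#'
#' @param bundles A named list of `cied_scenario` bundles.
#' @param n Optional override of the cohort size for every bundle.
#' @return A list with `runs` (per-bundle results) and `comparisons`
#'   (per-device `cied_comparison` objects).
#' @export
run_suite <- function(bundles, n = NULL) {
  runs <- lapply(bundles, run_scenario, n = n)
  comparisons <- list()
  devices <- unique(vapply(bundles, `[[`, "", "device"))
  for (device in devices) {
    idx <- vapply(bundles, function(b) b$device == device, TRUE)
    classes <- vapply(bundles[idx], `[[`, "", "battery")
    if (all(c("legacy", "extended") %in% classes)) {
      leg <- runs[idx][[which(classes == "legacy")[1]]]$summary
      ext <- runs[idx][[which(classes == "extended")[1]]]$summary
      comparisons[[device]] <- compare_scenarios(leg, ext)
    }
  }
  list(runs = runs, comparisons = comparisons)
}
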