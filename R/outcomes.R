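#' Summarise a simulated cohort
#'
#' Aggregates per-patient trajectories into the reporting quantities: the
#' percentage of patients free of each event type over the horizon (patients
#' dying before the horizon remain in the denominator), means and SDs of
#' discounted total cost and life years, and mean per-patient event counts.
#'
#' @param cohort A `cied_cohort` from [run_cohort()], or its `patients`
#'   data frame.
#' @return A `cied_summary` object.
#' @export
summarize_cohort <- function(cohort) {
  pts <- if (inherits(cohort, "cied_cohort")) cohort$patients else cohort
  if (is.null(pts) || nrow(pts) == 0) {
    stop("contract violation: summarize_cohort() needs a non-empty cohort", call. = FALSE)
  }
  pct_no <- function(x) 100 * mean(x == 0)
  structure(
    list(
      n = nrow(pts),
      pct_no_infection = pct_no(pts$infection),
      pct_no_complication = pct_no(pts$complication),
      pct_no_battery_change = pct_no(pts$battery_change),
      pct_no_revision = pct_no(pts$revision),
      pct_no_repeat = 100 * mean(pts$battery_change == 0 & pts$revision == 0),
      cost_mean = mean(pts$cost_disc), cost_sd = stats::sd(pts$cost_disc),
      cost_undisc_mean = mean(pts$cost_undisc),
      ly_mean = mean(pts$ly_disc), ly_sd = stats::sd(pts$ly_disc),
      ly_undisc_mean = mean(pts$ly),
      mean_counts = c(battery_change = mean(pts$battery_change),
                      revision = mean(pts$revision),
                      infection = mean(pts$infection),
                      complication = mean(pts$complication)),
      device = if (inherits(cohort, "cied_cohort")) cohort$params$device else NA_character_,
      battery = if (inherits(cohort, "cied_cohort"))
        cohort$params$battery$longevity_class else NA_character_
    ),
    class = "cied_summary"
  )
}

#' @export
print.cied_summary <- function(x, ...) {
  cat(sprintf("<cied_summary>%s n = %s\n",
              if (is.na(x$device)) "" else sprintf(" %s, %s battery;", x$device, x$battery),
              format(x$n, big.mark = ",")))
  cat(sprintf("  no infections %.1f%% | no complications %.1f%% | no battery changes %.1f%% | no revisions %.1f%% | neither %.1f%%\n",
              x$pct_no_infection, x$pct_no_complication, x$pct_no_battery_change,
              x$pct_no_revision, x$pct_no_repeat))
  cat(sprintf("  total cost $%s (SD $%s); life years %.2f (SD %.2f), discounted\n",
              format(round(x$cost_mean), big.mark = ","),
              format(round(x$cost_sd), big.mark = ","),
              x$ly_mean, x$ly_sd))
  invisible(x)
}

#' Compare a legacy-battery run against an extended-battery run
#'
#' Relative reductions are `100 * (legacy - extended) / legacy`, computed on
#' per-patient mean event counts and on mean discounted total cost; the
#' absolute cost difference is `legacy - extended`. A life-year difference
#' smaller than one model cycle (0.25 years) is flagged as equivalent.
#'
#' @param legacy,extended `cied_summary` objects from paired runs (same
#'   device, same master seed).
#' @return A `cied_comparison` object.
#' @export
compare_scenarios <- function(legacy, extended) {
  stopifnot(inherits(legacy, "cied_summary"), inherits(extended, "cied_summary"))
  red <- function(l, e) if (l == 0) NA_real_ else 100 * (l - e) / l
  reductions <- c(
    battery_change = red(legacy$mean_counts[["battery_change"]],
                         extended$mean_counts[["battery_change"]]),
    revision = red(legacy$mean_counts[["revision"]],
                   extended$mean_counts[["revision"]]),
    infection = red(legacy$mean_counts[["infection"]],
                    extended$mean_counts[["infection"]]),
    complication = red(legacy$mean_counts[["complication"]],
                       extended$mean_counts[["complication"]]),
    total_cost = red(legacy$cost_mean, extended$cost_mean)
  )
  structure(
    list(device = legacy$device,
         reductions_pct = reductions,
         cost_difference = legacy$cost_mean - extended$cost_mean,
         ly_difference = extended$ly_mean - legacy$ly_mean,
         ly_equivalent = abs(extended$ly_mean - legacy$ly_mean) < 0.25),
    class = "cied_comparison"
  )
}

#' @export
print.cied_comparison <- function(x, ...) {
  cat(sprintf("<cied_comparison>%s legacy vs extended battery\n",
              if (is.na(x$device)) "" else paste0(" ", x$device, ",")))
  r <- x$reductions_pct
  cat(sprintf("  reductions: revisions %.0f%%, battery changes %.0f%%, infections %.0f%%, complications %.0f%%, total cost %.0f%%\n",
              r[["revision"]], r[["battery_change"]], r[["infection"]],
              r[["complication"]], r[["total_cost"]]))
  cat(sprintf("  cost difference $%s per patient; life-year difference %+.3f%s\n",
              format(round(x$cost_difference), big.mark = ","), x$ly_difference,
              if (x$ly_equivalent) " (equivalent: < one cycle)" else ""))
  invisible(x)
}

#' Mean discounted cost by number of repeat procedures
#'
#' Repeat procedures are battery changes plus revisions after the primary
#' implant. In reference runs mean cost should be non-decreasing in the
#' repeat count: patients with additional procedures incur greater costs.
#'
#' @param cohort A `cied_cohort` or its `patients` data frame.
#' @return A data frame with columns `repeat_procedures`, `n_patients`,
#'   `mean_cost_disc`, ordered by count.
#' @export
cost_by_repeat_count <- function(cohort) {
  pts <- if (inherits(cohort, "cied_cohort")) cohort$patients else cohort
  if (is.null(pts) || nrow(pts) == 0) {
    stop("contract violation: cost_by_repeat_count() needs a non-empty cohort",
         call. = FALSE)
  }
  k <- pts$battery_change + pts$revision
  agg <- stats::aggregate(pts$cost_disc, by = list(repeat_procedures = k),
                          FUN = mean)
  cnt <- as.data.frame(table(repeat_procedures = k), stringsAsFactors = FALSE)
  out <- data.frame(repeat_procedures = agg$repeat_procedures,
                    n_patients = as.integer(cnt$Freq),
                    mean_cost_disc = agg$x)
  out[order(out$repeat_procedures), , drop = FALSE]
}
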