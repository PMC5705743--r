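#' Create the state of a patient entering the model
#'
#' All patients enter at the primary-implantation state in cycle 0.
#'
#' @param age Entry age (years).
#' @param cci Charlson band index (1 = CCI 0-2, 2 = 3-4, 3 = 5+) or label.
#' @return A `cied_patient_state` list with the Markov phase
#'   (`"A"` implant, `"B"` maintenance, `"C"` battery replacement,
#'   `"D"` revision, `"E"` dead) and the clocks: `cycle` (0-based),
#'   `qsg` (quarters since generator placement), `w` (quarters since last
#'   procedure), `gen_index` (generators placed so far) and `depl_at` (the
#'   current generator's depletion quarter, drawn at placement).
#' @export
new_patient_state <- function(age, cci) {
  if (is.character(cci)) cci <- match(cci, c("low", "mid", "high"))
  structure(
    list(alive = TRUE, phase = "A", pending_replace = FALSE,
         age = age, cci = as.integer(cci), cycle = 0L,
         qsg = 0L, w = 0L, last_proc = NA_integer_,
         depl_at = NA_integer_, gen_index = 0L),
    class = "cied_patient_state"
  )
}

# quarter of depletion for quantile u under the compiled battery CDF
battery_quantile_cdf <- function(cdf, u) {
  findInterval(u, cdf, left.open = TRUE)
}

#' Advance a living patient by one model cycle
#'
#' Applies the fixed within-cycle event order: (1) the scheduled procedure of
#' the occupied state (primary implant, generator change or revision, with
#' its cost and clock resets), (2) operative death, (3) all-cause death,
#' (4) battery-depletion check, (5) revision-for-other-reasons check,
#' (6) infection check, (7) non-infectious complication check, (8) follow-up
#' maintenance cost in procedure-free cycles. Infection, complication and
#' revision-for-other-reasons hazards apply during the first year (4 cycles,
#' clock `w < 4`) after the most recent procedure, at the rate keyed to that
#' procedure type. A detected infection sends the patient to the revision
#' state in the next cycle when `infection_triggers_revision` is set. A
#' revision trigger coinciding with battery depletion resolves to a single
#' revision in which the generator is replaced (both clocks reset).
#'
#' @param state A living `cied_patient_state`.
#' @param params A `cied_parameters` object (or the internal compiled form).
#' @param draws Numeric vector of uniforms driving the cycle:
#'   positions 1-6 are (operative death, all-cause death, revision-other,
#'   infection, complication, setting), and positions 7 onward are the
#'   per-generator depletion quantiles, indexed by generator number so that
#'   paired scenarios share depletion quantile draws (common random
#'   numbers). Cost draws use the current R random stream.
#' @return A list with `state` (the successor state), `events` (a list of
#'   cycle events, each with `kind`, `setting`, `cost_inst`, `cost_prof`)
#'   and `survived` (did the patient survive the cycle).
#' @export
step_patient <- function(state, params, draws) {
  if (!isTRUE(state$alive)) {
    stop("contract violation: step_patient() called on a dead patient", call. = FALSE)
  }
  cp <- if (inherits(params, "cied_parameters")) compile_parameters(params) else params
  events <- vector("list", 4L)
  n_ev <- 0L
  cci <- state$cci

  proc <- switch(state$phase, A = 1L, C = 2L, D = 3L, B = NULL,
                 stop("invalid phase: ", state$phase))

  if (!is.null(proc)) {
    if (proc == 1L) {
      inp <- draws[6] < cp$p_inpat_primary[[cci]]
      cc <- if (inp) cp$costs$primary_in else cp$costs$primary_out
      ci <- cost_draw(cc$inst[[cci]]); pr <- cost_draw(cc$prof[[cci]])
      kind <- "primary_implant"
    } else if (proc == 2L) {
      inp <- FALSE
      ci <- cost_draw(cp$costs$battery[[cci]]); pr <- 0
      kind <- "battery_change"
    } else {
      inp <- draws[6] < cp$p_inpat_revision[[cci]]
      cc <- if (inp) cp$costs$revision_in else cp$costs$revision_out
      ci <- cost_draw(cc$inst[[cci]]); pr <- cost_draw(cc$prof[[cci]])
      kind <- "revision"
    }
    n_ev <- n_ev + 1L
    events[[n_ev]] <- list(kind = kind,
                           setting = if (inp) "inpatient" else "outpatient",
                           cost_inst = ci, cost_prof = pr)
    state$w <- 0L
    state$last_proc <- proc
    if (proc == 2L ||
        (proc == 3L && (state$pending_replace || cp$revision_resets_battery))) {
      state$gen_index <- state$gen_index + 1L
      state$qsg <- 0L
      state$depl_at <- battery_quantile_cdf(cp$battery_cdf,
                                            draws[6L + state$gen_index])
    } else if (proc == 1L) {
      state$gen_index <- 1L
      state$qsg <- 0L
      state$depl_at <- battery_quantile_cdf(cp$battery_cdf, draws[7L])
    }
    state$pending_replace <- FALSE
    opk <- c("primary_implant", "generator_change", "revision")[proc]
    if (draws[1] < cp$op_mort[[opk]]) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- list(kind = "operative_death", setting = NA_character_,
                             cost_inst = 0, cost_prof = 0)
      state$alive <- FALSE
      state$phase <- "E"
      state$cycle <- state$cycle + 1L
      return(list(state = state, events = events[seq_len(n_ev)], survived = FALSE))
    }
  }

  age_row <- min(max(1L, as.integer(floor(state$age)) - (cp$q_death_age0 - 1L)),
                 nrow(cp$q_death))
  if (draws[2] < cp$q_death[age_row, cci]) {
    n_ev <- n_ev + 1L
    events[[n_ev]] <- list(kind = "other_death", setting = NA_character_,
                           cost_inst = 0, cost_prof = 0)
    state$alive <- FALSE
    state$phase <- "E"
    state$cycle <- state$cycle + 1L
    return(list(state = state, events = events[seq_len(n_ev)], survived = FALSE))
  }

  trigger_rev <- FALSE
  if (state$w < 4L) {
    lp <- state$last_proc
    if (draws[3] < cp$q_rev[[cci]]) trigger_rev <- TRUE
    if (draws[4] < cp$q_inf[cci, lp]) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- list(kind = "infection", setting = NA_character_,
                             cost_inst = cost_draw(cp$costs$infection[[cci]]),
                             cost_prof = 0)
      if (cp$infection_triggers_revision) trigger_rev <- TRUE
    }
    if (draws[5] < cp$q_comp[cci, lp]) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- list(kind = "complication", setting = NA_character_,
                             cost_inst = cost_draw(cp$costs$complication[[cci]]),
                             cost_prof = 0)
    }
  }

  if (is.null(proc)) {
    n_ev <- n_ev + 1L
    events[[n_ev]] <- list(kind = "maintenance", setting = NA_character_,
                           cost_inst = cost_draw(cp$costs$follow_up[[cci]]),
                           cost_prof = 0)
  }

  battery_signal <- !is.na(state$depl_at) && (state$qsg + 1L) >= state$depl_at
  if (trigger_rev) {
    state$phase <- "D"
    state$pending_replace <- battery_signal
  } else if (battery_signal) {
    state$phase <- "C"
  } else {
    state$phase <- "B"
  }
  state$qsg <- state$qsg + 1L
  state$w <- state$w + 1L
  state$age <- state$age + 0.25
  state$cycle <- state$cycle + 1L
  list(state = state, events = events[seq_len(n_ev)], survived = TRUE)
}

#' Simulate one patient trajectory
#'
#' Runs a patient from primary implantation (cycle 0) until death or the
#' model horizon, accruing per-cycle events, discounted and undiscounted
#' costs and life years. Life years accrue as 0.25 years per survived cycle;
#' the death cycle contributes none. Two independent random streams are
#' used: an event stream consuming a fixed number of uniforms per cycle
#' (so paired scenarios stay aligned) and a cost stream for sampling cost
#' distributions.
#'
#' @param params A `cied_parameters` object.
#' @param event_seed,cost_seed Integer seeds of the two patient streams.
#' @param keep_events Keep the per-cycle event ledger (a data frame)?
#' @param compiled Internal: pre-compiled parameter tables.
#' @return A `cied_trajectory` list: event counts, costs, life years,
#'   death cycle and kind, entry covariates, and (optionally) `events`.
#' @export
simulate_patient <- function(params, event_seed = 1L, cost_seed = event_seed + 1L,
                             keep_events = FALSE, compiled = NULL) {
  cp <- compiled %||% compile_parameters(params)
  horizon <- cp$horizon

  set.seed(event_seed)
  u_entry <- stats::runif(2L)
  u_depl <- stats::runif(40L)
  U <- matrix(stats::runif(6L * horizon), nrow = 6L)
  set.seed(cost_seed)

  age <- entry_age_quantile(cp$age_grid, u_entry[1])
  cci <- findInterval(u_entry[2], cp$case_mix_cdf, left.open = TRUE) + 1L
  cci <- min(cci, 3L)
  state <- new_patient_state(age, cci)

  counts <- c(primary_implant = 0, battery_change = 0, revision = 0,
              infection = 0, complication = 0)
  cost_undisc <- 0; cost_disc <- 0; ly <- 0; ly_disc <- 0
  death_cycle <- NA_integer_; death_kind <- NA_character_
  ledger <- if (keep_events) vector("list", horizon) else NULL

  for (cycle in seq_len(horizon) - 1L) {
    res <- step_patient(state, cp, c(U[, cycle + 1L], u_depl))
    state <- res$state
    dfc <- cp$df[cycle + 1L]
    for (ev in res$events) {
      k <- ev$kind
      if (k %in% names(counts)) counts[[k]] <- counts[[k]] + 1
      if (k == "operative_death" || k == "other_death") {
        death_cycle <- cycle
        death_kind <- k
      }
      cc <- ev$cost_inst + ev$cost_prof
      cost_undisc <- cost_undisc + cc
      cost_disc <- cost_disc + cc * dfc
    }
    if (keep_events && length(res$events)) {
      ledger[[cycle + 1L]] <- data.frame(
        cycle = cycle,
        kind = vapply(res$events, `[[`, "", "kind"),
        setting = vapply(res$events, `[[`, "", "setting"),
        cost_inst = vapply(res$events, `[[`, 0, "cost_inst"),
        cost_prof = vapply(res$events, `[[`, 0, "cost_prof"))
    }
    if (res$survived) {
      ly <- ly + 0.25
      ly_disc <- ly_disc + 0.25 * dfc
    } else {
      break
    }
  }

  structure(
    list(counts = counts, cost_undisc = cost_undisc, cost_disc = cost_disc,
         ly = ly, ly_disc = ly_disc,
         death_cycle = death_cycle, death_kind = death_kind,
         entry_age = age, cci = cci,
         events = if (keep_events) do.call(rbind, ledger[!vapply(ledger, is.null, TRUE)])),
    class = "cied_trajectory"
  )
}

#' Simulate a cohort of patients
#'
#' Runs `params$n_patients` independent patients. Per-patient random streams
#' are derived deterministically from the master seed (`params$seed`), so a
#' rerun is bitwise identical and two scenarios sharing a master seed and
#' cohort size assign the same streams to the same patient indices (common
#' random numbers).
#'
#' @param params A `cied_parameters` object.
#' @param n Override for the number of patients (defaults to
#'   `params$n_patients`).
#' @return A `cied_cohort` object whose `patients` element is a data frame
#'   with one row per patient: event counts, discounted/undiscounted costs
#'   and life years, death cycle and entry covariates.
#' @export
run_cohort <- function(params, n = NULL) {
  validate_parameters(params)
  n <- as.integer(n %||% params$n_patients)
  cp <- compile_parameters(params)
  set.seed(params$seed)
  seeds <- matrix(sample.int(2147483646L, 2L * n, replace = TRUE), ncol = 2L)

  cols <- c("primary_implant", "battery_change", "revision", "infection",
            "complication")
  out <- matrix(0, nrow = n, ncol = 9L)
  death_cycle <- rep(NA_integer_, n)
  death_kind <- rep(NA_character_, n)
  cci <- integer(n)

  for (i in seq_len(n)) {
    tr <- simulate_patient(params, seeds[i, 1L], seeds[i, 2L], compiled = cp)
    out[i, 1:5] <- tr$counts[cols]
    out[i, 6L] <- tr$cost_disc
    out[i, 7L] <- tr$cost_undisc
    out[i, 8L] <- tr$ly_disc
    out[i, 9L] <- tr$ly
    death_cycle[i] <- tr$death_cycle
    death_kind[i] <- tr$death_kind
    cci[i] <- tr$cci
  }
  patients <- data.frame(out)
  names(patients) <- c(cols, "cost_disc", "cost_undisc", "ly_disc", "ly")
  patients$death_cycle <- death_cycle
  patients$death_kind <- death_kind
  patients$cci <- factor(c("low", "mid", "high")[cci],
                         levels = c("low", "mid", "high"))
  structure(list(patients = patients, params = params, n = n),
            class = "cied_cohort")
}

#' @export
print.cied_cohort <- function(x, ...) {
  cat(sprintf("<cied_cohort> %s, %s battery: %s patients\n", x$params$device,
              x$params$battery$longevity_class %||% "custom",
              format(x$n, big.mark = ",")))
  cat(sprintf("  mean discounted cost $%s, mean discounted life years %.2f\n",
              format(round(mean(x$patients$cost_disc)), big.mark = ","),
              mean(x$patients$ly_disc)))
  invisible(x)
}

#' @export
print.cied_trajectory <- function(x, ...) {
  cat(sprintf("<cied_trajectory> entry age %.2f, CCI band %d; death cycle %s\n",
              x$entry_age, x$cci,
              if (is.na(x$death_cycle)) "none (horizon reached)" else x$death_cycle))
  cat(sprintf("  events: %s\n",
              paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
                    collapse = ", ")))
  cat(sprintf("  discounted cost $%s, discounted life years %.2f\n",
              format(round(x$cost_disc), big.mark = ","), x$ly_disc))
  invisible(x)
}
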