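#' Construct an all-cause and operative mortality model
#'
#' Background (non-operative) mortality is a Gompertz law in attained age,
#' with proportional multipliers for the Charlson comorbidity band and for
#' the device population. The quarterly probability of death at integer
#' attained age `a` in band `c` is
#' `1 - exp(-0.25 * base_rate * device_multiplier * cci_multiplier[c] *
#' exp(slope * (a - 65)))`.
#' Operative mortality applies once in the cycle of each surgical procedure.
#'
#' @param base_rate Gompertz level: annual hazard at age 65 for the
#'   mid-CCI band before the device multiplier.
#' @param slope Gompertz slope per year of age (>= 0).
#' @param cci_multipliers Named multipliers for bands `low` (CCI 0-2),
#'   `mid` (3-4) and `high` (5+).
#' @param device_multiplier Proportional hazard multiplier for the device
#'   population (calibrated so life years match the target cohort).
#' @param operative Named operative mortality probabilities for
#'   `primary_implant`, `revision` and `generator_change`.
#' @return A `cied_mortality` object.
#' @export
mortality_model <- function(base_rate,
                            slope = 0.09,
                            cci_multipliers = c(low = 0.75, mid = 1.0, high = 1.6),
                            device_multiplier = 1.0,
                            operative = c(primary_implant = 0.017,
                                          revision = 0.034,
                                          generator_change = 0.002)) {
  stopifnot(base_rate > 0, slope >= 0, device_multiplier > 0,
            all(cci_multipliers > 0))
  need <- c("primary_implant", "revision", "generator_change")
  if (!all(need %in% names(operative))) {
    stop("operative mortality needs probabilities for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(operative < 0) || any(operative > 1)) {
    stop("operative mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(base_rate = base_rate, slope = slope,
         cci_multipliers = cci_multipliers[c("low", "mid", "high")],
         device_multiplier = device_multiplier,
         operative = operative[need]),
    class = "cied_mortality"
  )
}

#' Quarterly all-cause death probability
#'
#' @param model A `cied_mortality` object.
#' @param age Attained age in years (the integer part is used).
#' @param cci Charlson band: `"low"`, `"mid"`, `"high"` (or index 1:3).
#' @return Quarterly death probability in `[0, 1)`. Vectorised over `age`.
#' @export
mortality_quarterly_prob <- function(model, age, cci) {
  if (is.character(cci)) cci <- match(cci, c("low", "mid", "high"))
  mult <- unname(model$cci_multipliers[cci])
  haz <- model$base_rate * model$device_multiplier * mult *
    exp(model$slope * (floor(age) - 65))
  1 - exp(-0.25 * haz)
}

#' @export
print.cied_mortality <- function(x, ...) {
  cat(sprintf("<mortality> Gompertz base %.4f/yr @65, slope %.3f/yr, device x%.3f\n",
              x$base_rate, x$slope, x$device_multiplier))
  cat(sprintf("  CCI multipliers %.2f/%.2f/%.2f; operative %0.1f%%/%0.1f%%/%0.1f%% (primary/revision/battery)\n",
              x$cci_multipliers[1], x$cci_multipliers[2], x$cci_multipliers[3],
              100 * x$operative[["primary_implant"]],
              100 * x$operative[["revision"]],
              100 * x$operative[["generator_change"]]))
  invisible(x)
}

#' Discretised entry-age distribution
#'
#' Age at primary implant follows a normal distribution truncated to
#' `[lower, upper]`, discretised to a quarter-year grid. The simulation
#' engine draws entry ages from exactly this grid (inverse CDF), so the
#' expected-value oracle can integrate over the same atoms and match the
#' engine without discretisation error.
#'
#' @param mean,sd Moments of the untruncated normal (years).
#' @param lower,upper Truncation bounds (years).
#' @param step Grid step (years; default one quarter).
#' @return A list with `age` (grid midpoints) and `weight` (probabilities
#'   summing to 1).
#' @export
entry_age_grid <- function(mean = 74.6, sd = 6.1, lower = 65, upper = 100,
                           step = 0.25) {
  edges <- seq(lower, upper, by = step)
  p <- stats::pnorm(edges, mean, sd)
  w <- diff(p)
  w <- w / sum(w)
  list(age = utils::head(edges, -1), weight = w)
}

#' Inverse-CDF entry-age draw on the discrete grid
#'
#' @param grid Result of [entry_age_grid()].
#' @param u Uniform(0,1) draw(s).
#' @return Entry age(s) on the grid.
#' @export
entry_age_quantile <- function(grid, u) {
  cdf <- cumsum(grid$weight)
  grid$age[pmin(findInterval(u, cdf, left.open = TRUE) + 1L, length(grid$age))]
}
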