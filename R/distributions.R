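#' Convert an annual event probability to a per-quarter probability
#'
#' The model cycle is one calendar quarter while the claims-derived event
#' rates are first-year probabilities, so every rate has to be converted to
#' the per-cycle probability `q` satisfying `1 - (1 - q)^4 = p_annual`
#' (independent application over four quarters reproduces the annual risk).
#'
#' @param p_annual Annual probability, in `[0, 1]`. Vectorised.
#' @return Per-quarter probability of the same length.
#' @examples
#' annual_to_quarterly(0.04)           # ~0.010154
#' quarterly_to_annual(annual_to_quarterly(0.3))
#' @export
annual_to_quarterly <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / 4)
}

#' @rdname annual_to_quarterly
#' @param q_quarterly Per-quarter probability, in `[0, 1]`.
#' @export
quarterly_to_annual <- function(q_quarterly) {
  if (any(!is.finite(q_quarterly)) || any(q_quarterly < 0) || any(q_quarterly > 1)) {
    stop("quarterly probability must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - q_quarterly)^4
}

new_cost_spec <- function(family, central, low, high, pars = list()) {
  structure(
    c(list(family = family, central = central, low = low, high = high), pars),
    class = "cied_cost_spec"
  )
}

#' Fit a lognormal cost distribution from a published reference range
#'
#' Costs are sampled from lognormal distributions whose median equals the
#' configured central value. The log-scale standard deviation is chosen by
#' least squares on the log bounds so that the central `coverage` interval
#' spans `[low, high]` as nearly as possible; with the median fixed this has
#' the closed form `sdlog = log(high / low) / (2 * z)` where
#' `z = qnorm((1 + coverage) / 2)`. A degenerate range (`low == high`)
#' returns a point mass.
#'
#' @param central Median cost (2016 USD).
#' @param low,high Reference range endpoints interpreted as a central
#'   coverage interval of the sampling distribution.
#' @param coverage Fraction of mass assigned to `[low, high]` (default 0.95).
#' @return A `cied_cost_spec` object.
#' @examples
#' fit_lognormal_from_range(100, 50, 200)  # sdlog ~ log(2)/1.96 = 0.3536
#' @export
fit_lognormal_from_range <- function(central, low, high, coverage = 0.95) {
  if (!is.finite(central) || !is.finite(low) || !is.finite(high) ||
      central <= 0 || low <= 0 || high <= 0) {
    stop("cost range values must be positive and finite", call. = FALSE)
  }
  if (low > high) stop("cost range has low > high", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)", call. = FALSE)
  if (low == high) {
    return(new_cost_spec("point", central, low, high))
  }
  z <- stats::qnorm((1 + coverage) / 2)
  sdlog <- log(high / low) / (2 * z)
  new_cost_spec("lognormal", central, low, high,
                list(meanlog = log(central), sdlog = sdlog, coverage = coverage))
}

#' Fit a rescaled beta cost distribution on a published range
#'
#' The beta family rows are represented as a beta distribution rescaled to
#' `[low, high]` with mean equal to `central`, keeping the support on the
#' printed range. `concentration` is the beta sum-of-shapes parameter
#' (larger means tighter around the mean). A central value on a range
#' endpoint, or a degenerate range, collapses to a point mass.
#'
#' @inheritParams fit_lognormal_from_range
#' @param concentration Beta concentration `alpha + beta` (default 4).
#' @return A `cied_cost_spec` object.
#' @export
fit_beta_from_range <- function(central, low, high, concentration = 4) {
  if (!is.finite(central) || !is.finite(low) || !is.finite(high) ||
      central < 0 || low < 0 || high < 0) {
    stop("cost range values must be non-negative and finite", call. = FALSE)
  }
  if (low > high || central < low || central > high) {
    stop("need low <= central <= high", call. = FALSE)
  }
  if (low == high || central == low || central == high) {
    return(new_cost_spec("point", central, low, high))
  }
  m <- (central - low) / (high - low)
  new_cost_spec("beta_scaled", central, low, high,
                list(shape1 = m * concentration,
                     shape2 = (1 - m) * concentration))
}

#' Mean of a cost distribution specification
#'
#' Lognormal means are `exp(meanlog + sdlog^2 / 2)`; note the configured
#' central value is a median, so the mean used in expected-value work is
#' slightly larger. Beta and point specifications have mean `central`.
#'
#' @param spec A `cied_cost_spec`.
#' @return Scalar mean (2016 USD).
#' @export
cost_mean <- function(spec) {
  switch(spec$family,
    point = spec$central,
    beta_scaled = spec$central,
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
    stop("unknown cost family: ", spec$family)
  )
}

#' Draw costs from a cost distribution specification
#'
#' @param spec A `cied_cost_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
cost_draw <- function(spec, n = 1L) {
  switch(spec$family,
    point = rep.int(spec$central, n),
    beta_scaled = spec$low +
      (spec$high - spec$low) * stats::rbeta(n, spec$shape1, spec$shape2),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unknown cost family: ", spec$family)
  )
}

#' @export
print.cied_cost_spec <- function(x, ...) {
  cat(sprintf("<cost %s> central $%s on [$%s, $%s]\n", x$family,
              format(x$central, big.mark = ","),
              format(x$low, big.mark = ","),
              format(x$high, big.mark = ",")))
  invisible(x)
}

#' Present-value discount factor for a model cycle
#'
#' Costs and life years accruing in cycle `cycle_index` (0-based quarters)
#' are discounted at an annual rate `annual_rate`:
#' `(1 + annual_rate)^(-cycle_index / 4)`.
#'
#' @param cycle_index Non-negative cycle index (quarters since model entry).
#' @param annual_rate Annual discount rate (e.g. 0.03). Must be `>= 0`.
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(4, 0.03)  # one year out: 1/1.03
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  if (any(annual_rate < 0)) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / 4)
}
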