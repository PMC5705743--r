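# Shared fixtures: all inputs are built in code.

# reference parameters with cheap run controls
small_params <- function(device = "ICD", battery = "legacy", n = 500L,
                         seed = 101L, ...) {
  reference_parameters(device, battery, n_patients = n, seed = seed, ...)
}

# degenerate parameter set: no events, (near) no deaths
quiet_params <- function(battery_median = 70, shape = 40, n = 50L, seed = 7L) {
  p <- reference_parameters("ICD", "legacy", n_patients = n, seed = seed)
  p$events$infection_annual[] <- 0
  p$events$complication_annual[] <- 0
  p$events$revision_other_annual[] <- 0
  p$mortality$base_rate <- 1e-12
  p$mortality$operative[] <- 0
  p$battery <- calibrate_battery_hazard(battery_median, shape, "legacy")
  p
}

# randomised but valid parameter sets for property tests
random_params <- function(seed) {
  set.seed(seed)
  device <- sample(c("ICD", "CRT-D"), 1)
  p <- reference_parameters(device,
                            sample(c("legacy", "extended"), 1),
                            discount_rate_annual = sample(c(0, 0.03, 0.06), 1),
                            n_patients = 20000L, seed = seed)
  scale_mat <- function(m) pmin(m * stats::runif(1, 0.5, 2), 0.5)
  p$events$infection_annual <- scale_mat(p$events$infection_annual)
  p$events$complication_annual <- scale_mat(p$events$complication_annual)
  p$events$revision_other_annual <- pmin(
    p$events$revision_other_annual * stats::runif(1, 0.5, 2), 0.3)
  p$mortality$base_rate <- p$mortality$base_rate * stats::runif(1, 0.7, 1.5)
  p$battery <- calibrate_battery_hazard(sample(18:48, 1), 5, "custom")
  validate_parameters(p)
  p
}

# z-scores of engine means against oracle expectations, in units of the
# engine's standard errors
oracle_engine_z <- function(params, n = params$n_patients) {
  ex <- expected_outcomes(build_expanded_chain(params), params)
  co <- run_cohort(params, n = n)
  pts <- co$patients
  z <- function(x, target) {
    se <- stats::sd(x) / sqrt(length(x))
    if (se == 0) return(0)
    (mean(x) - target) / se
  }
  c(battery_change = z(pts$battery_change, ex$counts[["battery_change"]]),
    revision = z(pts$revision, ex$counts[["revision"]]),
    infection = z(pts$infection, ex$counts[["infection"]]),
    complication = z(pts$complication, ex$counts[["complication"]]),
    cost = z(pts$cost_disc, ex$cost_disc),
    ly = z(pts$ly_disc, ex$ly_disc))
}
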