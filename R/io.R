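# Result serialisation, run manifests and the command-line entry point.
# Output formatting follows the reporting conventions: currency in 2016 USD,
# percentages to one decimal, life years to two decimals.

summary_to_list <- function(s) {
  list(
    device = s$device, battery = s$battery, n = s$n,
    pct_no_infections = round(s$pct_no_infection, 1),
    pct_no_complications = round(s$pct_no_complication, 1),
    pct_no_battery_changes = round(s$pct_no_battery_change, 1),
    pct_no_revisions = round(s$pct_no_revision, 1),
    pct_neither_battery_change_nor_revision = round(s$pct_no_repeat, 1),
    total_cost_mean = round(s$cost_mean, 2), total_cost_sd = round(s$cost_sd, 2),
    life_years_mean = round(s$ly_mean, 2), life_years_sd = round(s$ly_sd, 2),
    mean_counts = as.list(s$mean_counts)
  )
}

comparison_to_list <- function(cmp) {
  list(device = cmp$device,
       reductions_pct = as.list(round(cmp$reductions_pct, 1)),
       cost_difference = round(cmp$cost_difference, 2),
       life_year_difference = round(cmp$ly_difference, 2),
       life_years_equivalent = cmp$ly_equivalent)
}

#' Write a cohort summary (JSON and CSV)
#'
#' @param summary A `cied_summary`.
#' @param path Output path without extension; `.json` and `.csv` are added.
#' @return The JSON path, invisibly.
#' @export
write_summary <- function(summary, path) {
  l <- summary_to_list(summary)
  jsonlite::write_json(l, paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  flat <- l[!vapply(l, is.list, TRUE)]
  utils::write.csv(as.data.frame(flat), paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}

#' Build a run manifest
#'
#' Every result file is traceable to a manifest recording the scenario name,
#' a hash of the full serialised configuration, the master seed, the cohort
#' size and the package version. Identical configuration and seed give an
#' identical hash and identical result files.
#'
#' @param scenario_name Label of the run.
#' @param params The `cied_parameters` used.
#' @return A list suitable for JSON serialisation.
#' @export
run_manifest <- function(scenario_name, params) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_parameters(params, tf)
  list(scenario = scenario_name,
       config_hash = unname(tools::md5sum(tf)),
       seed = params$seed,
       n_patients = params$n_patients,
       package_version = as.character(utils::packageVersion("ciedsim")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_manifest <- function(manifest, dir, name) {
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

log_msg <- function(level, scenario, ...) {
  message(sprintf("[%s] %s %s: %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), scenario,
                  paste0(...)))
}

arg_value <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1L]
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (one configured run), `oracle` (deterministic
#' expected values), `suite` (reference or sensitivity bundles),
#' `generate-claims`, `derive-params` and `compare`. A thin launcher script
#' is installed under `inst/cli/ciedsim.R`.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cied_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv)) stop("usage: ciedsim <simulate|oracle|suite|generate-claims|derive-params|compare> ...",
                            call. = FALSE)
    cmd <- argv[1]
    args <- argv[-1]
    out <- arg_value(args, "--out", ".")
    switch(cmd,
      simulate = {
        params <- load_parameters(arg_value(args, "--config"))
        n <- as.integer(arg_value(args, "--n", params$n_patients))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        log_msg("INFO", "simulate", sprintf("%s, %s battery, n=%d", params$device,
                params$battery$longevity_class %||% "custom", n))
        cohort <- run_cohort(params, n = n)
        s <- summarize_cohort(cohort)
        write_summary(s, file.path(out, "summary"))
        if (!is.null(arg_value(args, "--trajectories"))) {
          utils::write.csv(cohort$patients,
                           file.path(out, arg_value(args, "--trajectories")),
                           row.names = FALSE)
        }
        write_manifest(run_manifest("simulate", params), out, "simulate")
      },
      oracle = {
        params <- load_parameters(arg_value(args, "--config"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        ex <- expected_outcomes(build_expanded_chain(params), params)
        jsonlite::write_json(
          list(counts = as.list(ex$counts),
               total_cost_mean = round(ex$cost_disc, 2),
               life_years_mean = round(ex$ly_disc, 2)),
          file.path(out, "oracle.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE)
        write_manifest(run_manifest("oracle", params), out, "oracle")
      },
      suite = {
        which <- arg_value(args, "--which", "reference")
        n <- as.integer(arg_value(args, "--n", 20000L))
        seed <- as.integer(arg_value(args, "--seed", 1L))
        bundles <- reference_suite(n_patients = n, seed = seed)
        if (which == "sensitivity") bundles <- sensitivity_suite(bundles[[1]])
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        res <- run_suite(bundles)
        for (nm in names(res$runs)) {
          write_summary(res$runs[[nm]]$summary, file.path(out, nm))
          write_manifest(run_manifest(nm, res$runs[[nm]]$params), out, nm)
          log_msg("INFO", nm, "written")
        }
        for (dev in names(res$comparisons)) {
          jsonlite::write_json(comparison_to_list(res$comparisons[[dev]]),
                               file.path(out, paste0("comparison_", gsub("-", "", dev), ".json")),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE)
        }
      },
      `generate-claims` = {
        n <- as.integer(arg_value(args, "--n", 1000L))
        seed <- as.integer(arg_value(args, "--seed", 1L))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        g <- generate_claims(claims_generation_spec(n), seed = seed)
        utils::write.csv(g$beneficiaries, file.path(out, "beneficiaries.csv"), row.names = FALSE)
        utils::write.csv(g$claims, file.path(out, "claims.csv"), row.names = FALSE)
        utils::write.csv(g$ground_truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
        log_msg("INFO", "generate-claims", sprintf("n=%d seed=%d", n, seed))
      },
      `derive-params` = {
        dir <- arg_value(args, "--claims")
        bens <- utils::read.csv(file.path(dir, "beneficiaries.csv"),
                                colClasses = c(birth_date = "Date", enrollment_start = "Date",
                                               enrollment_end = "Date", death_date = "Date"))
        claims <- utils::read.csv(file.path(dir, "claims.csv"),
                                  colClasses = c(service_date = "Date"))
        cohort <- identify_cohort(bens, claims)
        params <- derive_parameters(claims, cohort)
        write_parameters(params, out)
        log_msg("INFO", "derive-params", sprintf("cohort n=%d -> %s", nrow(cohort), out))
      },
      compare = {
        read_s <- function(f) jsonlite::read_json(f, simplifyVector = TRUE)
        l <- read_s(arg_value(args, "--legacy"))
        e <- read_s(arg_value(args, "--extended"))
        mk <- function(x) structure(list(
          device = x$device, cost_mean = x$total_cost_mean,
          ly_mean = x$life_years_mean,
          mean_counts = unlist(x$mean_counts)), class = "cied_summary")
        cmp <- compare_scenarios(mk(l), mk(e))
        jsonlite::write_json(comparison_to_list(cmp), out, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
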