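# Scenario pipeline: parameters -> staffing/beds -> contribution ->
# optimisation -> accessibility, with CSV report tables in the layout of
# the published scenario tables and a machine-readable solution file.

#' Built-in scenario configurations
#'
#' Four named scenarios of the regional analysis:
#' `"three-fixed-beds"` (all three hospitals at their historical bed
#' stocks and observed case loads), `"three-optimized-beds"` (observed
#' case loads, beds shrunk to full utilization), `"one-hospital"` (each
#' ward type concentrated in a single hospital, beds optimised) and
#' `"two-hospitals"` (exactly two hospitals open, both ward types at
#' each, allocation optimised).
#'
#' @param name Scenario name.
#' @param seed Seed recorded for the run (the study scenarios are
#'   deterministic; a synthetic-demand run uses it for generation).
#' @return A configuration list with sections `scenario`, `parameters`,
#'   `demand` and `accessibility`.
#' @export
scenario_config <- function(name = c("three-fixed-beds",
                                     "three-optimized-beds",
                                     "one-hospital", "two-hospitals"),
                            seed = 1L) {
  name <- match.arg(name)
  list(
    scenario = list(id = name, preset = name),
    parameters = NULL,
    demand = list(source = "study", seed = seed),
    accessibility = list(breaks = c(20, 30, 40))
  )
}

normalise_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$scenario)) {
    stop_invalid("invalid configuration: missing [scenario] section")
  }
  for (sec in c("demand", "accessibility")) {
    if (is.null(config[[sec]])) config[[sec]] <- list()
  }
  config
}

#' Run a planning scenario
#'
#' Executes the whole pipeline for one scenario configuration (a list as
#' from [scenario_config()], or a path to a YAML file with the same
#' sections): loads or derives parameters, resolves the demand source
#' (study fixture or synthetic region), builds and solves the planning
#' problem, and tabulates the result. When the demand source carries a
#' travel-time matrix, the accessibility band table for the open
#' hospitals is included.
#'
#' @param config Configuration list or YAML path.
#' @param params Optional `ward_params` overriding the configuration.
#' @param region Optional demand source: a `study_region` or `region`.
#' @param out_dir Optional output directory; when given, report CSVs, a
#'   key/value solution file and a run log are written via
#'   [write_report()].
#' @return An object of class `scenario_report`.
#' @examples
#' rep <- run_scenario(scenario_config("one-hospital"))
#' rep$objective
#' @export
run_scenario <- function(config, params = NULL, region = NULL,
                         out_dir = NULL) {
  config <- normalise_config(config)
  if (is.null(params)) {
    params <- if (is.null(config$parameters)) {
      default_parameters()
    } else if (is.character(config$parameters)) {
      load_parameters(config$parameters)
    } else {
      config$parameters
    }
  }
  if (is.null(region)) {
    src <- config$demand$source %||% "study"
    region <- if (identical(src, "study")) {
      study_region()
    } else if (identical(src, "synthetic")) {
      simulate_region(region_recipe(seed = config$demand$seed %||% 1L))
    } else {
      stop_invalid("invalid configuration: unknown demand source '%s'", src)
    }
  }
  demand <- config$demand$totals %||% region$demand
  demand <- stats::setNames(as.numeric(demand), names(region$demand))
  scen <- config$scenario
  preset <- scen$preset %||% "custom"
  problem <- switch(
    preset,
    "three-fixed-beds" = plan_problem(
      params, demand, n_hospitals = ncol(region$hospital_cases),
      hospital_names = region$hospitals,
      fixed_cases = region$hospital_cases, fixed_beds = region$beds),
    "three-optimized-beds" = plan_problem(
      params, demand, n_hospitals = ncol(region$hospital_cases),
      hospital_names = region$hospitals,
      fixed_cases = region$hospital_cases),
    "one-hospital" = plan_problem(
      params, demand, n_hospitals = 3,
      hospital_names = if (inherits(region, "study_region"))
        region$hospitals else NULL,
      n_open_hospitals = 1, open_wards_per_drg = 1,
      wards_follow_hospital = TRUE),
    "two-hospitals" = plan_problem(
      params, demand, n_hospitals = 3,
      hospital_names = if (inherits(region, "study_region"))
        region$hospitals else NULL,
      n_open_hospitals = 2, open_wards_per_drg = 2,
      wards_follow_hospital = TRUE),
    plan_problem(
      params, demand,
      n_hospitals = scen$n_hospitals %||% 3,
      n_open_hospitals = scen$n_open_hospitals,
      open_wards_per_drg = scen$open_wards_per_drg,
      wards_follow_hospital = isTRUE(scen$wards_follow_hospital))
  )
  plan <- plan_region(problem)
  tab <- as.data.frame(plan)
  bands <- NULL
  if (!is.null(region$minutes)) {
    open_names <- colnames(region$minutes)[
      seq_len(min(ncol(region$minutes), length(plan$hospital_open)))][
        plan$hospital_open == 1]
    if (length(open_names)) {
      bands <- travel_band_table(
        region$minutes, open_names,
        region$municipalities[, c("pop_children", "pop_women")],
        breaks = config$accessibility$breaks %||% c(20, 30, 40))
    }
  }
  report <- structure(list(
    scenario = scen$id %||% preset,
    table = tab,
    ward_totals = stats::setNames(
      vapply(rownames(plan$x), function(j) {
        sum(tab$contribution[tab$ward == j])
      }, 0), rownames(plan$x)),
    objective = plan$objective,
    plan = plan,
    bands = bands,
    meta = list(status = plan$status, gap = 0,
                configs_evaluated = plan$configs_evaluated,
                seed = config$demand$seed %||% NA_integer_)
  ), class = "scenario_report")
  if (!is.null(out_dir)) write_report(report, out_dir, params = params)
  report
}

#' Write a scenario report to disk
#'
#' Writes `report_table.csv` (ward rows plus per-ward and grand totals),
#' `solution.txt` (key/value decision variables), `bands.csv` (if an
#' accessibility table exists) and `run_log.txt`. Outputs are bit-stable:
#' re-running the same configuration reproduces identical files.
#'
#' @param report A `scenario_report`.
#' @param dir Output directory.
#' @param params Optional parameter set to record in the log.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$table
  totals <- data.frame(hospital = "Total",
                       ward = names(report$ward_totals),
                       beds = vapply(names(report$ward_totals), function(j)
                         sum(tab$beds[tab$ward == j]), 0),
                       cases = vapply(names(report$ward_totals), function(j)
                         sum(tab$cases[tab$ward == j]), 0),
                       utilization_pct = NA_real_,
                       contribution = as.numeric(report$ward_totals))
  grand <- data.frame(hospital = "Total", ward = "all", beds = sum(tab$beds),
                      cases = sum(tab$cases), utilization_pct = NA_real_,
                      contribution = report$objective)
  utils::write.csv(rbind(tab, totals, grand),
                   file.path(dir, "report_table.csv"), row.names = FALSE)
  plan <- report$plan
  kv <- c(sprintf("scenario=%s", report$scenario),
          sprintf("objective=%.2f", report$objective),
          sprintf("status=%s", plan$status),
          sprintf("x[%s,%s]=%d",
                  rownames(plan$x)[row(plan$x)],
                  colnames(plan$x)[col(plan$x)], as.integer(plan$x)),
          sprintf("beta[%s,%s]=%d",
                  rownames(plan$beta)[row(plan$beta)],
                  colnames(plan$beta)[col(plan$beta)],
                  as.integer(plan$beta)),
          sprintf("beds[%s,%s]=%d",
                  rownames(plan$beds)[row(plan$beds)],
                  colnames(plan$beds)[col(plan$beds)],
                  as.integer(plan$beds)),
          sprintf("staff[%s,%s]=%d",
                  rownames(plan$staff_units)[row(plan$staff_units)],
                  colnames(plan$staff_units)[col(plan$staff_units)],
                  as.integer(plan$staff_units)))
  writeLines(kv, file.path(dir, "solution.txt"))
  if (!is.null(report$bands)) {
    utils::write.csv(report$bands, file.path(dir, "bands.csv"),
                     row.names = FALSE)
  }
  log <- c(sprintf("scenario: %s", report$scenario),
           sprintf("status: %s (gap 0, %d configurations)",
                   plan$status, report$meta$configs_evaluated))
  if (!is.null(params)) {
    log <- c(log, "parameters:",
             utils::capture.output(print(params)))
  }
  log <- c(log, "decision variables:",
           utils::capture.output(print(round(coef(plan), 2))))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario '%s': objective %s EUR\n", x$scenario,
              formatC(round(x$objective), big.mark = ",", format = "d")))
  print(x$table, row.names = FALSE)
  if (!is.null(x$bands)) {
    cat("Accessibility bands:\n")
    print(x$bands, row.names = FALSE)
  }
  invisible(x)
}

#' Compare scenario reports side by side
#'
#' @param reports A list of `scenario_report` objects (at least two).
#' @return A data frame with one row per scenario: objective and, when
#'   available, the population shares per travel band; the attribute
#'   `"objective_diff"` holds the pairwise objective differences to the
#'   first scenario.
#' @export
compare_scenarios <- function(reports) {
  if (length(reports) < 2) stop_invalid("need at least two reports")
  rows <- lapply(reports, function(r) {
    row <- data.frame(scenario = r$scenario, objective = r$objective)
    if (!is.null(r$bands)) {
      for (col in grep("_share$", names(r$bands), value = TRUE)) {
        for (b in seq_len(nrow(r$bands))) {
          row[[paste(col, r$bands$band[b])]] <- r$bands[[col]][b]
        }
      }
    }
    row
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  attr(out, "objective_diff") <- out$objective - out$objective[1]
  out
}
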