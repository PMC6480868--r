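#' @title Parameter derivation for ward economics
#' @description Derivation helpers that turn primitive planning assumptions
#'   (shift coverage, salaries, case-mix indices, caesarean rates) into the
#'   working constants of the ward-planning model: DRG rebates, mixed lengths
#'   of stay, annual staff capacities and unit costs, care-time coefficients
#'   and minimum staffing levels.
#' @name parameters
NULL

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a DRG rebate from the state base case value
#'
#' Revenue per case under a DRG (diagnosis related group) lump-sum scheme is
#' the federal-state base case value multiplied by the case-mix index of the
#' case class. The value is returned unrounded; rounding to cents is a
#' display concern (unit-rounding the rebate propagates to euro-level errors
#' once multiplied by annual case volumes).
#'
#' @param base_case_value State base case value in EUR (> 0).
#' @param case_mix_index Dimensionless average cost weight (> 0).
#' @return Rebate in EUR per case (unrounded double).
#' @examples
#' derive_rebate(3117.36, 0.483) # paediatric rebate, 1505.68 printed to cents
#' @export
derive_rebate <- function(base_case_value, case_mix_index) {
  if (!is.numeric(base_case_value) || !is.numeric(case_mix_index) ||
      any(base_case_value <= 0) || any(case_mix_index <= 0)) {
    stop_invalid("base_case_value and case_mix_index must be positive numbers")
  }
  base_case_value * case_mix_index
}

#' Mixed length of stay across delivery modes
#'
#' Average obstetric length of stay as the caesarean-rate-weighted mean of
#' the vaginal and caesarean lengths of stay.
#'
#' @param caesarean_rate Fraction of births delivered by caesarean section
#'   (in \[0, 1\]).
#' @param los_caesarean,los_vaginal Lengths of stay in days (> 0).
#' @return Mixed length of stay in days.
#' @examples
#' derive_mixed_los(0.356, 7.3, 3.6) # about 4.92 days
#' @export
derive_mixed_los <- function(caesarean_rate, los_caesarean, los_vaginal) {
  if (caesarean_rate < 0 || caesarean_rate > 1) {
    stop_invalid("caesarean_rate must lie in [0, 1]")
  }
  if (los_caesarean <= 0 || los_vaginal <= 0) {
    stop_invalid("lengths of stay must be positive")
  }
  caesarean_rate * los_caesarean + (1 - caesarean_rate) * los_vaginal
}

#' Annual employer cost of one staff unit
#'
#' Gross annual salary plus the employer's share of social contributions.
#'
#' @param gross Gross annual salary in EUR (> 0).
#' @param employer_share Employer's contribution share as a fraction (>= 0).
#' @return Annual cost in EUR per staff unit.
#' @examples
#' derive_staff_unit_cost(42000, 0.35) # 56,700 for a nurse or midwife
#' derive_staff_unit_cost(75000, 0.35) # 101,250 for a physician
#' @export
derive_staff_unit_cost <- function(gross, employer_share) {
  if (any(gross <= 0)) stop_invalid("gross salary must be positive")
  if (any(employer_share < 0)) stop_invalid("employer_share must be >= 0")
  gross * (1 + employer_share)
}

#' Annual productive capacity of one staff unit
#'
#' Weekly working time times the weeks actually worked (52 minus absence
#' weeks for holiday, training and illness).
#'
#' @param weekly_hours Contracted weekly working time in hours.
#' @param absence_weeks Weeks per year of absence (0 <= absence_weeks < 52).
#' @return Capacity in hours per year.
#' @examples
#' derive_annual_capacity(40, 8) # 1760 h
#' @export
derive_annual_capacity <- function(weekly_hours, absence_weeks) {
  if (weekly_hours <= 0 || weekly_hours > 60) {
    stop_invalid("weekly_hours must lie in (0, 60]")
  }
  if (absence_weeks < 0 || absence_weeks >= 52) {
    stop_invalid("absence_weeks must lie in [0, 52)")
  }
  weekly_hours * (52 - absence_weeks)
}

#' Minimum staffing from round-the-clock coverage
#'
#' A ward that must be staffed 365 days a year, 24 hours a day, needs enough
#' contracted units to cover the weekly staffed hours. With
#' `shifts_per_day` shifts of equal length, `core_shift_staff` persons are
#' present during the two core shifts and `offpeak_staff` during the
#' remaining shifts. One contracted unit supplies
#' `weekly_hours * (52 - absence_weeks) / 52` hours in an average week; the
#' minimum is the coverage demand divided by that supply, rounded up.
#'
#' @param core_shift_staff Staff present per core shift (two core shifts/day).
#' @param offpeak_staff Staff present per off-peak shift.
#' @param shifts_per_day Number of equal shifts per day (>= 1).
#' @param weekly_hours,absence_weeks Contract primitives, see
#'   [derive_annual_capacity()].
#' @return Integer minimum number of staff units.
#' @examples
#' derive_min_staff_from_coverage(2, 1, 3, 40, 8) # 9 nurses
#' derive_min_staff_from_coverage(1, 1, 3, 40, 8) # 5 midwives
#' @export
derive_min_staff_from_coverage <- function(core_shift_staff, offpeak_staff,
                                           shifts_per_day, weekly_hours,
                                           absence_weeks) {
  if (shifts_per_day < 1) stop_invalid("shifts_per_day must be >= 1")
  if (core_shift_staff < 0 || offpeak_staff < 0) {
    stop_invalid("staff counts must be >= 0")
  }
  shift_len <- 24 / shifts_per_day
  core_shifts <- min(2, shifts_per_day)
  daily_hours <- core_shift_staff * core_shifts * shift_len +
    offpeak_staff * (shifts_per_day - core_shifts) * shift_len
  weekly_demand <- 7 * daily_hours
  weekly_supply <- weekly_hours * (52 - absence_weeks) / 52
  as.integer(ceiling(round(weekly_demand / weekly_supply, 9)))
}

#' Care-time coefficients per case
#'
#' Hours of each staff category consumed by one case, derived from daily
#' care intensities and lengths of stay. Obstetric nursing covers the mother
#' plus the newborn over the mixed length of stay; obstetric physician time
#' is the caesarean-rate-weighted mean of the per-delivery times.
#'
#' @param paed A list of paediatric primitives: `nursing_hours_per_day`,
#'   `los` (days), `physician_minutes_per_day`.
#' @param obs A list of obstetric primitives: `caesarean_rate`,
#'   `los_vaginal`, `los_caesarean`, `nursing_hours_per_day_mother`,
#'   `nursing_hours_per_day_newborn`, `delivery_duration` (midwife hours per
#'   birth), `physician_min_vaginal`, `physician_min_caesarean`.
#' @return Named numeric vector of hours per case for the five staff
#'   categories `ped_nurse`, `ped_physician`, `midwife`, `obs_nurse`,
#'   `obs_physician`.
#' @examples
#' derive_care_hours()["ped_nurse"] # 5.2 h/day x 3.1 days = 16.12 h/case
#' @export
derive_care_hours <- function(paed = paediatrics_primitives(),
                              obs = obstetrics_primitives()) {
  los_mixed <- derive_mixed_los(obs$caesarean_rate, obs$los_caesarean,
                                obs$los_vaginal)
  c(
    ped_nurse = paed$nursing_hours_per_day * paed$los,
    ped_physician = paed$physician_minutes_per_day / 60 * paed$los,
    midwife = obs$delivery_duration,
    obs_nurse = (obs$nursing_hours_per_day_mother +
                   obs$nursing_hours_per_day_newborn) * los_mixed,
    obs_physician = (1 - obs$caesarean_rate) * obs$physician_min_vaginal / 60 +
      obs$caesarean_rate * obs$physician_min_caesarean / 60
  )
}

#' Primitive planning assumptions
#'
#' Default primitives of the applied model. `paediatrics_primitives()`:
#' 5.2 nursing hours per patient-day, 3.1 days average stay, 45 physician
#' minutes per patient-day. `obstetrics_primitives()`: 35.6% caesarean rate,
#' stays of 3.6 (vaginal) and 7.3 (caesarean) days, 2.8 + 1.8 nursing hours
#' per day for mother and newborn, 14.5 midwife hours per birth, 60/300
#' physician minutes per vaginal/caesarean delivery (the extra 300 min of
#' caesarean theatre nursing is recorded but not part of the ward nursing
#' coefficient). `salary_primitives()`: collective-agreement gross salaries,
#' 35% employer share, 40-hour weeks, 8 absence weeks.
#'
#' @return A list of primitives.
#' @export
paediatrics_primitives <- function() {
  list(nursing_hours_per_day = 5.2, los = 3.1, physician_minutes_per_day = 45)
}

#' @rdname paediatrics_primitives
#' @export
obstetrics_primitives <- function() {
  list(
    caesarean_rate = 0.356,
    los_vaginal = 3.6,
    los_caesarean = 7.3,
    nursing_hours_per_day_mother = 2.8,
    nursing_hours_per_day_newborn = 1.8,
    delivery_duration = 14.5,
    physician_min_vaginal = 60,
    physician_min_caesarean = 300,
    extra_nursing_caesarean = 300
  )
}

#' @rdname paediatrics_primitives
#' @export
salary_primitives <- function() {
  list(
    gross_salary_by_role = c(nurse = 42000, senior_nurse = 50000,
                             physician = 75000, senior_physician = 120000),
    employer_share = 0.35,
    weekly_hours = 40,
    absence_weeks = 8
  )
}

ward_spec <- function(drg_id, rebate, variable_cost, los, care_hours,
                      department_fixed, bed_fixed, drg_fixed = 0,
                      min_beds = 5L) {
  if (rebate <= variable_cost) {
    stop_invalid("ward '%s': rebate must exceed variable cost", drg_id)
  }
  if (los <= 0) stop_invalid("ward '%s': length of stay must be positive", drg_id)
  if (any(care_hours < 0)) {
    stop_invalid("ward '%s': care hours must be >= 0", drg_id)
  }
  structure(list(drg_id = drg_id, rebate = rebate,
                 variable_cost = variable_cost, los = los,
                 care_hours = care_hours, department_fixed = department_fixed,
                 bed_fixed = bed_fixed, drg_fixed = drg_fixed,
                 min_beds = as.integer(min_beds)),
            class = "ward_spec")
}

#' Working parameter set of the ward-planning model
#'
#' Builds the full parameter set (two ward specifications and five staff
#' categories) from the primitive assumptions. Every constant is derived:
#' staff capacities via [derive_annual_capacity()], unit costs via
#' [derive_staff_unit_cost()], staffing minima via
#' [derive_min_staff_from_coverage()], care-time coefficients via
#' [derive_care_hours()], and the paediatric rebate via [derive_rebate()]
#' kept unrounded. The obstetric rebate is a canonical constant (default
#' 3135.11 EUR/birth): the published base-value-times-case-mix product
#' (3136.06) and the printed figure (3135.10) both differ slightly from the
#' value the reference result tables were demonstrably computed with, so the
#' reconciling value is stored directly and is configurable.
#'
#' @param base_case_value State base case value, EUR.
#' @param cmi_paediatrics Paediatric case-mix index.
#' @param obstetric_rebate Canonical obstetric rebate, EUR per birth.
#' @param variable_cost_paed,variable_cost_obs Direct cost per case, EUR.
#' @param department_fixed_paed,department_fixed_obs Annual department fixed
#'   costs, EUR (administration, cleaning, heating, senior and head-of-ward
#'   salaries; used as given).
#' @param bed_fixed_paed,bed_fixed_obs Annual fixed cost per bed, EUR.
#' @param min_beds Minimum beds for an open ward.
#' @param min_midwives Minimum midwives for an open obstetric ward. The
#'   coverage rule gives 5; the head midwife could reduce it to 4, but the
#'   applied model charges 5.
#' @param paed,obs,salaries Primitive lists, see [paediatrics_primitives()].
#' @param hospital_fixed Hospital-level fixed cost, EUR/year (default 0).
#' @return An object of class `ward_params`: a list with elements `wards`
#'   (named list of ward specifications), `staff` (data frame of staff
#'   categories with annual capacity, unit cost, care hours per case and
#'   minimum units) and `hospital_fixed`.
#' @examples
#' p <- default_parameters()
#' p$wards$paediatrics$rebate
#' @export
default_parameters <- function(base_case_value = 3117.36,
                               cmi_paediatrics = 0.483,
                               obstetric_rebate = 3135.11,
                               variable_cost_paed = 152.59,
                               variable_cost_obs = 244.64,
                               department_fixed_paed = 576500,
                               department_fixed_obs = 679000,
                               bed_fixed_paed = 15253.47,
                               bed_fixed_obs = 20212.24,
                               min_beds = 5L,
                               min_midwives = 5L,
                               paed = paediatrics_primitives(),
                               obs = obstetrics_primitives(),
                               salaries = salary_primitives(),
                               hospital_fixed = 0) {
  care <- derive_care_hours(paed, obs)
  cap <- derive_annual_capacity(salaries$weekly_hours, salaries$absence_weeks)
  cost_nurse <- derive_staff_unit_cost(salaries$gross_salary_by_role[["nurse"]],
                                       salaries$employer_share)
  cost_phys <- derive_staff_unit_cost(
    salaries$gross_salary_by_role[["physician"]], salaries$employer_share)
  min_nurses <- derive_min_staff_from_coverage(2, 1, 3, salaries$weekly_hours,
                                               salaries$absence_weeks)
  staff <- data.frame(
    id = c("ped_nurse", "ped_physician", "midwife", "obs_nurse",
           "obs_physician"),
    ward = c("paediatrics", "paediatrics", "obstetrics", "obstetrics",
             "obstetrics"),
    capacity_hours = cap,
    unit_cost = c(cost_nurse, cost_phys, cost_nurse, cost_nurse, cost_phys),
    care_hours = unname(care),
    min_units = as.integer(c(min_nurses, 5L, min_midwives, min_nurses, 5L)),
    stringsAsFactors = FALSE
  )
  wards <- list(
    paediatrics = ward_spec(
      "paediatrics",
      rebate = derive_rebate(base_case_value, cmi_paediatrics),
      variable_cost = variable_cost_paed,
      los = paed$los,
      care_hours = care[c("ped_nurse", "ped_physician")],
      department_fixed = department_fixed_paed,
      bed_fixed = bed_fixed_paed,
      min_beds = min_beds
    ),
    obstetrics = ward_spec(
      "obstetrics",
      rebate = obstetric_rebate,
      variable_cost = variable_cost_obs,
      los = derive_mixed_los(obs$caesarean_rate, obs$los_caesarean,
                             obs$los_vaginal),
      care_hours = care[c("midwife", "obs_nurse", "obs_physician")],
      department_fixed = department_fixed_obs,
      bed_fixed = bed_fixed_obs,
      min_beds = min_beds
    )
  )
  structure(list(wards = wards, staff = staff,
                 hospital_fixed = hospital_fixed,
                 primitives = list(paediatrics = paed, obstetrics = obs,
                                   salaries = salaries)),
            class = "ward_params")
}

#' Load the parameter set from a YAML configuration
#'
#' Reads a nested key/value configuration (see
#' `system.file("extdata", "parameters.yaml", package = "wardplan")` for the
#' packaged fixture), validates ranges and units, and runs the same
#' derivations as [default_parameters()]. With `verbose = TRUE` every
#' derived constant is logged with the primitives it came from.
#'
#' @param path Path to a YAML file.
#' @param verbose Log derived constants via [message()].
#' @return A `ward_params` object.
#' @export
load_parameters <- function(path, verbose = FALSE) {
  cfg <- yaml::read_yaml(path)
  need <- c("revenue", "costs", "paediatrics", "obstetrics", "salaries")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop_invalid("configuration is missing section(s): %s",
                 paste(missing, collapse = ", "))
  }
  sal <- salary_primitives()
  sal$gross_salary_by_role[names(cfg$salaries$gross)] <-
    unlist(cfg$salaries$gross)
  sal$employer_share <- cfg$salaries$employer_share
  sal$weekly_hours <- cfg$salaries$weekly_hours
  sal$absence_weeks <- cfg$salaries$absence_weeks
  paed <- utils::modifyList(paediatrics_primitives(), cfg$paediatrics)
  obs <- utils::modifyList(obstetrics_primitives(), cfg$obstetrics)
  p <- default_parameters(
    base_case_value = cfg$revenue$base_case_value,
    cmi_paediatrics = cfg$revenue$cmi_paediatrics,
    obstetric_rebate = cfg$revenue$obstetric_rebate,
    variable_cost_paed = cfg$costs$variable_paediatrics,
    variable_cost_obs = cfg$costs$variable_obstetrics,
    department_fixed_paed = cfg$costs$department_fixed_paediatrics,
    department_fixed_obs = cfg$costs$department_fixed_obstetrics,
    bed_fixed_paed = cfg$costs$bed_fixed_paediatrics,
    bed_fixed_obs = cfg$costs$bed_fixed_obstetrics,
    min_beds = cfg$costs$min_beds %||% 5L,
    min_midwives = cfg$obstetrics$min_midwives %||% 5L,
    paed = paed[c("nursing_hours_per_day", "los", "physician_minutes_per_day")],
    obs = obs[names(obstetrics_primitives())],
    salaries = sal,
    hospital_fixed = cfg$costs$hospital_fixed %||% 0
  )
  if (verbose) {
    message(sprintf("paediatric rebate: %.5f = %.2f x %.3f",
                    p$wards$paediatrics$rebate, cfg$revenue$base_case_value,
                    cfg$revenue$cmi_paediatrics))
    message(sprintf("obstetric rebate (canonical): %.2f",
                    p$wards$obstetrics$rebate))
    message(sprintf("mixed obstetric LOS: %.4f days", p$wards$obstetrics$los))
    message(sprintf("annual staff capacity: %g h", p$staff$capacity_hours[1]))
    for (i in seq_len(nrow(p$staff))) {
      message(sprintf("staff %s: %.2f h/case, %s EUR/unit, min %d",
                      p$staff$id[i], p$staff$care_hours[i],
                      format(p$staff$unit_cost[i], big.mark = ","),
                      p$staff$min_units[i]))
    }
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ward_params <- function(x, ...) {
  cat("Ward-planning parameter set\n")
  for (w in x$wards) {
    cat(sprintf("  %-12s rebate %10.2f  variable %8.2f  LOS %5.2f d  dept fixed %s  bed fixed %s  min beds %d\n",
                w$drg_id, w$rebate, w$variable_cost, w$los,
                format(w$department_fixed, big.mark = ","),
                format(w$bed_fixed, big.mark = ","), w$min_beds))
  }
  cat("Staff categories:\n")
  print(x$staff, row.names = FALSE)
  invisible(x)
}
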