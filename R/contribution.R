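# The marginal-contribution ladder of a ward: revenue minus direct costs
# (contribution I), minus DRG-fixed costs (II), minus department-level fixed
# blocks (III). In the applied model the department block folds together the
# department fixed cost, the per-bed fixed costs and the step-fixed staff
# costs, which is how the result tables book them.

ward_staff <- function(params_or_staff, ward) {
  staff <- if (inherits(params_or_staff, "ward_params")) {
    params_or_staff$staff
  } else {
    params_or_staff
  }
  out <- staff[staff$ward == ward$drg_id, , drop = FALSE]
  if (nrow(out) == 0) stop_invalid("no staff categories for ward '%s'",
                                   ward$drg_id)
  out
}

# Annual cost of an OPEN ward as a function of allocated cases (vectorised).
# Unlike required_staff_units()/required_beds(), an open ward with zero
# cases still pays its department fixed cost, minimum staffing and minimum
# bed stock: opening a ward is what triggers the block, not the first case.
open_ward_cost <- function(cases, ward, staff, beds = NULL) {
  staff_cost <- rep(0, length(cases))
  for (i in seq_len(nrow(staff))) {
    units <- pmax(staff$min_units[i],
                  ceiling(round(cases * staff$care_hours[i] /
                                  staff$capacity_hours[i], 9)))
    staff_cost <- staff_cost + units * staff$unit_cost[i]
  }
  if (is.null(beds)) {
    beds <- pmax(ward$min_beds, ceiling(round(cases * ward$los / 365, 9)))
  }
  ward$department_fixed + ward$drg_fixed + staff_cost + beds * ward$bed_fixed
}

#' Contribution-margin ladder of one ward
#'
#' Computes the marginal-contribution ladder for a ward treating `cases`
#' cases per year: revenue, direct costs, contribution I, DRG-fixed costs,
#' contribution II, department-level fixed block (department fixed cost,
#' bed fixed costs and step-fixed staff costs), contribution III. A closed
#' ward (zero cases, `open = FALSE`) returns an all-zero ladder.
#'
#' @param cases Annual case count.
#' @param ward A ward specification (element of
#'   `default_parameters()$wards`).
#' @param staff A `ward_params` object or a staff data frame; only the rows
#'   belonging to the ward are used.
#' @param staff_units Optional named integer vector of staff units per
#'   category; defaults to [required_staff_units()] per category. Supplied
#'   staffing must cover the care-hour demand and respect the minima.
#' @param beds Optional bed stock; defaults to [required_beds()]. Supplied
#'   beds must cover the patient-days.
#' @param open Treat the ward as open even with zero cases (it then pays
#'   its full fixed block). Defaults to `cases > 0`.
#' @return An object of class `contribution_ladder`.
#' @examples
#' p <- default_parameters()
#' ward_contribution(1820, p$wards$paediatrics, p, beds = 24)
#' @export
ward_contribution <- function(cases, ward, staff, staff_units = NULL,
                              beds = NULL, open = cases > 0) {
  if (length(cases) != 1 || cases < 0) {
    stop_invalid("cases must be a single count >= 0")
  }
  staff <- ward_staff(staff, ward)
  if (!open) {
    return(new_ladder(ward$drg_id, cases = 0, beds = 0L,
                      staff_units = stats::setNames(integer(nrow(staff)),
                                                    staff$id),
                      revenue = 0, direct = 0, drg_fixed = 0, dept = 0))
  }
  if (is.null(staff_units)) {
    staff_units <- stats::setNames(
      pmax(staff$min_units,
           ceiling(round(cases * staff$care_hours / staff$capacity_hours, 9))),
      staff$id)
  } else {
    staff_units <- staff_units[staff$id]
    demand <- cases * staff$care_hours
    if (any(is.na(staff_units)) ||
        any(staff_units * staff$capacity_hours < demand - 1e-6) ||
        any(staff_units < staff$min_units)) {
      stop_invalid("infeasible staffing for ward '%s': units must cover the care-hour demand and the staffing minima", # nolint
                   ward$drg_id)
    }
  }
  if (is.null(beds)) {
    beds <- if (cases == 0) ward$min_beds else
      required_beds(cases, ward$los, ward$min_beds)
  } else if (beds * 365 < cases * ward$los - 1e-6 ||
             (beds < ward$min_beds && open)) {
    stop_invalid("infeasible bed stock for ward '%s'", ward$drg_id)
  }
  dept <- ward$department_fixed + beds * ward$bed_fixed +
    sum(staff_units * staff$unit_cost)
  new_ladder(ward$drg_id, cases = cases, beds = as.integer(beds),
             staff_units = stats::setNames(as.integer(staff_units), staff$id),
             revenue = cases * ward$rebate,
             direct = cases * ward$variable_cost,
             drg_fixed = ward$drg_fixed, dept = dept,
             utilization = bed_utilization(cases, ward$los, max(beds, 1L)))
}

new_ladder <- function(id, cases, beds, staff_units, revenue, direct,
                       drg_fixed, dept, hospital_fixed = 0,
                       utilization = 0) {
  c1 <- revenue - direct
  c2 <- c1 - drg_fixed
  c3 <- c2 - dept
  structure(list(
    ward = id, cases = cases, beds = beds, staff_units = staff_units,
    utilization = utilization,
    revenue = revenue, direct_cost = direct, contribution_I = c1,
    drg_fixed = drg_fixed, contribution_II = c2, department_fixed = dept,
    contribution_III = c3, hospital_fixed = hospital_fixed,
    profit = c3 - hospital_fixed
  ), class = "contribution_ladder")
}

#' Aggregate contribution ladders
#'
#' Field-wise sum of a collection of ladders, subtracting a hospital-level
#' (or region-level) fixed cost from the profit line. Aggregation is
#' associative; an empty collection gives the zero ladder.
#'
#' @param ladders A list of `contribution_ladder` objects.
#' @param hospital_fixed Fixed cost booked below contribution III, EUR.
#' @return A `contribution_ladder`.
#' @export
aggregate_ladders <- function(ladders, hospital_fixed = 0) {
  num_fields <- c("cases", "beds", "revenue", "direct_cost", "drg_fixed",
                  "department_fixed", "hospital_fixed")
  acc <- stats::setNames(as.list(rep(0, length(num_fields))), num_fields)
  units <- integer(0)
  for (l in ladders) {
    stopifnot(inherits(l, "contribution_ladder"))
    for (f in num_fields) acc[[f]] <- acc[[f]] + l[[f]]
    for (nm in names(l$staff_units)) {
      units[nm] <- (if (nm %in% names(units)) units[nm] else 0L) +
        l$staff_units[nm]
    }
  }
  out <- new_ladder("total", cases = acc$cases, beds = as.integer(acc$beds),
                    staff_units = units, revenue = acc$revenue,
                    direct = acc$direct_cost, drg_fixed = acc$drg_fixed,
                    dept = acc$department_fixed,
                    hospital_fixed = acc$hospital_fixed + hospital_fixed)
  out
}

#' @export
print.contribution_ladder <- function(x, ...) {
  eur <- function(v) formatC(round(v), big.mark = ",", format = "d")
  cat(sprintf("Contribution ladder (%s): %d cases, %d beds\n",
              x$ward, x$cases, x$beds))
  if (length(x$staff_units) && any(x$staff_units > 0)) {
    cat("  staff units:",
        paste(sprintf("%s=%d", names(x$staff_units), x$staff_units),
              collapse = ", "), "\n")
  }
  cat(sprintf("  revenue            %14s\n", eur(x$revenue)))
  cat(sprintf("  - direct cost      %14s\n", eur(x$direct_cost)))
  cat(sprintf("  = contribution I   %14s\n", eur(x$contribution_I)))
  cat(sprintf("  - DRG fixed        %14s\n", eur(x$drg_fixed)))
  cat(sprintf("  = contribution II  %14s\n", eur(x$contribution_II)))
  cat(sprintf("  - department block %14s\n", eur(x$department_fixed)))
  cat(sprintf("  = contribution III %14s\n", eur(x$contribution_III)))
  cat(sprintf("  - hospital fixed   %14s\n", eur(x$hospital_fixed)))
  cat(sprintf("  = profit/loss      %14s\n", eur(x$profit)))
  invisible(x)
}
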