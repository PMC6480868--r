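# Step-fixed capacity rules: staffing units, beds, utilization.
# Staff and beds are indivisible, so requirements round up; a closed ward
# (zero cases) needs nothing. round(.,9) guards the ceiling against binary
# floating-point noise at exact step boundaries.

#' Staff units required for a case load
#'
#' Smallest integer number of staff units that covers the annual care hours
#' demanded by `cases` while respecting the minimum staffing of an open
#' ward. A ward with zero cases is closed and needs no staff.
#'
#' @param cases Annual case count(s); vectorised.
#' @param care_hours_per_case Hours of this category consumed per case.
#' @param capacity Annual productive hours of one unit.
#' @param minimum Minimum units for an open ward.
#' @return Integer unit count(s).
#' @examples
#' required_staff_units(1820, 16.12, 1760, 9) # 17 paediatric nurses
#' required_staff_units(496, 2.325, 1760, 5)  # minimum of 5 physicians binds
#' @export
required_staff_units <- function(cases, care_hours_per_case, capacity,
                                 minimum) {
  if (any(cases < 0)) stop_invalid("cases must be >= 0")
  if (capacity <= 0) stop_invalid("capacity must be positive")
  workload <- ceiling(round(cases * care_hours_per_case / capacity, 9))
  as.integer(ifelse(cases == 0, 0L, pmax(minimum, workload)))
}

#' Beds required for a case load
#'
#' Beds needed so that annual patient-days (`cases * los`) fit into annual
#' bed-days (`beds * 365`), with a minimum bed stock for an open ward and 0
#' for a closed one. A 365-day year is used (100% utilization framing, no
#' occupancy discount).
#'
#' @param cases Annual case count(s); vectorised.
#' @param los Average length of stay in days.
#' @param min_beds Minimum beds for an open ward.
#' @return Integer bed count(s).
#' @examples
#' required_beds(3373, 3.1)    # 29 paediatric beds
#' required_beds(280, 4.9172)  # minimum of 5 binds (ceiling gives 4)
#' @export
required_beds <- function(cases, los, min_beds = 5L) {
  if (any(cases < 0)) stop_invalid("cases must be >= 0")
  if (los <= 0) stop_invalid("los must be positive")
  need <- ceiling(round(cases * los / 365, 9))
  as.integer(ifelse(cases == 0, 0L, pmax(min_beds, need)))
}

#' Capacity utilization of a ward
#'
#' Annual patient-days divided by annual bed-days.
#'
#' @param cases Annual case count(s).
#' @param los Average length of stay in days.
#' @param beds Bed stock; must be positive when `cases > 0`.
#' @return Utilization as a fraction; 0 for an empty closed ward.
#' @examples
#' bed_utilization(1057, 3.1, 18) # about 50%
#' @export
bed_utilization <- function(cases, los, beds) {
  if (any(beds == 0 & cases > 0)) {
    stop_invalid("beds must be positive when cases > 0")
  }
  ifelse(cases == 0, 0, cases * los / (beds * 365))
}
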