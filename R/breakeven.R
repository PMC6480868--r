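# Break-even case volumes. A ward's contribution margin is piecewise
# linear in its case load with downward jumps at every staff or bed step,
# so it can touch zero briefly and fall back below it. The planning-
# relevant break-even volume is the smallest load at and ABOVE which the
# margin stays non-negative, i.e. one past the last loss-making volume.

#' Break-even case volume of a stand-alone ward
#'
#' Scans integer case counts and returns the smallest annual volume such
#' that the ward's contribution margin III is non-negative at that volume
#' and at every larger volume up to `cap` (beds and integer staffing are
#' re-derived at every step via the ceiling rules). Because the margin has
#' step discontinuities it can cross zero more than once; the suffix
#' definition used here is the volume from which the ward is durably
#' viable.
#'
#' @param ward A ward specification.
#' @param staff A `ward_params` object or staff data frame.
#' @param cap Largest volume scanned; if the margin is still negative
#'   somewhere in the top bed-step below `cap`, the break-even is reported
#'   as unreachable.
#' @return A list of class `break_even` with elements `cases`, `beds`,
#'   `reached` and `contribution` (the margin at the break-even volume).
#' @examples
#' p <- default_parameters()
#' break_even(p$wards$paediatrics, p) # 1587 cases, 14 beds
#' @export
break_even <- function(ward, staff, cap = 5000) {
  staff_df <- ward_staff(staff, ward)
  margin <- ward$rebate - ward$variable_cost
  if (margin <= 0) {
    return(structure(list(cases = NA_integer_, beds = NA_integer_,
                          reached = FALSE, cap = cap,
                          reason = "margin per case is not positive"),
                     class = "break_even"))
  }
  x <- seq_len(cap)
  contrib <- x * margin - open_ward_cost(x, ward, staff_df)
  neg <- which(contrib < 0)
  cases <- if (length(neg) == 0) 1L else max(neg) + 1L
  if (cases > cap) {
    return(structure(list(cases = NA_integer_, beds = NA_integer_,
                          reached = FALSE, cap = cap,
                          reason = sprintf("no durable break-even below cap = %d", cap)), # nolint
                     class = "break_even"))
  }
  structure(list(cases = cases,
                 beds = required_beds(cases, ward$los, ward$min_beds),
                 reached = TRUE, contribution = contrib[cases], cap = cap),
            class = "break_even")
}

#' @export
print.break_even <- function(x, ...) {
  if (!x$reached) {
    cat(sprintf("Break-even unreachable (%s)\n", x$reason))
  } else {
    cat(sprintf("Break-even at %d cases/year (%d beds); margin there %s EUR\n",
                x$cases, x$beds,
                formatC(round(x$contribution), big.mark = ",", format = "d")))
  }
  invisible(x)
}
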