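# Plain-text (CSV) interchange for regions. Municipalities: one row per
# municipality with columns id, x_km, y_km, pop_children, pop_women,
# cases_paed, cases_obst. Travel times: long format with columns id,
# hospital_id, minutes.

#' Write a region to CSV files
#'
#' @param region A `region` from [simulate_region()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`municipalities.csv`,
#'   `travel_times.csv`, `hospitals.csv`).
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  muni_path <- file.path(dir, "municipalities.csv")
  tt_path <- file.path(dir, "travel_times.csv")
  hosp_path <- file.path(dir, "hospitals.csv")
  cols <- c("id", "x_km", "y_km", "pop_children", "pop_women",
            "cases_paed", "cases_obst")
  utils::write.csv(region$municipalities[, cols], muni_path,
                   row.names = FALSE)
  long <- data.frame(
    id = rep(rownames(region$minutes), times = ncol(region$minutes)),
    hospital_id = rep(colnames(region$minutes),
                      each = nrow(region$minutes)),
    minutes = as.vector(region$minutes)
  )
  utils::write.csv(long, tt_path, row.names = FALSE)
  utils::write.csv(region$hospitals, hosp_path, row.names = FALSE)
  invisible(c(muni_path, tt_path, hosp_path))
}

#' Read a region from CSV files
#'
#' Counterpart of [write_region()]; validates the column schema and
#' reassembles the travel-time matrix.
#'
#' @param municipalities_csv Path to the municipality table.
#' @param travel_times_csv Path to the long-format travel-time table.
#' @return A list of class `region` (without a recipe).
#' @export
read_region <- function(municipalities_csv, travel_times_csv) {
  muni <- utils::read.csv(municipalities_csv, stringsAsFactors = FALSE)
  need <- c("id", "x_km", "y_km", "pop_children", "pop_women",
            "cases_paed", "cases_obst")
  missing <- setdiff(need, names(muni))
  if (length(missing)) {
    stop_invalid("municipality table is missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  long <- utils::read.csv(travel_times_csv, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "hospital_id", "minutes"), names(long))
  if (length(missing)) {
    stop_invalid("travel-time table is missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  hosp_ids <- sort(unique(long$hospital_id))
  minutes <- matrix(NA_real_, nrow = nrow(muni), ncol = length(hosp_ids),
                    dimnames = list(muni$id, hosp_ids))
  minutes[cbind(match(long$id, muni$id),
                match(long$hospital_id, hosp_ids))] <- long$minutes
  if (any(is.na(minutes))) {
    stop_invalid("travel-time table does not cover every municipality x hospital pair") # nolint
  }
  catchment_total <- c(paediatrics = sum(muni$cases_paed),
                       obstetrics = sum(muni$cases_obst))
  structure(list(municipalities = muni,
                 hospitals = data.frame(id = hosp_ids),
                 minutes = minutes, catchment_total = catchment_total,
                 demand = catchment_total, recipe = NULL),
            class = "region")
}
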