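# Travel-time catchments and accessibility. Patients are assumed to visit
# the nearest OPEN hospital by travel time; municipalities are assigned
# whole (by their centre point). External competitor hospitals in
# neighbouring regions may appear as additional columns of the travel-time
# matrix: they capture municipalities like any other site but contribute
# no economics to the planning stage.

check_matrix <- function(minutes) {
  if (!is.matrix(minutes) || is.null(colnames(minutes))) {
    stop_invalid("minutes must be a municipality x hospital matrix with hospital column names") # nolint
  }
  if (any(!is.finite(minutes)) || any(minutes < 0)) {
    stop_invalid("travel times must be finite and >= 0")
  }
}

resolve_open <- function(minutes, open_hospitals) {
  if (length(open_hospitals) == 0) {
    stop_invalid("invalid scenario: at least one hospital must be open")
  }
  if (is.character(open_hospitals)) {
    bad <- setdiff(open_hospitals, colnames(minutes))
    if (length(bad)) stop_invalid("unknown hospital(s): %s",
                                  paste(bad, collapse = ", "))
    open_hospitals <- match(open_hospitals, colnames(minutes))
  }
  sort(unique(open_hospitals))
}

#' Assign municipalities to nearest-open-hospital catchments
#'
#' Every municipality is assigned to the open hospital with the smallest
#' travel time; ties go to the hospital with the lower column index (lower
#' id). Case counts, if given, aggregate to catchment totals.
#'
#' @param minutes Municipality-by-hospital travel-time matrix in minutes,
#'   with hospital names as column names.
#' @param open_hospitals Open hospitals (indices or column names).
#' @param cases Optional data frame or matrix of per-municipality case
#'   counts (one column per ward type) to aggregate by catchment.
#' @return A list of class `catchment_assignment` with `nearest` (hospital
#'   name per municipality), `minutes_to_nearest`, and, when `cases` is
#'   given, `catchment_cases` (hospital-by-ward-type totals over open
#'   hospitals).
#' @export
assign_catchments <- function(minutes, open_hospitals = colnames(minutes),
                              cases = NULL) {
  check_matrix(minutes)
  open <- resolve_open(minutes, open_hospitals)
  sub <- minutes[, open, drop = FALSE]
  idx <- apply(sub, 1, which.min) # first minimum = lowest id on ties
  nearest <- colnames(sub)[idx]
  out <- list(nearest = stats::setNames(nearest, rownames(minutes)),
              minutes_to_nearest = stats::setNames(
                sub[cbind(seq_len(nrow(sub)), idx)], rownames(minutes)),
              open = colnames(sub))
  if (!is.null(cases)) {
    cases <- as.matrix(cases)
    if (nrow(cases) != nrow(minutes)) {
      stop_invalid("cases must have one row per municipality")
    }
    totals <- rowsum(cases, group = factor(nearest, levels = colnames(sub)))
    out$catchment_cases <- totals
  }
  structure(out, class = "catchment_assignment")
}

#' Population beyond a travel-time threshold
#'
#' Share and absolute count of a population stratum whose nearest open
#' hospital is further than `threshold_minutes` away.
#'
#' @inheritParams assign_catchments
#' @param threshold_minutes Travel-time threshold (> 0).
#' @param population Per-municipality population of the stratum.
#' @return A list with `share` (fraction) and `count`.
#' @export
population_share_beyond <- function(minutes, open_hospitals, threshold_minutes,
                                    population) {
  if (threshold_minutes <= 0) stop_invalid("threshold must be > 0")
  if (length(population) != nrow(minutes) || any(population < 0)) {
    stop_invalid("population must be a non-negative vector with one entry per municipality") # nolint
  }
  a <- assign_catchments(minutes, open_hospitals)
  beyond <- a$minutes_to_nearest > threshold_minutes
  total <- sum(population)
  list(share = if (total == 0) 0 else sum(population[beyond]) / total,
       count = sum(population[beyond]))
}

#' Population by travel-time band
#'
#' Tabulates population strata into travel-time bands to the nearest open
#' hospital (default bands: up to 20, 20-30, 30-40 and over 40 minutes).
#'
#' @inheritParams assign_catchments
#' @param populations Data frame of per-municipality stratum counts (e.g.
#'   columns `pop_children`, `pop_women`).
#' @param breaks Band boundaries in minutes.
#' @return A data frame with one row per band and one count column per
#'   stratum plus the band share columns.
#' @export
travel_band_table <- function(minutes, open_hospitals, populations,
                              breaks = c(20, 30, 40)) {
  a <- assign_catchments(minutes, open_hospitals)
  populations <- as.data.frame(populations)
  edges <- c(0, breaks, Inf)
  labels <- c(paste0("<=", breaks[1], " min"),
              paste0(breaks[-length(breaks)], "-", breaks[-1], " min"),
              paste0(">", breaks[length(breaks)], " min"))
  band <- cut(a$minutes_to_nearest, breaks = edges, labels = labels,
              include.lowest = TRUE, right = TRUE)
  out <- data.frame(band = labels)
  for (col in names(populations)) {
    counts <- tapply(populations[[col]], band, sum, default = 0)
    out[[col]] <- as.numeric(counts[labels])
    tot <- sum(populations[[col]])
    out[[paste0(col, "_share")]] <-
      if (tot == 0) 0 else out[[col]] / tot
  }
  out
}
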