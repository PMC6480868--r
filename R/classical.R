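# Two classical planning formulas that frame the regional problem: the
# Hill-Burton bed-demand formula used in state hospital plans, and the
# hexagonal-catchment cost-per-inhabitant formula linking hospital cost to
# the maximum travel distance in a region.

#' Hill-Burton bed demand
#'
#' Beds required by a department serving a population:
#' `P * h / 1000` admissions per year, times the average length of stay,
#' spread over `365 * a` usable bed-days per bed and year.
#'
#' @param population Population served (P).
#' @param admission_rate_per_1000 Annual admissions per 1000 inhabitants.
#' @param avg_los_days Average length of stay in days.
#' @param occupancy_rate Target occupancy in (0, 1].
#' @return Bed demand as a real number (callers may round up).
#' @examples
#' hill_burton_beds(170000, 50, 3.1, 0.85)
#' @export
hill_burton_beds <- function(population, admission_rate_per_1000,
                             avg_los_days, occupancy_rate) {
  if (any(occupancy_rate <= 0) || any(occupancy_rate > 1)) {
    stop_invalid("occupancy_rate must lie in (0, 1]")
  }
  if (any(population < 0) || any(admission_rate_per_1000 < 0) ||
      any(avg_los_days <= 0)) {
    stop_invalid("population and admission rate must be >= 0, LOS > 0")
  }
  population * admission_rate_per_1000 * avg_los_days /
    (occupancy_rate * 1000 * 365)
}

#' Hospital cost per inhabitant under hexagonal catchments
#'
#' If every inhabitant is within `r` km of a hospital and catchments tile
#' the region as regular hexagons (area `3 r^2 sin(60 deg)` each), the
#' region needs `AT / (3 r^2 sin 60)` hospitals; the annual cost per
#' inhabitant is the fixed cost of those hospitals spread over the
#' population plus the admission-rate-weighted variable cost:
#' `K/P = AT / (P 3 r^2 sin 60) * F + h v`. The admission rate `h` is per
#' inhabitant and year.
#'
#' @param max_distance_km Maximum travel distance r in km (> 0).
#' @param total_area_km2 Region area AT in square km.
#' @param population Regional population P.
#' @param admission_rate Admissions per inhabitant and year.
#' @param fixed_cost_per_hospital Annual fixed cost F per hospital, EUR.
#' @param variable_cost_per_case Variable cost v per case, EUR.
#' @return Cost in EUR per inhabitant per year.
#' @examples
#' hexagon_cost_per_capita(25, 10000, 5e5, 0.2, 1e7, 3000)
#' @export
hexagon_cost_per_capita <- function(max_distance_km, total_area_km2,
                                    population, admission_rate,
                                    fixed_cost_per_hospital,
                                    variable_cost_per_case) {
  if (any(max_distance_km <= 0)) stop_invalid("max_distance_km must be > 0")
  if (any(c(total_area_km2, population, fixed_cost_per_hospital) <= 0) ||
      any(c(admission_rate, variable_cost_per_case) < 0)) {
    stop_invalid("area, population and fixed cost must be > 0; rates >= 0")
  }
  sin60 <- sqrt(3) / 2 # hexagon geometry: sin(60 degrees)
  total_area_km2 / (population * 3 * max_distance_km^2 * sin60) *
    fixed_cost_per_hospital + admission_rate * variable_cost_per_case
}

#' Cost-per-inhabitant curve over maximum distances
#'
#' Evaluates [hexagon_cost_per_capita()] on a grid of maximum distances,
#' for plotting the accessibility/cost trade-off.
#'
#' @param r Vector of maximum distances in km.
#' @inheritParams hexagon_cost_per_capita
#' @return A data frame of class `hexagon_curve` with columns
#'   `max_distance_km` and `cost_per_capita`.
#' @export
hexagon_cost_curve <- function(r = seq(5, 60, by = 1), total_area_km2,
                               population, admission_rate,
                               fixed_cost_per_hospital,
                               variable_cost_per_case) {
  out <- data.frame(
    max_distance_km = r,
    cost_per_capita = hexagon_cost_per_capita(
      r, total_area_km2, population, admission_rate,
      fixed_cost_per_hospital, variable_cost_per_case)
  )
  class(out) <- c("hexagon_curve", "data.frame")
  out
}

#' @export
plot.hexagon_curve <- function(x, ...) {
  graphics::plot(x$max_distance_km, x$cost_per_capita, type = "l",
                 xlab = "maximum distance to nearest hospital [km]",
                 ylab = "hospital cost per inhabitant [EUR/year]", ...)
  invisible(x)
}
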