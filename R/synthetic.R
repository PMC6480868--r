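# Synthetic regions with the statistical structure the planning analysis
# assumes: municipalities with skewed population sizes, at-risk strata
# (children under 18, women 15-50), Poisson case counts with stratum-
# proportional means, hospitals at the most populous places, and travel
# times proportional to straight-line distance. Defaults mirror the scale
# of a rural north-east German district (about 3,900 km^2, 240,000
# inhabitants, three hospital sites, about 3,000 paediatric cases and
# 1,000 births per year arising in the region).

#' Recipe for a synthetic planning region
#'
#' @param n_municipalities Number of municipalities.
#' @param area_km2 Region area (rectangle) in square km.
#' @param population_total Total population.
#' @param population_dispersion Log-scale standard deviation of the
#'   lognormal municipality-size distribution (right-skewed: few towns,
#'   many villages).
#' @param frac_children Fraction of the population under 18.
#' @param frac_women Fraction of the population that is women aged 15-50.
#' @param admission_rate_paed Paediatric admissions per child per year.
#' @param birth_rate Births per woman (15-50) per year.
#' @param n_hospitals Number of hospital sites (placed at the most
#'   populous municipalities).
#' @param road_factor Minutes of travel per straight-line km (detour and
#'   speed folded into one factor).
#' @param external_inflow Named fractions of extra hospital case load from
#'   outside the region, per ward type, reflecting that hospitals can
#'   treat more cases than their catchments contain.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `region_recipe`.
#' @export
region_recipe <- function(n_municipalities = 60,
                          area_km2 = 3930,
                          population_total = 240000,
                          population_dispersion = 1.1,
                          frac_children = 0.107,
                          frac_women = 0.146,
                          admission_rate_paed = 0.117,
                          birth_rate = 0.029,
                          n_hospitals = 3,
                          road_factor = 1.1,
                          external_inflow = c(paediatrics = 0.12,
                                              obstetrics = 0.42),
                          seed = 1L) {
  if (frac_children < 0 || frac_children > 1 || frac_women < 0 ||
      frac_women > 1) {
    stop_invalid("strata fractions must lie in [0, 1]")
  }
  if (admission_rate_paed < 0 || birth_rate < 0) {
    stop_invalid("rates must be >= 0")
  }
  if (road_factor <= 0) stop_invalid("road_factor must be > 0")
  if (n_hospitals > n_municipalities) {
    stop_invalid("invalid recipe: n_hospitals exceeds n_municipalities")
  }
  structure(as.list(environment()), class = "region_recipe")
}

#' Generate a synthetic region
#'
#' Scatters municipality centres uniformly over a rectangle of the given
#' area, draws municipality populations from a lognormal distribution
#' normalised to the regional total, splits them into the at-risk strata,
#' draws integer case counts per municipality from Poisson distributions
#' with mean rate-times-stratum, places hospitals at the `n_hospitals`
#' most populous municipalities and derives the travel-time matrix as
#' Euclidean distance times the road factor. Fully reproducible from the
#' recipe seed.
#'
#' @param recipe A [region_recipe()].
#' @return A list of class `region` with elements `municipalities` (data
#'   frame: id, x_km, y_km, pop_children, pop_women, cases_paed,
#'   cases_obst), `hospitals` (data frame: id, municipality, x_km, y_km),
#'   `minutes` (travel-time matrix), `demand` (regional hospital case
#'   load per ward type, catchment cases scaled by the external inflow)
#'   and the `recipe`.
#' @export
simulate_region <- function(recipe = region_recipe()) {
  stopifnot(inherits(recipe, "region_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n_municipalities
  side_x <- sqrt(recipe$area_km2 * 2) # 2:1 rectangle, roughly coastal
  side_y <- sqrt(recipe$area_km2 / 2)
  muni <- data.frame(
    id = sprintf("m%02d", seq_len(n)),
    x_km = stats::runif(n, 0, side_x),
    y_km = stats::runif(n, 0, side_y)
  )
  w <- stats::rlnorm(n, meanlog = 0, sdlog = recipe$population_dispersion)
  pop <- round(w / sum(w) * recipe$population_total)
  muni$population <- pop
  muni$pop_children <- round(pop * recipe$frac_children)
  muni$pop_women <- round(pop * recipe$frac_women)
  muni$cases_paed <- stats::rpois(n, recipe$admission_rate_paed *
                                    muni$pop_children)
  muni$cases_obst <- stats::rpois(n, recipe$birth_rate * muni$pop_women)
  host <- order(pop, decreasing = TRUE)[seq_len(recipe$n_hospitals)]
  hospitals <- data.frame(
    id = sprintf("h%d", seq_len(recipe$n_hospitals)),
    municipality = muni$id[host],
    x_km = muni$x_km[host],
    y_km = muni$y_km[host]
  )
  dist_km <- sqrt(outer(muni$x_km, hospitals$x_km, "-")^2 +
                    outer(muni$y_km, hospitals$y_km, "-")^2)
  minutes <- dist_km * recipe$road_factor
  dimnames(minutes) <- list(muni$id, hospitals$id)
  catchment_total <- c(paediatrics = sum(muni$cases_paed),
                       obstetrics = sum(muni$cases_obst))
  inflow <- recipe$external_inflow[names(catchment_total)]
  inflow[is.na(inflow)] <- 0
  demand <- round(catchment_total * (1 + inflow))
  structure(list(municipalities = muni, hospitals = hospitals,
                 minutes = minutes, catchment_total = catchment_total,
                 demand = demand, recipe = recipe),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("Synthetic region: %d municipalities, %d hospitals, %s inhabitants\n", # nolint
              nrow(x$municipalities), nrow(x$hospitals),
              format(sum(x$municipalities$population), big.mark = ",")))
  cat(sprintf("Regional cases: %d paediatric, %d births (hospital demand %d / %d with external inflow)\n", # nolint
              x$catchment_total[["paediatrics"]],
              x$catchment_total[["obstetrics"]],
              x$demand[["paediatrics"]], x$demand[["obstetrics"]]))
  invisible(x)
}

#' The study region's printed case loads and bed stocks
#'
#' The 2014 data of the three-hospital study region: per-hospital ward
#' case loads, nearest-hospital catchment case totals and historical bed
#' stocks. Hospital case loads exceed the catchment totals because
#' patients flow in from outside the region; the economic scenarios use
#' the hospital volumes as regional demand.
#'
#' @return A list of class `study_region` with `hospitals` (names),
#'   `hospital_cases` and `catchment_cases` (ward-by-hospital matrices),
#'   `beds` (ward-by-hospital matrix) and `demand` (regional totals per
#'   ward type).
#' @examples
#' study_region()$demand # 3373 paediatric cases, 1437 births
#' @export
study_region <- function() {
  hospitals <- c("Greifswald", "Wolgast", "Anklam")
  hospital_cases <- rbind(paediatrics = c(1820, 1057, 496),
                          obstetrics = c(800, 357, 280))
  catchment_cases <- rbind(paediatrics = c(1192, 926, 898),
                           obstetrics = c(518, 203, 293))
  beds <- rbind(paediatrics = c(24L, 18L, 16L),
                obstetrics = c(24L, 11L, 6L))
  colnames(hospital_cases) <- colnames(catchment_cases) <-
    colnames(beds) <- hospitals
  structure(list(hospitals = hospitals, hospital_cases = hospital_cases,
                 catchment_cases = catchment_cases, beds = beds,
                 demand = rowSums(hospital_cases)),
            class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat("Study region (2014): ward case loads and bed stocks\n")
  cat("Hospital cases:\n"); print(x$hospital_cases)
  cat("Catchment cases:\n"); print(x$catchment_cases)
  cat("Beds:\n"); print(x$beds)
  invisible(x)
}
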