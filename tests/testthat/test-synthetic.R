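test_that("generation is deterministic in the seed", {
  r1 <- simulate_region(region_recipe(seed = 11))
  r2 <- simulate_region(region_recipe(seed = 11))
  expect_identical(r1$municipalities, r2$municipalities)
  expect_identical(r1$minutes, r2$minutes)
  r3 <- simulate_region(region_recipe(seed = 12))
  expect_false(identical(r1$municipalities, r3$municipalities))
})

test_that("case totals sit within 3 SD of the analytic generator mean", {
  rec <- region_recipe(seed = 5)
  reg <- simulate_region(rec)
  mu_paed <- rec$admission_rate_paed * sum(reg$municipalities$pop_children)
  mu_obst <- rec$birth_rate * sum(reg$municipalities$pop_women)
  expect_lt(abs(sum(reg$municipalities$cases_paed) - mu_paed),
            3 * sqrt(mu_paed))
  expect_lt(abs(sum(reg$municipalities$cases_obst) - mu_obst),
            3 * sqrt(mu_obst))
})

test_that("populations and strata conserve the recipe totals", {
  rec <- region_recipe(seed = 9)
  reg <- simulate_region(rec)
  muni <- reg$municipalities
  expect_lt(abs(sum(muni$population) - rec$population_total),
            rec$n_municipalities) # rounding slack of < 1 per municipality
  expect_true(all(muni$pop_children + muni$pop_women <= muni$population + 2))
  expect_true(all(muni$pop_children >= 0 & muni$pop_women >= 0))
  expect_equal(nrow(reg$hospitals), rec$n_hospitals)
  expect_error(region_recipe(n_municipalities = 2, n_hospitals = 3),
               "invalid recipe")
})

test_that("the study fixture carries the printed case loads and beds", {
  expect_equal(unname(study$demand),
               c(3373, 1437))
  expect_equal(sum(study$catchment_cases["paediatrics", ]), 3016)
  expect_equal(sum(study$catchment_cases["obstetrics", ]), 1014)
  expect_equal(unname(study$hospital_cases["paediatrics", ]),
               c(1820, 1057, 496))
  expect_equal(unname(study$beds["obstetrics", ]), c(24L, 11L, 6L))
  expect_true(all(study$hospital_cases >= 0))
})

test_that("a study-scale synthetic region reproduces the scenario pattern", {
  reg <- simulate_region(region_recipe(seed = 1))
  # demand within 10% of the study-region scale
  expect_lt(abs(reg$demand[["paediatrics"]] - 3373) / 3373, 0.1)
  expect_lt(abs(reg$demand[["obstetrics"]] - 1437) / 1437, 0.1)
  one <- plan_region(plan_problem(
    params, demand = reg$demand, n_hospitals = 3, n_open_hospitals = 1,
    open_wards_per_drg = 1, wards_follow_hospital = TRUE))
  three <- plan_region(plan_problem(
    params, demand = reg$demand, n_hospitals = 3, n_open_hospitals = 3,
    open_wards_per_drg = 3, wards_follow_hospital = TRUE))
  expect_gt(one$objective, 0)   # concentration is viable
  expect_lt(three$objective, 0) # three parallel wards are not
  expect_lt(abs(one$objective - 2087597) / 2087597, 0.1)
})

test_that("regions round-trip through the CSV schema", {
  reg <- simulate_region(region_recipe(seed = 2, n_municipalities = 12))
  dir <- tempfile()
  paths <- write_region(reg, dir)
  back <- read_region(paths[1], paths[2])
  expect_equal(back$municipalities$pop_children,
               reg$municipalities$pop_children)
  expect_equal(back$minutes, reg$minutes)
  expect_equal(unname(back$catchment_total), unname(reg$catchment_total))
  # schema violations are named
  bad <- reg$municipalities[, setdiff(names(reg$municipalities),
                                      "pop_children")]
  f <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_region(f, paths[2]), "missing column")
})
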