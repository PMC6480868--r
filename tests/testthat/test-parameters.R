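test_that("rebate derivation is the base value times the case-mix index", {
  expect_equal(round(derive_rebate(3117.36, 0.483), 2), 1505.68)
  expect_equal(derive_rebate(1234.5, 1), 1234.5)
  # linear in both arguments
  expect_equal(derive_rebate(2 * 3117.36, 0.483),
               2 * derive_rebate(3117.36, 0.483))
  expect_equal(derive_rebate(3117.36, 3 * 0.483),
               3 * derive_rebate(3117.36, 0.483))
  expect_error(derive_rebate(-1, 0.5), "positive")
  expect_error(derive_rebate(100, 0), "positive")
})

test_that("mixed length of stay is the caesarean-weighted mean", {
  expect_equal(round(derive_mixed_los(0.356, 7.3, 3.6), 2), 4.92)
  expect_equal(derive_mixed_los(0, 7.3, 3.6), 3.6)
  expect_equal(derive_mixed_los(1, 7.3, 3.6), 7.3)
  for (rate in seq(0, 1, by = 0.1)) {
    los <- derive_mixed_los(rate, 7.3, 3.6)
    expect_gte(los, 3.6)
    expect_lte(los, 7.3)
  }
  expect_error(derive_mixed_los(1.2, 7.3, 3.6), "\\[0, 1\\]")
})

test_that("staff unit costs and annual capacities match the working set", {
  expect_equal(derive_staff_unit_cost(42000, 0.35), 56700)
  expect_equal(derive_staff_unit_cost(75000, 0.35), 101250)
  expect_equal(derive_staff_unit_cost(12345, 0), 12345)
  expect_equal(derive_annual_capacity(40, 8), 1760)
  expect_equal(derive_annual_capacity(40, 0), 2080)
  expect_equal(derive_annual_capacity(20, 8), 880)
  expect_error(derive_annual_capacity(40, 52), "absence")
})

test_that("coverage minima reproduce the staffing floors", {
  # 2 nurses on two core shifts, 1 off-peak: 9 nurses
  expect_identical(derive_min_staff_from_coverage(2, 1, 3, 40, 8), 9L)
  # one person around the clock: 5 midwives
  expect_identical(derive_min_staff_from_coverage(1, 1, 3, 40, 8), 5L)
  # no absence: 24 h/day over a 40 h week is 4.2, rounds up to 5
  expect_identical(derive_min_staff_from_coverage(1, 1, 3, 40, 0), 5L)
  expect_identical(derive_min_staff_from_coverage(0, 0, 3, 40, 8), 0L)
})

test_that("care-time coefficients derive from the daily primitives", {
  care <- derive_care_hours()
  expect_equal(care[["ped_nurse"]], 5.2 * 3.1)
  expect_equal(care[["ped_physician"]], 0.75 * 3.1)
  expect_equal(care[["midwife"]], 14.5)
  expect_equal(round(care[["obs_nurse"]], 2), 22.62)
  expect_equal(care[["obs_physician"]], 0.644 * 1 + 0.356 * 5)
})

test_that("the derived parameter set reproduces the printed constants", {
  expect_true(all(params$staff$capacity_hours == 1760))
  expect_equal(sort(unique(params$staff$unit_cost)), c(56700, 101250))
  expect_equal(round(params$wards$paediatrics$rebate, 2), 1505.68)
  expect_equal(params$wards$paediatrics$los, 3.10)
  expect_equal(round(params$wards$obstetrics$los, 2), 4.92)
  expect_identical(params$staff$min_units,
                   c(9L, 5L, 5L, 9L, 5L))
})

test_that("the YAML loader reproduces the default parameter set", {
  path <- system.file("extdata", "parameters.yaml", package = "wardplan")
  loaded <- load_parameters(path)
  expect_equal(loaded$wards, params$wards)
  expect_equal(loaded$staff, params$staff)
  expect_message(load_parameters(path, verbose = TRUE), "rebate")
  bad <- tempfile(fileext = ".yaml")
  writeLines("revenue:\n  base_case_value: 1", bad)
  expect_error(load_parameters(bad), "missing section")
})
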