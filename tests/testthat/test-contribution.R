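ped <- params$wards$paediatrics
obs <- params$wards$obstetrics

test_that("ward ladders reproduce the three-hospital margins to the euro", {
  g <- ward_contribution(1820, ped, params, beds = 24)
  expect_identical(g$staff_units[["ped_nurse"]], 17L)
  expect_identical(g$staff_units[["ped_physician"]], 5L)
  expect_lt(abs(g$contribution_III - 49899), 5)
  a <- ward_contribution(496, ped, params, beds = 16)
  expect_identical(a$staff_units[["ped_nurse"]], 9L) # minimum binds
  expect_lt(abs(a$contribution_III - (-1165970)), 5)
  # ladder identities
  expect_equal(g$contribution_I, g$revenue - g$direct_cost)
  expect_equal(g$contribution_II, g$contribution_I - g$drg_fixed)
  expect_equal(g$contribution_III, g$contribution_II - g$department_fixed)
})

test_that("a closed ward has an all-zero ladder", {
  z <- ward_contribution(0, ped, params)
  for (f in c("revenue", "direct_cost", "contribution_I", "contribution_II",
              "contribution_III", "profit", "beds")) {
    expect_equal(z[[f]], 0, info = f)
  }
})

test_that("aggregation sums field-wise and is associative", {
  gp <- ward_contribution(1820, ped, params, beds = 24)
  go <- ward_contribution(800, obs, params, beds = 24)
  hosp <- aggregate_ladders(list(gp, go))
  expect_lt(abs(hosp$profit - (-328670)), 10)
  wp <- ward_contribution(1057, ped, params, beds = 18)
  wo <- ward_contribution(357, obs, params, beds = 11)
  flat <- aggregate_ladders(list(gp, go, wp, wo))
  nested <- aggregate_ladders(list(aggregate_ladders(list(gp, go)),
                                   aggregate_ladders(list(wp, wo))))
  expect_equal(flat$profit, nested$profit)
  expect_equal(flat$contribution_I, nested$contribution_I)
  # empty collection is the zero ladder
  expect_equal(aggregate_ladders(list())$profit, 0)
})

test_that("contribution is linear in cases between step thresholds", {
  margin <- ped$rebate - ped$variable_cost
  c0 <- ward_contribution(1000, ped, params)
  c1 <- ward_contribution(1001, ped, params)
  expect_identical(c0$staff_units, c1$staff_units) # no step crossed
  expect_identical(c0$beds, c1$beds)
  expect_equal(c1$contribution_III - c0$contribution_III, margin)
})

test_that("infeasible staffing or beds are rejected", {
  expect_error(
    ward_contribution(1820, ped, params,
                      staff_units = c(ped_nurse = 10L, ped_physician = 5L)),
    "infeasible staffing")
  expect_error(
    ward_contribution(1820, ped, params,
                      staff_units = c(ped_nurse = 17L, ped_physician = 4L)),
    "infeasible staffing")
  expect_error(ward_contribution(3373, ped, params, beds = 20),
               "infeasible bed")
})

test_that("an open ward with zero cases still pays its fixed block", {
  z <- ward_contribution(0, ped, params, open = TRUE)
  expect_identical(z$staff_units[["ped_nurse"]], 9L)
  expect_identical(z$beds, 5L)
  expect_lt(z$contribution_III, -1e6) # full minimum block
})
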