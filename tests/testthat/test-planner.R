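small_problem <- function(...) {
  plan_problem(params, demand = c(paediatrics = 60, obstetrics = 40),
               n_hospitals = 2, ...)
}

test_that("solver and exhaustive oracle agree on small instances", {
  for (args in list(list(),
                    list(open_wards_per_drg = 1),
                    list(n_open_hospitals = 2,
                         wards_follow_hospital = TRUE))) {
    pr <- do.call(small_problem, args)
    solved <- plan_region(pr)
    enum <- enumerate_plans(pr, case_step = 1)
    expect_equal(solved$objective, enum$objective, tolerance = 1e-9,
                 info = paste(names(args), collapse = "+"))
  }
})

test_that("the oracle refuses oversized grids and honours case_step", {
  pr <- plan_problem(params, demand = c(paediatrics = 3373,
                                        obstetrics = 1437),
                     n_hospitals = 3)
  expect_error(enumerate_plans(pr, case_step = 1, max_cells = 2e4),
               "too large")
  pr4 <- plan_problem(params, demand = c(paediatrics = 10, obstetrics = 10),
                      n_hospitals = 4)
  expect_error(enumerate_plans(pr4), "too large")
  # coarse grid is a lower bound on the optimum
  pr2 <- small_problem()
  coarse <- enumerate_plans(pr2, case_step = 20)
  expect_lte(coarse$objective, plan_region(pr2)$objective + 1e-9)
})

test_that("solutions satisfy the linking and coverage constraints", {
  for (pr in list(small_problem(),
                  small_problem(open_wards_per_drg = 1),
                  plan_problem(params,
                               demand = c(paediatrics = 500,
                                          obstetrics = 200),
                               n_hospitals = 3))) {
    sol <- plan_region(pr)
    expect_true(all(sol$x <= pr$big_M * sol$beta))          # II
    expect_true(all(colSums(sol$x) <=
                      pr$big_M * sol$hospital_open))        # III/IV
    expect_equal(rowSums(sol$x), pr$demand)                 # V
    expect_equal(sol$objective, sol$total$profit)
  }
})

test_that("removing a scenario constraint never lowers the optimum", {
  free <- plan_region(small_problem())$objective
  one <- plan_region(small_problem(open_wards_per_drg = 1))$objective
  two_full <- plan_region(small_problem(
    n_open_hospitals = 2, wards_follow_hospital = TRUE))$objective
  expect_gte(free + 1e-9, one)
  expect_gte(free + 1e-9, two_full)
})

test_that("zero demand opens nothing, even with doubled fixed blocks", {
  pr <- plan_problem(params, demand = c(paediatrics = 0, obstetrics = 0),
                     n_hospitals = 2)
  sol <- plan_region(pr)
  expect_equal(sol$objective, 0)
  expect_true(all(sol$beta == 0))
  heavy <- default_parameters(department_fixed_paed = 2 * 576500,
                              department_fixed_obs = 2 * 679000)
  pr2 <- plan_problem(heavy, demand = c(paediatrics = 0, obstetrics = 0),
                      n_hospitals = 2)
  expect_equal(plan_region(pr2)$objective, 0)
})

test_that("infeasible scenarios fail with the violated constraint named", {
  expect_error(plan_region(small_problem(open_wards_per_drg = 0)),
               "infeasible scenario")
  expect_error(
    plan_problem(params, demand = c(paediatrics = 10, obstetrics = 5),
                 n_hospitals = 2,
                 fixed_cases = rbind(c(4, 4), c(5, 0))),
    "constraint V")
  expect_error(
    plan_problem(params, demand = c(paediatrics = 10, obstetrics = 5),
                 big_M = 10),
    "big_M")
})

test_that("symmetric optima resolve to the lowest hospital index", {
  sol <- plan_region(plan_problem(
    params, demand = c(paediatrics = 3373, obstetrics = 1437),
    n_hospitals = 3, n_open_hospitals = 1, open_wards_per_drg = 1,
    wards_follow_hospital = TRUE))
  expect_equal(unname(sol$hospital_open), c(1L, 0L, 0L))
  expect_equal(unname(sol$x[, 1]), unname(sol$problem$demand))
})

test_that("a fixed allocation is priced as given", {
  sol <- plan_region(plan_problem(
    params, demand = study$demand, n_hospitals = 3,
    hospital_names = study$hospitals,
    fixed_cases = study$hospital_cases, fixed_beds = study$beds))
  expect_equal(sol$x, study$hospital_cases + 0)
  expect_equal(sol$beds["paediatrics", "Wolgast"], 18L,
               ignore_attr = TRUE)
  expect_lt(abs(sol$objective - (-4449210)), 15)
})
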