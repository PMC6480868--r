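test_that("municipalities go to the nearest open hospital, ties to lower id", {
  m <- toy_minutes()
  a <- assign_catchments(m)
  expect_equal(unname(a$nearest), c("h1", "h2", "h1"))
  expect_equal(unname(a$minutes_to_nearest), c(10, 5, 20))
  # with h1 closed everything moves to h2
  a2 <- assign_catchments(m, "h2")
  expect_true(all(a2$nearest == "h2"))
  expect_error(assign_catchments(m, character(0)), "at least one")
  expect_error(assign_catchments(m, "h9"), "unknown")
})

test_that("catchment case totals conserve the regional totals", {
  m <- toy_minutes()
  cases <- cbind(paed = c(5, 7, 11), obst = c(2, 3, 4))
  rownames(cases) <- rownames(m)
  for (open in list("h1", "h2", c("h1", "h2"))) {
    a <- assign_catchments(m, open, cases = cases)
    expect_equal(colSums(a$catchment_cases), colSums(cases),
                 info = paste(open, collapse = "+"))
  }
  # single open hospital captures everything
  a1 <- assign_catchments(m, "h1", cases = cases)
  expect_equal(a1$catchment_cases["h1", ], colSums(cases))
})

test_that("closing a hospital never shortens any travel time", {
  reg <- simulate_region(region_recipe(seed = 7))
  m <- reg$minutes
  full <- assign_catchments(m)$minutes_to_nearest
  for (drop in colnames(m)) {
    closed <- assign_catchments(m, setdiff(colnames(m), drop))
    expect_true(all(closed$minutes_to_nearest >= full - 1e-12))
    for (thr in c(10, 20, 40)) {
      s_full <- population_share_beyond(m, colnames(m), thr,
                                        reg$municipalities$pop_children)
      s_closed <- population_share_beyond(m, setdiff(colnames(m), drop),
                                          thr,
                                          reg$municipalities$pop_children)
      expect_gte(s_closed$share + 1e-12, s_full$share)
    }
  }
})

test_that("shares beyond a threshold hit both trivial extremes", {
  m <- toy_minutes()
  pop <- c(100, 200, 300)
  far <- population_share_beyond(m, colnames(m), 1e6, pop)
  expect_equal(far$share, 0)
  expect_equal(far$count, 0)
  near <- population_share_beyond(m, colnames(m), 1e-9, pop)
  expect_equal(near$share, 1) # all times strictly positive
  expect_error(population_share_beyond(m, colnames(m), 0, pop), "> 0")
  expect_error(population_share_beyond(m, colnames(m), 10, pop[1:2]),
               "municipality")
})

test_that("band tables partition the population", {
  reg <- simulate_region(region_recipe(seed = 3))
  tab <- travel_band_table(reg$minutes, colnames(reg$minutes),
                           reg$municipalities[, c("pop_children",
                                                  "pop_women")])
  expect_equal(sum(tab$pop_children),
               sum(reg$municipalities$pop_children))
  expect_equal(sum(tab$pop_women_share), 1)
  expect_equal(nrow(tab), 4)
})
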