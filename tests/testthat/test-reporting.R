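test_that("the study scenarios reproduce the published grand totals", {
  r_fixed <- run_scenario(scenario_config("three-fixed-beds"))
  expect_lt(abs(r_fixed$objective - (-4449210)), 15)
  r_opt <- run_scenario(scenario_config("three-optimized-beds"))
  expect_lt(abs(r_opt$objective - (-3617868)), 15)
  # per-ward column totals are internally consistent with the cells
  expect_equal(sum(r_opt$table$contribution), r_opt$objective)
  expect_equal(unname(r_opt$ward_totals["paediatrics"]),
               sum(r_opt$table$contribution[
                 r_opt$table$ward == "paediatrics"]))
})

test_that("an empty-demand scenario yields a zero report", {
  cfg <- scenario_config("one-hospital")
  cfg$scenario$preset <- "custom"
  cfg$demand$totals <- c(0, 0)
  rep <- run_scenario(cfg)
  expect_equal(rep$objective, 0)
  expect_true(all(rep$table$contribution == 0))
  expect_true(all(rep$table$beds == 0))
})

test_that("report files are bit-stable across reruns", {
  rep <- run_scenario(scenario_config("three-fixed-beds"))
  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep, d1, params = params)
  write_report(run_scenario(scenario_config("three-fixed-beds")), d2,
               params = params)
  for (f in c("report_table.csv", "solution.txt", "run_log.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  tab <- utils::read.csv(file.path(d1, "report_table.csv"))
  grand <- tab$contribution[tab$hospital == "Total" & tab$ward == "all"]
  expect_equal(grand, rep$objective, tolerance = 1e-6)
})

test_that("configurations load from YAML and invalid ones are refused", {
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(scenario_config("one-hospital"), cfg_path)
  rep <- run_scenario(cfg_path)
  expect_lt(abs(rep$objective - 2087597), 5)
  expect_error(run_scenario(list(demand = list())), "scenario")
  bad <- scenario_config("one-hospital")
  bad$demand$source <- "oracle-of-delphi"
  expect_error(run_scenario(bad), "unknown demand source")
})

test_that("synthetic-demand runs carry accessibility bands", {
  cfg <- scenario_config("one-hospital", seed = 4)
  cfg$demand$source <- "synthetic"
  rep <- run_scenario(cfg)
  expect_false(is.null(rep$bands))
  expect_equal(nrow(rep$bands), 4)
  expect_equal(sum(rep$bands$pop_children_share), 1)
})

test_that("scenario comparison reports objective differences", {
  r1 <- run_scenario(scenario_config("one-hospital"))
  r3 <- run_scenario(scenario_config("three-fixed-beds"))
  cmp <- compare_scenarios(list(r1, r3))
  diffs <- attr(cmp, "objective_diff")
  expect_equal(diffs[1], 0)
  expect_lt(abs(diffs[2] - (r3$objective - r1$objective)), 1e-6)
  expect_gt(r1$objective, r3$objective) # concentration dominates
  same <- compare_scenarios(list(r1, r1))
  expect_equal(attr(same, "objective_diff"), c(0, 0))
  expect_error(compare_scenarios(list(r1)), "at least two")
})
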