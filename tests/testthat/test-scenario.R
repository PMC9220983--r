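test_that("a tumor-free cohort yields only false positives", {
  cohort <- manual_cohort(data.frame(has_tumor = rep(FALSE, 400),
                                     age_other_cause_death = 90))
  ctrl <- natural_course(cohort)
  r <- run_scenario(comparator_spec(), cohort, ctrl)
  expect_equal(unlist(unclass(r$counts)), c(invasive_screen = 0,
                                            invasive_interval = 0,
                                            dcis_screen = 0,
                                            dcis_interval = 0))
  expect_equal(r$summary$false_positives_per_1000, 13 * (1 - 0.88) * 1000)
  expect_equal(r$summary$overdiagnoses_per_1000, 0)
})

test_that("rerunning a scenario with the same seeds is bit-identical", {
  sim <- shared_sim()
  spec <- scenario_spec("lb", test_characteristics(0.91, 1.15, 0.96))
  a <- run_scenario(spec, sim$cohort, sim$control)
  b <- run_scenario(spec, sim$cohort, sim$control)
  expect_identical(as.data.frame(a$screened$women),
                   as.data.frame(b$screened$women))
  expect_identical(a$summary$qalys_gained_per_1000,
                   b$summary$qalys_gained_per_1000)
  expect_identical(a$cost$total, b$cost$total)
})

test_that("a scenario with the comparator's characteristics is equivalent to it", {
  sim <- shared_sim()
  clone <- scenario_spec("clone",
                         test_characteristics(0.91, 1.21, 0.88, price = 149))
  res <- run_grid(list(comparator_spec(), clone), sim$cohort,
                  control = sim$control)
  expect_equal(res$icer_status[2], "equivalent")
  expect_equal(res$max_price_usd[2], 149)
  expect_equal(res$combined_pct[1], res$combined_pct[2])
})

test_that("grid configuration errors are caught", {
  sim <- shared_sim()
  comp <- comparator_spec()
  lb <- scenario_spec("lb", test_characteristics(0, 1.21, 0.96))
  expect_error(run_grid(list(comp, comp), sim$cohort, control = sim$control),
               "duplicate")
  expect_error(run_grid(list(lb), sim$cohort, control = sim$control),
               "comparator")
  # a comparator-only grid is fine
  res <- run_grid(list(comp), sim$cohort, control = sim$control)
  expect_equal(nrow(res), 1L)
})

test_that("the default grid enumerates the documented level sets", {
  grid <- default_scenario_grid()
  expect_length(grid, 1 + 2 * 9 * 3)
  expect_equal(sum(vapply(grid, `[[`, NA, "is_comparator")), 1L)
  sizes <- sort(unique(vapply(grid[-1], function(s)
    s$test$median_detect_size, 0)))
  expect_equal(sizes, sort(c(seq(1.03, 1.39, by = 0.06), 0.61, 0.01)))
})

test_that("only scenarios matching the comparator's QALYs carry a maximum price", {
  sim <- shared_sim()
  specs <- list(comparator_spec(),
                scenario_spec("worse", test_characteristics(0, 1.39, 0.88)),
                scenario_spec("better", test_characteristics(0.91, 1.03, 1.0)))
  res <- run_grid(specs, sim$cohort, control = sim$control)
  has_price <- !is.na(res$max_price_usd) & !res$is_comparator
  expect_true(all(res$delta_qalys_vs_comparator_per_1000[has_price] >= 0))
  expect_true(all(res$delta_qalys_vs_comparator_per_1000[
    !has_price & !res$is_comparator] < 0))
})

test_that("ROC overlay points encode test characteristics and the mortality flag", {
  sim <- shared_sim()
  specs <- list(comparator_spec(),
                scenario_spec("perfect spec", test_characteristics(0.91, 1.21, 1.0)),
                scenario_spec("small tumors", test_characteristics(0.91, 1.03, 0.88)))
  res <- run_grid(specs, sim$cohort, control = sim$control)
  roc <- export_roc_points(res)
  expect_equal(roc$fpr[res$label == "perfect spec"], 0)
  expect_equal(roc$fpr[res$is_comparator], 0.12)
  expect_equal(roc$tpr, res$combined_pct / 100)
  comp_mort <- res$mortality_reduction_pct[res$is_comparator]
  expect_equal(roc$filled, res$mortality_reduction_pct >= comp_mort)
})

test_that("results tables export with stable column sets", {
  sim <- shared_sim()
  res <- run_grid(list(comparator_spec(),
                       scenario_spec("lb", test_characteristics(0, 1.21, 1.0))),
                  sim$cohort, control = sim$control, keep_details = TRUE)
  out1 <- tempfile(fileext = ".csv")
  write_outcome_table(res, out1)
  expect_equal(names(utils::read.csv(out1)),
               c("label", "combined_pct", "specificity_pct",
                 "mortality_reduction_pct", "false_positives_per_1000",
                 "overdiagnoses_per_1000", "qalys_gained_per_1000",
                 "total_cost_ref_usd1000", "max_price_usd"))
  out2 <- tempfile(fileext = ".csv")
  write_sensitivity_table(res, out2)
  tab <- utils::read.csv(out2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$combined_pct, res$combined_pct)
  expect_equal(tab$dcis_pct, res$dcis_pct)
  expect_true(all(tab$invasive_screen + tab$invasive_interval +
                    tab$dcis_screen + tab$dcis_interval > 0))
})

test_that("scenario grids round-trip through YAML configuration", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    policy = list(start_age = 45, stop_age = 54, interval = 1),
    scenarios = list(
      list(label = "dm", dcis_sensitivity = 0.91, median_detect_size = 1.21,
           specificity = 0.88, price = 149, comparator = TRUE),
      list(label = "lb", dcis_sensitivity = 0, median_detect_size = 1.09,
           specificity = 0.96))), path)
  specs <- read_scenario_config(path)
  expect_length(specs, 2)
  expect_true(specs[[1]]$is_comparator)
  expect_equal(scheduled_ages(specs[[2]]$policy), 45:54)
  expect_equal(specs[[2]]$test$median_detect_size, 1.09)
  expect_true(is.na(specs[[2]]$test$price))
})
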