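test_that("scheduled ages enumerate the policy", {
  expect_equal(scheduled_ages(screening_policy()), seq(50, 74, 2))
  expect_length(scheduled_ages(screening_policy()), 13)
  expect_equal(scheduled_ages(screening_policy(50, 50, 2)), 50)
  expect_length(scheduled_ages(screening_policy(45, 54, 1)), 10)
})

test_that("an undetecting, perfectly specific test reproduces the control universe exactly", {
  sim <- shared_sim()
  sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                        null_test())
  w <- sc$women
  ctrl <- sim$control
  for (col in c("dx_age", "dx_mode", "dx_diameter", "stage", "bc_death_age",
                "death_age", "death_cause")) {
    expect_identical(w[[col]], ctrl[[col]], label = col)
  }
  expect_equal(false_positive_count(sc), 0)
})

test_that("false positives are affine in 1 - specificity with slope equal to negative screens", {
  sim <- shared_sim()
  run_fp <- function(spec) {
    sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                          test_characteristics(0.91, 1.21, spec))
    c(fp = false_positive_count(sc), neg = sum(sc$rounds$n_negative))
  }
  a <- run_fp(1.0); b <- run_fp(0.96); d <- run_fp(0.88)
  expect_equal(a[["fp"]], 0)
  # negative-screen counts are identical across specificities (no behaviour
  # change after a false positive), so the slope is the negative-screen count
  expect_equal(a[["neg"]], b[["neg"]])
  expect_equal(b[["fp"]], 0.04 * b[["neg"]])
  expect_equal(d[["fp"]], 0.12 * d[["neg"]])
})

test_that("screens never happen after death and stop at diagnosis", {
  cohort <- manual_cohort(data.frame(has_tumor = FALSE,
                                     age_other_cause_death = c(51, 49.5, 90)))
  sc <- apply_screening(cohort, natural_course(cohort), screening_policy(),
                        test_characteristics(0.91, 1.21, 0.88))
  expect_equal(sc$women$n_screens, c(1L, 0L, 13L))
  # a screen-detected woman exits the schedule at diagnosis
  sim <- shared_sim()
  sc2 <- apply_screening(sim$cohort, sim$control, screening_policy(),
                         test_characteristics(0.91, 1.21, 0.88))
  w <- sc2$women
  det <- w$dx_mode %in% c("screen_invasive", "screen_dcis")
  rounds_by_age <- function(a) findInterval(a, seq(50, 74, 2))
  expect_true(all(w$n_screens[det] <= rounds_by_age(w$dx_age[det])))
})

test_that("detection counts partition diagnosed cancers and ignore specificity", {
  sim <- shared_sim()
  run_counts <- function(spec) {
    classify_cancers(apply_screening(sim$cohort, sim$control,
                                     screening_policy(),
                                     test_characteristics(0.91, 1.21, spec)))
  }
  c88 <- run_counts(0.88)
  c100 <- run_counts(1.0)
  expect_identical(unclass(c88), unclass(c100))
  sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                        test_characteristics(0.91, 1.21, 0.88))
  w <- sc$women
  in_window <- !is.na(w$dx_age) & w$dx_age >= 50 & w$dx_age < 75
  expect_equal(c88$invasive_screen + c88$invasive_interval +
                 c88$dcis_screen + c88$dcis_interval, sum(in_window))
  # a tumor-free cohort counts nothing
  empty <- manual_cohort(data.frame(has_tumor = rep(FALSE, 5)))
  c0 <- classify_cancers(apply_screening(empty, natural_course(empty),
                                         screening_policy(),
                                         test_characteristics(0.91, 1.21, 0.88)))
  expect_equal(unlist(unclass(c0)), c(invasive_screen = 0,
                                      invasive_interval = 0,
                                      dcis_screen = 0, dcis_interval = 0))
})

test_that("sensitivity conversion reproduces printed integer percentages", {
  expect_equal(unname(compute_sensitivities(list(
    invasive_screen = 499859, invasive_interval = 280403,
    dcis_screen = 211799, dcis_interval = 25736))), c(89, 64, 70))
  expect_equal(unname(compute_sensitivities(list(
    invasive_screen = 575168, invasive_interval = 247101,
    dcis_screen = 0, dcis_interval = 30604))), c(0, 70, 67))
  expect_equal(unname(compute_sensitivities(list(
    invasive_screen = 7, invasive_interval = 0,
    dcis_screen = 3, dcis_interval = 0))), c(100, 100, 100))
  expect_error(compute_sensitivities(list(
    invasive_screen = 0, invasive_interval = 0,
    dcis_screen = 0, dcis_interval = 0)), "undefined")
})

test_that("combined sensitivity is monotone in median size and DCIS sensitivity", {
  sim <- shared_sim()
  comb <- function(dcis, size) {
    sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                          test_characteristics(dcis, size, 1.0))
    unname(compute_sensitivities(classify_cancers(sc))["combined"])
  }
  by_size <- vapply(c(0.61, 1.03, 1.21, 1.39), function(s) comb(0.91, s), 0)
  expect_true(all(diff(by_size) <= 0))
  by_dcis <- vapply(c(0, 0.5, 0.91), function(d) comb(d, 1.21), 0)
  expect_true(all(diff(by_dcis) >= 0))
})

test_that("screening never makes a woman worse off than her unscreened self", {
  sim <- shared_sim()
  for (test in list(test_characteristics(0.91, 1.21, 0.88),
                    test_characteristics(0, 0.61, 0.96))) {
    sc <- apply_screening(sim$cohort, sim$control, screening_policy(), test)
    expect_true(all(sc$women$death_age >= sim$control$death_age))
  }
})

test_that("mismatched cohort/control pairs are rejected", {
  sim <- shared_sim()
  other <- sample_life_histories(100, natural_history_params(), seed = 2)
  expect_error(apply_screening(other, sim$control, screening_policy(),
                               null_test()),
               "contract violation")
})
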