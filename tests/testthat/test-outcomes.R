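# independent numeric oracle for present values accrued over an interval
pv_interval <- function(from, to, rate, ref = 30) {
  if (to <= from) return(0)
  stats::integrate(function(t) (1 + rate)^-(t - ref), from, to,
                   rel.tol = 1e-12)$value
}

test_that("one attended screen costs (1 - 0.994) of one week, undiscounted", {
  cohort <- manual_cohort(data.frame(has_tumor = FALSE,
                                     age_other_cause_death = 80))
  sc <- apply_screening(cohort, natural_course(cohort),
                        screening_policy(50, 50, 2),
                        test_characteristics(0.91, 1.21, 1.0))
  q <- compute_qalys(sc, utility_table(), discount_rate = 0)
  expect_equal(unname(q$decrements["screening"]), 0.006 / 52)
  expect_equal(sum(sc$rounds$n_screens), 1)
})

test_that("a hand-integrated event ledger matches the pipeline", {
  # one woman: clinical local-stage diagnosis at 40, BC death at 42.5
  ledger <- data.table::data.table(
    woman_id = 1L, dx_age = 40, dx_mode = "clinical_invasive",
    dx_diameter = 1.5, stage = "local", bc_death_age = 42.5,
    death_age = 42.5, death_cause = "breast_cancer")
  u <- utility_table()
  q <- compute_qalys(ledger, u, discount_rate = 0.03, reference_age = 30)
  ly <- pv_interval(30, 42.5, 0.03)
  workup <- (1 - 0.895) * (5 / 52) / 1.03^10
  care <- (1 - 0.90) * pv_interval(40, 41, 0.03) +
    (1 - 0.93) * pv_interval(41, 41.5, 0.03) +
    (1 - 0.49) * pv_interval(41.5, 42.5, 0.03)
  expect_equal(q$life_years, ly, tolerance = 1e-9)
  expect_equal(unname(q$decrements["clinical_detection"]), workup,
               tolerance = 1e-12)
  expect_equal(unname(q$decrements["bc_care"]), care, tolerance = 1e-9)
  expect_equal(q$qalys, ly - workup - care, tolerance = 1e-9)
  # the terminal year of a breast-cancer death is lived at utility 0.49
  # regardless of stage; an other-cause decedent uses the stage's
  # terminal-OCD utility instead
  ledger2 <- data.table::copy(ledger)[, `:=`(stage = "distant",
                                             death_cause = "other",
                                             bc_death_age = NA_real_)]
  q2 <- compute_qalys(ledger2, u, discount_rate = 0)
  expect_equal(unname(q2$decrements["bc_care"]),
               (1 - 0.60) * 1 + (1 - 0.62) * 0.5 + (1 - 0.62) * 1)
})

test_that("QALY decrements are additive and discounting at zero recovers raw sums", {
  sim <- shared_sim()
  sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                        test_characteristics(0.91, 1.21, 0.88))
  q <- compute_qalys(sc, utility_table(), discount_rate = 0.03)
  expect_equal(q$qalys, q$life_years - sum(q$decrements))
  q0 <- compute_qalys(sc, utility_table(), discount_rate = 0)
  expect_equal(q0$life_years,
               sum(pmax(sc$women$death_age, 30) - 30))
})

test_that("care phases partition diagnosis-to-death for every diagnosed woman", {
  sim <- shared_sim()
  sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                        test_characteristics(0.91, 1.21, 0.88))
  # with every phase utility at 0.5 the care decrement is half the
  # diagnosis-to-death time, so additivity of the three phases is exposed
  u_half <- utility_table(phase_utilities = matrix(
    0.5, 4, 4, dimnames = dimnames(utility_table()$phase_utilities)))
  q <- compute_qalys(sc, u_half, discount_rate = 0)
  w <- sc$women[!is.na(sc$women$dx_age), ]
  expect_equal(unname(q$decrements["bc_care"]),
               0.5 * sum(pmax(w$death_age, 30) - pmax(w$dx_age, 30)))
})

test_that("QALYs gained are non-decreasing in specificity", {
  sim <- shared_sim()
  qg <- vapply(c(0.88, 0.96, 1.0), function(spec) {
    sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                          test_characteristics(0.91, 1.21, spec))
    summarize_outcomes(sc, sim$control)$qalys_gained_per_1000
  }, 0)
  expect_true(all(diff(qg) > 0))
})

test_that("overdiagnoses are screened-universe diagnoses that could never have helped", {
  sim <- shared_sim()
  sc_null <- apply_screening(sim$cohort, sim$control, screening_policy(),
                             null_test())
  expect_equal(as.numeric(count_overdiagnoses(sc_null, sim$control)), 0)

  # constructed trio: a screen-detected regressing DCIS is the only
  # overdiagnosis; an interval cancer and a healthy woman are not
  trio <- manual_cohort(data.frame(
    has_tumor = c(TRUE, TRUE, FALSE),
    starts_as_dcis = c(TRUE, FALSE, NA),
    dcis_fate = c("regress", NA, NA),
    onset_age = c(49, 45, NA), dcis_dwell = c(10, NA, NA),
    growth_rate = c(NA, 0.5, NA),
    d_clinical = c(NA, 2, NA), d_fatal = c(NA, 10, NA),
    u_detect = c(0.5, 0.999999, 0.5), u_dcis_detect = c(0.01, 0.5, 0.5),
    age_other_cause_death = c(85, 85, 85)))
  ctrl <- natural_course(trio)
  sc <- apply_screening(trio, ctrl, screening_policy(),
                        test_characteristics(0.91, 1.21, 0.88))
  expect_equal(sc$women$dx_mode, c("screen_dcis", "clinical_invasive", "none"))
  expect_equal(attr(count_overdiagnoses(sc, ctrl), "count"), 1L)
})

test_that("mortality reduction is arithmetic on breast-cancer death counts", {
  expect_equal(mortality_reduction(750, 1000), 25.0)
  expect_equal(mortality_reduction(10, 10), 0)
  expect_error(mortality_reduction(5, 0), "undefined")
  sim <- shared_sim()
  sc <- apply_screening(sim$cohort, sim$control, screening_policy(),
                        test_characteristics(0.91, 0.61, 0.88))
  # independent recount from the per-woman ledger
  recount_s <- sum(table(sc$women$death_cause)["breast_cancer"])
  recount_c <- sum(table(sim$control$death_cause)["breast_cancer"])
  expect_equal(bc_deaths(sc), recount_s)
  expect_equal(mortality_reduction(sc, sim$control),
               round(100 * (1 - recount_s / recount_c), 1))
})

test_that("the packaged utility fixture reproduces the in-code table", {
  path <- system.file("extdata", "utility_table.csv", package = "screensim")
  expect_equal(read_utility_table(path), utility_table())
  expect_error(utility_table(screening_utility = 1.2), "utilities")
})
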