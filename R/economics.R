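#' Cost table: screening, workup, and care costs in 2020 USD
#'
#' Defaults: USD 149 per comparator (digital mammography) screen; a
#' false-positive workup costs USD 152 of follow-up imaging for every woman
#' plus a tissue biopsy (USD 1455 / 1463 / 1550 by age group 50-64 / 65-74 /
#' 75-100) in 10.6% of them, applied in expectation; true-positive
#' diagnostics cost USD 2316 / 2329 / 1964 by the same age groups; care costs
#' are per stage and phase of care, with the continuous phase accrued per
#' year and the initial / terminal / terminal-OCD phases accrued over their
#' (up to) 12-month windows. Diagnoses before age 50 use the youngest age
#' band.
#'
#' @param screen_cost_comparator USD per comparator screen.
#' @param fp_imaging USD follow-up imaging per false positive.
#' @param fp_biopsy USD tissue biopsy by age band (length 3).
#' @param fp_biopsy_fraction Fraction of false positives biopsied.
#' @param tp_diagnostics USD diagnostic workup per detected cancer, by age
#'   band (length 3).
#' @param age_breaks Lower bounds of the second and third age bands.
#' @param care_costs 4x4 matrix (stages x phases) of care costs, USD; the
#'   `continuous` column is per year, the others per phase.
#' @return A `cost_table` object.
#' @export
#' @examples
#' cost_table()$care_costs
cost_table <- function(screen_cost_comparator = 149,
                       fp_imaging = 152,
                       fp_biopsy = c(1455, 1463, 1550),
                       fp_biopsy_fraction = 0.106,
                       tp_diagnostics = c(2316, 2329, 1964),
                       age_breaks = c(65, 75),
                       care_costs = default_care_costs()) {
  stages <- c("in_situ", "local", "regional", "distant")
  phases <- c("initial", "continuous", "terminal", "terminal_ocd")
  if (!is.matrix(care_costs) || !identical(rownames(care_costs), stages) ||
      !identical(colnames(care_costs), phases))
    stop("care_costs must be a 4x4 matrix with stages as rows and phases ",
         "as columns", call. = FALSE)
  if (any(c(screen_cost_comparator, fp_imaging, fp_biopsy, tp_diagnostics,
            care_costs) < 0))
    stop("costs must be non-negative", call. = FALSE)
  if (length(fp_biopsy) != 3L || length(tp_diagnostics) != 3L)
    stop("fp_biopsy and tp_diagnostics need one value per age band",
         call. = FALSE)
  structure(list(screen_cost_comparator = screen_cost_comparator,
                 fp_imaging = fp_imaging, fp_biopsy = fp_biopsy,
                 fp_biopsy_fraction = fp_biopsy_fraction,
                 tp_diagnostics = tp_diagnostics, age_breaks = age_breaks,
                 care_costs = care_costs),
            class = "cost_table")
}

default_care_costs <- function() {
  matrix(c(14848, 1336, 56995, 7879,
           24240, 2306, 59550, 6332,
           41352, 4474, 64516, 10762,
           55985, 19212, 81656, 20081),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("in_situ", "local", "regional", "distant"),
                         c("initial", "continuous", "terminal",
                           "terminal_ocd")))
}

#' Read a cost table from CSV
#'
#' Long format with columns `item`, `group` (age band or `stage:phase`),
#' `value`; see the packaged fixture
#' `system.file("extdata", "cost_table.csv", package = "screensim")`.
#'
#' @param path CSV path.
#' @return A [cost_table()] object.
#' @export
read_cost_table <- function(path) {
  x <- utils::read.csv(path)
  pick <- function(item) x$value[x$item == item]
  care <- x[x$item == "care", ]
  cc <- default_care_costs()
  sp <- do.call(rbind, strsplit(care$group, ":", fixed = TRUE))
  cc[sp] <- care$value
  cost_table(screen_cost_comparator = pick("screen_comparator"),
             fp_imaging = pick("fp_imaging"),
             fp_biopsy = pick("fp_biopsy"),
             fp_biopsy_fraction = pick("fp_biopsy_fraction"),
             tp_diagnostics = pick("tp_diagnostics"),
             care_costs = cc)
}

#' Discount a cost or effect to the reference age
#'
#' `amount / (1 + rate)^(event_age - reference_age)`. Events before the
#' reference age are a domain error here (the simulation pipeline clamps
#' instead; see the methods vignette).
#'
#' @param amount Value at the event age.
#' @param event_age Age of the event (years, `>= reference_age`).
#' @param rate Annual discount rate.
#' @param reference_age Anchor age.
#' @return Present value at the reference age.
#' @export
#' @examples
#' discount_amount(100, 40, 0.03, 30)  # 100 / 1.03^10
discount_amount <- function(amount, event_age, rate, reference_age = 30) {
  if (any(event_age < reference_age))
    stop("event precedes the discounting reference age", call. = FALSE)
  amount / (1 + rate)^(event_age - reference_age)
}

age_band <- function(age, breaks) {
  findInterval(age, breaks) + 1L
}

#' Total discounted cost of a universe
#'
#' Sums discounted screening costs (screens times per-test price),
#' false-positive workup costs (imaging for every expected false positive
#' plus biopsy for the biopsied fraction), diagnostic workup at every
#' detection (split into screen-detected and clinically detected
#' components), and stage/phase care costs over the care-phase windows used
#' by [compute_qalys()].
#'
#' @param outcomes A [natural_course()] table or [apply_screening()] result.
#' @param costs A [cost_table()].
#' @param price Per-test price in USD; defaults to the test's own price, or
#'   to the comparator screen cost for a test without one. Ignored for the
#'   no-screening universe.
#' @param discount_rate,reference_age Discounting parameters.
#' @return A `cost_summary`: list with `total`, `components` (named:
#'   `screening`, `tp_followup`, `fp`, `clinical_detection`, `bc_care`),
#'   `disc_screens` (discounted screen count, the exact slope of total cost
#'   in the per-test price), `price`, and `n`.
#' @export
total_cost <- function(outcomes, costs = cost_table(), price = NULL,
                       discount_rate = 0.03, reference_age = 30) {
  screened <- inherits(outcomes, "screened_outcomes")
  w <- if (screened) outcomes$women else outcomes
  n <- if (screened) attr(outcomes, "n") else attr(outcomes, "n") %||% nrow(w)
  vf <- function(a) discount_factor(a, discount_rate, reference_age)

  cost_screening <- 0
  cost_fp <- 0
  disc_screens <- 0
  if (screened) {
    test <- attr(outcomes, "test")
    if (is.null(price)) price <- test$price
    if (is.null(price) || is.na(price)) price <- costs$screen_cost_comparator
    r <- outcomes$rounds
    disc_screens <- sum(r$n_screens * vf(r$age))
    cost_screening <- price * disc_screens
    fp_unit <- costs$fp_imaging +
      costs$fp_biopsy_fraction * costs$fp_biopsy[age_band(r$age,
                                                          costs$age_breaks)]
    cost_fp <- (1 - test$specificity) * sum(r$n_negative * vf(r$age) * fp_unit)
  } else {
    price <- 0
  }

  dx <- !is.na(w$dx_age)
  screen_dx <- dx & w$dx_mode %in% c("screen_invasive", "screen_dcis")
  clin_dx <- dx & w$dx_mode %in% c("clinical_invasive", "clinical_dcis")
  diag_cost <- function(sel) {
    a <- w$dx_age[sel]
    sum(vf(a) * costs$tp_diagnostics[age_band(a, costs$age_breaks)])
  }
  cost_tp <- diag_cost(screen_dx)
  cost_clin <- diag_cost(clin_dx)

  cost_care <- 0
  if (any(dx)) {
    cc <- costs$care_costs
    dxa <- w$dx_age[dx]
    D <- w$death_age[dx]
    st <- w$stage[dx]
    bc <- w$death_cause[dx] == "breast_cancer"
    ph <- care_phases(dxa, D)
    dy <- function(a, b) discounted_years(a, b, discount_rate, reference_age)
    term_cost <- ifelse(bc, cc[st, "terminal"], cc[st, "terminal_ocd"])
    # initial / terminal costs accrue over their (up to 1-year) windows and
    # are pro-rated when the window is truncated by death.
    cost_care <- sum(cc[st, "initial"] * dy(ph$dx, ph$initial_end) +
                       cc[st, "continuous"] * dy(ph$initial_end,
                                                 ph$terminal_start) +
                       term_cost * dy(ph$terminal_start, ph$death))
  }

  components <- c(screening = cost_screening, tp_followup = cost_tp,
                  fp = cost_fp, clinical_detection = cost_clin,
                  bc_care = cost_care)
  structure(list(total = sum(components), components = components,
                 disc_screens = disc_screens, price = price, n = n),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("<cost_summary> n = %d | total USD %.0f (test price %.0f)\n",
              x$n, x$total, x$price))
  cat("  components:", paste(sprintf("%s %.0f", names(x$components),
                                     x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Incremental cost-effectiveness ratio against a comparator
#'
#' `(scenario cost - comparator cost) / (scenario QALYs - comparator QALYs)`
#' on a common cohort and denominator. Dominance is flagged instead of
#' divided: a scenario that saves money without losing QALYs is `dominant`, a
#' scenario that costs more without gaining QALYs is `dominated`, identical
#' arms are `equivalent`; otherwise `status` is `icer` and the ratio is
#' reported (negative ratios — cheaper but less effective — are reported
#' with status `tradeoff`).
#'
#' @param scenario_cost,scenario_qalys,comparator_cost,comparator_qalys
#'   Discounted totals per the same denominator.
#' @return An `icer_result`: `delta_cost`, `delta_qalys`, `icer` (`NA` when
#'   flagged), `status`.
#' @export
#' @examples
#' icer(150000 + 7e6, 3 + 40, 7e6, 40)  # USD 50,000 per QALY
icer <- function(scenario_cost, scenario_qalys,
                 comparator_cost, comparator_qalys) {
  dc <- scenario_cost - comparator_cost
  dq <- scenario_qalys - comparator_qalys
  if (dq == 0 && dc == 0) {
    status <- "equivalent"; val <- NA_real_
  } else if (dq >= 0 && dc <= 0) {
    status <- "dominant"; val <- NA_real_
  } else if (dq <= 0 && dc >= 0) {
    status <- "dominated"; val <- NA_real_
  } else if (dq > 0) {
    status <- "icer"; val <- dc / dq
  } else {
    status <- "tradeoff"; val <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qalys = dq, icer = val,
                 status = status), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dC %.0f, dQ %.3f: %s", x$delta_cost,
              x$delta_qalys, x$status))
  if (!is.na(x$icer)) cat(sprintf(" (%.0f USD/QALY)", x$icer))
  cat("\n")
  invisible(x)
}

#' Maximum per-test price at a cost-effectiveness threshold
#'
#' Total cost is exactly affine in the per-test price with slope equal to the
#' discounted screen count, so the price at which the scenario's ICER against
#' the comparator equals the threshold has the closed form
#' `P* = P_ref + (threshold * dQ - dC(P_ref)) / S`, where `dC(P_ref)` is the
#' cost difference at the reference price and `S` the scenario's discounted
#' screens. No price is returned (`NA`) for scenarios with fewer QALYs than
#' the comparator: no price makes a health loss cost-effective under a
#' willingness-to-pay threshold.
#'
#' @param scenario_cost Scenario total discounted cost at `ref_price`.
#' @param scenario_qalys Scenario discounted QALYs.
#' @param disc_screens Scenario discounted screen count (same denominator).
#' @param comparator_cost,comparator_qalys Comparator totals (at the
#'   comparator's own test price).
#' @param ref_price Per-test price at which `scenario_cost` was computed
#'   (default 0).
#' @param threshold Willingness-to-pay threshold, USD/QALY (default 50,000).
#' @return Maximum price in USD, or `NA` when the scenario yields fewer
#'   QALYs than the comparator.
#' @export
max_price <- function(scenario_cost, scenario_qalys, disc_screens,
                      comparator_cost, comparator_qalys,
                      ref_price = 0, threshold = 50000) {
  if (disc_screens == 0)
    stop("no screens performed: a per-test price is undefined", call. = FALSE)
  dq <- scenario_qalys - comparator_qalys
  if (dq < 0) return(NA_real_)
  dc <- scenario_cost - comparator_cost
  ref_price + (threshold * dq - dc) / disc_screens
}

#' Relative reduction in overdiagnoses
#'
#' `100 * (1 - scenario rate / comparator rate)`.
#'
#' @param comparator_rate,scenario_rate Overdiagnoses per 1000 women.
#' @return Percent reduction.
#' @export
#' @examples
#' overdiagnosis_reduction(18.1, 1.9)  # ~90
overdiagnosis_reduction <- function(comparator_rate, scenario_rate) {
  if (comparator_rate == 0)
    stop("comparator overdiagnosis rate is zero: reduction undefined",
         call. = FALSE)
  100 * (1 - scenario_rate / comparator_rate)
}
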