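#' Scenario specification
#'
#' One row of the experiment: a screening test, a policy, and whether this
#' scenario is the comparator that the cost-effectiveness layer prices
#' against.
#'
#' @param label Unique scenario label.
#' @param test A [test_characteristics()].
#' @param policy A [screening_policy()].
#' @param is_comparator Exactly one scenario per grid must set this.
#' @return A `scenario_spec`.
#' @export
#' @examples
#' comparator_spec()
scenario_spec <- function(label, test, policy = screening_policy(),
                          is_comparator = FALSE) {
  stopifnot(inherits(test, "test_characteristics"),
            inherits(policy, "screening_policy"))
  structure(list(label = label, test = test, policy = policy,
                 is_comparator = is_comparator), class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
comparator_spec <- function(policy = screening_policy()) {
  scenario_spec("digital mammography",
                test_characteristics(0.91, 1.21, 0.88, price = 149,
                                     label = "digital mammography"),
                policy = policy, is_comparator = TRUE)
}

#' Run one screening scenario on a prebuilt cohort
#'
#' Applies the scenario's test and policy to the cohort, classifies the
#' detected cancers, converts them to screening sensitivities, aggregates
#' per-1000 benefits and harms against the shared no-screening universe, and
#' costs the screened universe. Tests without a price are costed at a
#' reference price of 0; the affine-in-price identity (see [max_price()])
#' supplies any other price without re-simulation.
#'
#' @param spec A [scenario_spec()].
#' @param cohort A [sample_life_histories()] table.
#' @param control The [natural_course()] outcomes of `cohort`.
#' @param utilities,costs Lookup tables.
#' @param discount_rate,reference_age Discounting parameters.
#' @param window Counting window for [classify_cancers()].
#' @param control_qalys,control_cost Optional precomputed control-universe
#'   summaries (shared across a grid).
#' @return A `scenario_result`: list with `spec`, `screened`, `counts`,
#'   `sensitivities`, `summary` ([summarize_outcomes()]), `cost`
#'   ([total_cost()] at the reference price, per cohort), `ref_price`, and
#'   `roc_point` (`fpr = 1 - specificity`, `tpr` = combined sensitivity as a
#'   fraction).
#' @export
run_scenario <- function(spec, cohort, control,
                         utilities = utility_table(), costs = cost_table(),
                         discount_rate = 0.03, reference_age = 30,
                         window = c(50, 74),
                         control_qalys = NULL, control_cost = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  screened <- apply_screening(cohort, control, spec$policy, spec$test)
  counts <- classify_cancers(screened, window = window)
  sens <- if (sum(unlist(counts)) == 0) {
    c(dcis = NA_real_, invasive = NA_real_, combined = NA_real_)
  } else {
    compute_sensitivities(counts)
  }
  summ <- summarize_outcomes(screened, control, utilities,
                             discount_rate, reference_age,
                             control_qalys = control_qalys)
  ref_price <- if (is.na(spec$test$price)) 0 else spec$test$price
  cost <- total_cost(screened, costs, price = ref_price,
                     discount_rate, reference_age)
  structure(list(spec = spec, screened = screened, counts = counts,
                 sensitivities = sens, summary = summ, cost = cost,
                 ref_price = ref_price,
                 roc_point = c(fpr = 1 - spec$test$specificity,
                               tpr = unname(sens["combined"]) / 100)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$sensitivities
  cat(sprintf("<scenario_result> %s%s\n", x$spec$label,
              if (x$spec$is_comparator) " (comparator)" else ""))
  cat(sprintf("  sensitivities: DCIS %s%% / invasive %s%% / combined %s%%\n",
              s["dcis"], s["invasive"], s["combined"]))
  cat(sprintf("  mortality reduction %.1f%% | overdiagnoses %.2f/1000 | FPs %.1f/1000\n",
              x$summary$mortality_reduction_pct,
              x$summary$overdiagnoses_per_1000,
              x$summary$false_positives_per_1000))
  invisible(x)
}

#' Default scenario grid
#'
#' The comparator plus every combination of DCIS sensitivity (91% or 0%),
#' median detection size (1.03-1.39 cm in 0.06 cm steps, plus the 0.61 cm
#' and 0.01 cm near-perfect sizes), and specificity (88%, 96%, 100%), with
#' the per-test price left open.
#'
#' @param policy A [screening_policy()] shared by all scenarios.
#' @return List of [scenario_spec()]s (the comparator first).
#' @export
default_scenario_grid <- function(policy = screening_policy()) {
  grid <- expand.grid(dcis = c(0.91, 0),
                      size = c(seq(1.03, 1.39, by = 0.06), 0.61, 0.01),
                      spec = c(0.88, 0.96, 1.00))
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    lab <- sprintf("LB dcis=%d%% size=%.2f spec=%d%%",
                   round(100 * g$dcis), g$size, round(100 * g$spec))
    scenario_spec(lab, test_characteristics(g$dcis, g$size, g$spec),
                  policy = policy)
  })
  c(list(comparator_spec(policy)), specs)
}

#' Run a scenario grid on one shared cohort
#'
#' Builds the no-screening universe once, runs every scenario on the same
#' histories, and derives each scenario's ICER and maximum per-test price
#' against the comparator. Scenarios with fewer QALYs than the comparator
#' carry no maximum price.
#'
#' @param scenarios List of [scenario_spec()]s containing exactly one
#'   comparator; labels must be unique.
#' @param cohort A [sample_life_histories()] table.
#' @param utilities,costs Lookup tables.
#' @param threshold Willingness-to-pay threshold, USD/QALY.
#' @param discount_rate,reference_age,window Passed to [run_scenario()].
#' @param control Optional precomputed [natural_course()] outcomes.
#' @param keep_details Keep each full `scenario_result` in
#'   `attr(, "details")`.
#' @return A `grid_results` data.table, one row per scenario: test inputs,
#'   sensitivities, per-1000 outcomes, total discounted cost per 1000 women
#'   at the reference price (`total_cost_ref_usd1000`, in thousands),
#'   `icer_status`, `icer_usd_per_qaly` and `max_price_usd`.
#' @export
run_grid <- function(scenarios, cohort,
                     utilities = utility_table(), costs = cost_table(),
                     threshold = 50000, discount_rate = 0.03,
                     reference_age = 30, window = c(50, 74),
                     control = NULL, keep_details = FALSE) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  labels <- vapply(scenarios, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  comp_i <- which(vapply(scenarios, `[[`, NA, "is_comparator"))
  if (length(comp_i) != 1L)
    stop("the grid needs exactly one comparator scenario", call. = FALSE)

  control <- control %||% natural_course(cohort)
  control_qalys <- compute_qalys(control, utilities, discount_rate,
                                 reference_age)
  n <- attr(control, "n")
  per1000 <- function(x) x * 1000 / n

  results <- lapply(scenarios, run_scenario, cohort = cohort,
                    control = control, utilities = utilities, costs = costs,
                    discount_rate = discount_rate,
                    reference_age = reference_age, window = window,
                    control_qalys = control_qalys)
  comp <- results[[comp_i]]

  rows <- lapply(results, function(r) {
    ic <- icer(r$cost$total, r$summary$qalys$qalys,
               comp$cost$total, comp$summary$qalys$qalys)
    mp <- if (r$spec$is_comparator) NA_real_ else
      max_price(r$cost$total, r$summary$qalys$qalys, r$cost$disc_screens,
                comp$cost$total, comp$summary$qalys$qalys,
                ref_price = r$ref_price, threshold = threshold)
    data.table(
      label = r$spec$label,
      is_comparator = r$spec$is_comparator,
      dcis_sensitivity_pct = 100 * r$spec$test$dcis_sensitivity,
      median_detect_size_cm = r$spec$test$median_detect_size,
      specificity_pct = 100 * r$spec$test$specificity,
      dcis_pct = r$sensitivities["dcis"],
      invasive_pct = r$sensitivities["invasive"],
      combined_pct = r$sensitivities["combined"],
      mortality_reduction_pct = r$summary$mortality_reduction_pct,
      false_positives_per_1000 = r$summary$false_positives_per_1000,
      overdiagnoses_per_1000 = r$summary$overdiagnoses_per_1000,
      qalys_gained_per_1000 = r$summary$qalys_gained_per_1000,
      delta_qalys_vs_comparator_per_1000 =
        per1000(r$summary$qalys$qalys - comp$summary$qalys$qalys),
      total_cost_ref_usd1000 = per1000(r$cost$total) / 1000,
      ref_price_usd = r$ref_price,
      icer_status = ic$status,
      icer_usd_per_qaly = ic$icer,
      max_price_usd = mp
    )
  })
  out <- rbindlist(rows)
  setattr(out, "threshold", threshold)
  setattr(out, "n", n)
  if (keep_details) setattr(out, "details", results)
  setattr(out, "class", c("grid_results", class(out)))
  out[]
}

#' Export scenarios as ROC overlay points
#'
#' One point per scenario: false-positive rate `1 - specificity` against
#' true-positive rate (combined sensitivity as a fraction), annotated with
#' the maximum price and flagged (`filled`) when the scenario's mortality
#' reduction is at least the comparator's — the points a reader overlays on
#' an externally published ROC curve.
#'
#' @param results A [run_grid()] table.
#' @return A data.table: `label`, `fpr`, `tpr`, `max_price_usd`, `filled`.
#' @export
export_roc_points <- function(results) {
  stopifnot(inherits(results, "grid_results"))
  comp_mort <- results$mortality_reduction_pct[results$is_comparator]
  results[, .(label, fpr = 1 - specificity_pct / 100,
              tpr = combined_pct / 100, max_price_usd,
              filled = mortality_reduction_pct >= comp_mort)]
}

#' Write results tables as CSV
#'
#' `write_sensitivity_table()` emits the detection-count/sensitivity table
#' (counts by mode and pathology plus the three sensitivities);
#' `write_outcome_table()` emits the per-1000 outcomes and pricing table.
#'
#' @param results A [run_grid()] table (with details kept, for counts) or
#'   `grid_results` row subset.
#' @param path Output CSV path.
#' @export
write_outcome_table <- function(results, path) {
  cols <- c("label", "combined_pct", "specificity_pct",
            "mortality_reduction_pct", "false_positives_per_1000",
            "overdiagnoses_per_1000", "qalys_gained_per_1000",
            "total_cost_ref_usd1000", "max_price_usd")
  fwrite(as.data.table(results)[, cols, with = FALSE], path)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
write_sensitivity_table <- function(results, path) {
  details <- attr(results, "details")
  if (is.null(details))
    stop("run_grid(..., keep_details = TRUE) is needed for the ",
         "sensitivity table", call. = FALSE)
  rows <- lapply(details, function(r) {
    data.table(label = r$spec$label,
               dcis_sensitivity_pct = 100 * r$spec$test$dcis_sensitivity,
               median_detect_size_cm = r$spec$test$median_detect_size,
               invasive_screen = r$counts$invasive_screen,
               invasive_interval = r$counts$invasive_interval,
               dcis_screen = r$counts$dcis_screen,
               dcis_interval = r$counts$dcis_interval,
               dcis_pct = r$sensitivities["dcis"],
               invasive_pct = r$sensitivities["invasive"],
               combined_pct = r$sensitivities["combined"])
  })
  fwrite(rbindlist(rows), path)
  invisible(path)
}

#' Read a scenario grid from a YAML configuration file
#'
#' The file holds an optional `policy` block (fields of
#' [screening_policy()]) and a `scenarios` list whose entries have `label`,
#' `dcis_sensitivity`, `median_detect_size`, `specificity`, optional `price`
#' and `comparator` flags.
#'
#' @param path YAML path.
#' @return List of [scenario_spec()]s.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  policy <- do.call(screening_policy, cfg$policy %||% list())
  lapply(cfg$scenarios, function(s) {
    scenario_spec(s$label,
                  test_characteristics(s$dcis_sensitivity,
                                       s$median_detect_size, s$specificity,
                                       price = s$price %||% NA_real_,
                                       label = s$label),
                  policy = policy,
                  is_comparator = isTRUE(s$comparator))
  })
}
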