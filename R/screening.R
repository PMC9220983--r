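#' Screening policy (schedule and attendance)
#'
#' @param start_age,stop_age First and last scheduled screening ages (years).
#' @param interval Years between screens.
#' @param attendance Per-round attendance probability (1 = every woman
#'   attends every round while alive and undiagnosed).
#' @return A `screening_policy` object. The default is biennial screening at
#'   ages 50-74 (13 rounds).
#' @export
#' @examples
#' scheduled_ages(screening_policy())
screening_policy <- function(start_age = 50, stop_age = 74, interval = 2,
                             attendance = 1.0) {
  if (start_age >= stop_age && !(start_age == stop_age))
    stop("start_age must not exceed stop_age", call. = FALSE)
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  if (attendance < 0 || attendance > 1)
    stop("attendance must be a probability", call. = FALSE)
  structure(list(start_age = start_age, stop_age = stop_age,
                 interval = interval, attendance = attendance),
            class = "screening_policy")
}

#' @rdname screening_policy
#' @param policy A `screening_policy`.
#' @return `scheduled_ages()`: the ordered vector of scheduled ages
#'   `start, start + interval, ..., <= stop`.
#' @export
scheduled_ages <- function(policy) {
  seq(policy$start_age, policy$stop_age, by = policy$interval)
}

#' Screening test characteristics
#'
#' One point of the scenario grid: how well the test sees DCIS, how small an
#' invasive tumor it can see (as the median of the Weibull
#' screen-detectability threshold), how often it is falsely positive in a
#' woman with nothing to find, and what one test costs.
#'
#' @param dcis_sensitivity Per-round probability of detecting a DCIS lesion
#'   during its pre-clinical dwell.
#' @param median_detect_size Median tumor diameter (cm) at screen
#'   detectability; smaller means a more sensitive test for invasive disease.
#' @param specificity Probability that a screen of a woman with no detectable
#'   cancer is (correctly) negative.
#' @param price Cost per test in USD (`NA` while still to be determined, as
#'   for a hypothetical test whose maximum viable price is the quantity of
#'   interest).
#' @param label Optional scenario label.
#' @return A `test_characteristics` object.
#' @export
#' @examples
#' mammography <- test_characteristics(0.91, 1.21, 0.88, price = 149,
#'                                     label = "digital mammography")
test_characteristics <- function(dcis_sensitivity, median_detect_size,
                                 specificity, price = NA_real_,
                                 label = NULL) {
  for (p in c(dcis_sensitivity, specificity))
    if (is.na(p) || p < 0 || p > 1)
      stop("sensitivity/specificity must be probabilities in [0, 1]",
           call. = FALSE)
  if (is.na(median_detect_size) || median_detect_size <= 0)
    stop("median_detect_size must be positive", call. = FALSE)
  structure(list(dcis_sensitivity = dcis_sensitivity,
                 median_detect_size = median_detect_size,
                 specificity = specificity, price = price,
                 label = label %||% sprintf("dcis%d_size%.2f_spec%d",
                                            round(100 * dcis_sensitivity),
                                            median_detect_size,
                                            round(100 * specificity))),
            class = "test_characteristics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the screening (intervention) universe
#'
#' Replays the *same* life histories as [natural_course()] under a screening
#' policy and test: the parallel-universe contrast. At every attended round a
#' woman who is alive and undiagnosed is screened. An invasive tumor is
#' detected once its diameter has reached the tumor's screen-detectability
#' threshold (the stored uniform `u_detect` mapped through the scenario's
#' Weibull, so the same tumor is consistently easier or harder to find across
#' scenarios); a DCIS lesion in its pre-clinical dwell is detected with the
#' test's DCIS sensitivity per round (a stored uniform mapped through the
#' geometric first-success law, so a more sensitive test always detects at
#' least as early). Screen detection before the fatal diameter cures;
#' detection at or after it advances the diagnosis but not death. Undetected
#' tumors follow the control course. Women exit screening permanently at
#' diagnosis.
#'
#' False positives are not simulated woman-by-woman: a negative screen of a
#' woman with no detectable cancer is falsely positive with probability
#' `1 - specificity`, and since a false positive changes neither her schedule
#' nor her disease course, the per-round count of such screens (returned in
#' `$rounds`) carries the expected false-positive burden exactly. Rounds at
#' which an undetected DCIS lesion is present are treated as test misses, not
#' false-positive candidates.
#'
#' @param cohort A [sample_life_histories()] table.
#' @param control The [natural_course()] outcomes for the same cohort.
#' @param policy A [screening_policy()].
#' @param test A [test_characteristics()].
#' @param attendance_seed Seed for per-round attendance draws, used only when
#'   `policy$attendance < 1`; defaults to the cohort seed so that scenarios
#'   share attendance patterns.
#' @return An object of class `screened_outcomes`: a list with `$women` (one
#'   row per woman: `woman_id`, `dx_age`, `dx_mode` in `none` /
#'   `screen_invasive` / `screen_dcis` / `clinical_invasive` /
#'   `clinical_dcis`, `dx_diameter`, `stage`, `bc_death_age`, `death_age`,
#'   `death_cause`, `n_screens`), and `$rounds` (per scheduled age: number of
#'   screens performed and number of false-positive-eligible negative
#'   screens). Attributes `test`, `policy`, `n`.
#' @export
apply_screening <- function(cohort, control, policy, test,
                            attendance_seed = attr(cohort, "seed")) {
  stopifnot(inherits(cohort, "life_histories"),
            inherits(control, "course_outcomes"),
            inherits(policy, "screening_policy"),
            inherits(test, "test_characteristics"))
  if (nrow(cohort) != nrow(control) ||
      !identical(cohort$woman_id, control$woman_id))
    stop("control outcomes do not pair with this cohort (parallel-universe ",
         "contract violation)", call. = FALSE)

  params <- attr(cohort, "params")
  d0 <- params$onset_diameter
  ages <- scheduled_ages(policy)
  n <- nrow(cohort)

  # Per-woman derived quantities (NA-safe: comparisons with NA gate to FALSE
  # via isTRUE-style masks below).
  d_screen <- detection_threshold_quantile(cohort$u_detect,
                                           test$median_detect_size,
                                           params$detect_threshold_shape)
  g <- cohort$growth_rate
  inv_onset <- cohort$invasive_onset
  t_det <- inv_onset + pmax(0, log(d_screen / d0)) / g
  t_clin <- control$t_clinical
  t_fatal <- control$t_fatal
  ocd <- cohort$age_other_cause_death
  death_ctrl <- control$death_age
  ctrl_dx <- fifelse(is.na(control$dx_age), Inf, control$dx_age)

  is_dcis <- !is.na(cohort$starts_as_dcis) & cohort$starts_as_dcis
  dcis_lo <- cohort$onset_age
  dcis_hi <- cohort$onset_age + cohort$dcis_dwell

  # Geometric first-success construction: number of screens of the dwelling
  # lesion needed for detection, shared across scenarios through u_dcis_detect.
  s0 <- test$dcis_sensitivity
  trials_needed <- rep(Inf, n)
  if (s0 >= 1) {
    trials_needed[is_dcis] <- 1
  } else if (s0 > 0) {
    u <- cohort$u_dcis_detect
    trials_needed[is_dcis] <-
      1 + floor(log(1 - u[is_dcis]) / log(1 - s0))
  }

  # Outcome columns start as the control course and are overwritten on
  # screen detection.
  women <- data.table(
    woman_id = cohort$woman_id,
    dx_age = control$dx_age,
    dx_mode = control$dx_mode,
    dx_diameter = control$dx_diameter,
    stage = control$stage,
    bc_death_age = control$bc_death_age,
    death_age = control$death_age,
    death_cause = control$death_cause,
    n_screens = 0L
  )

  detected <- rep(FALSE, n)
  dcis_misses <- rep(0L, n)
  n_screens_round <- integer(length(ages))
  n_negative_round <- integer(length(ages))
  n_screens_w <- integer(n)
  att_base <- stream_seed(attendance_seed %||% 0L, "attendance")

  has_inv <- !is.na(inv_onset)
  for (j in seq_along(ages)) {
    a <- ages[j]
    active <- !detected & a < ctrl_dx & a < death_ctrl
    if (policy$attendance < 1) {
      set.seed(att_base + j)
      active <- active & (runif(n) < policy$attendance)
    }
    if (!any(active)) next
    n_screens_round[j] <- sum(active)
    n_screens_w[active] <- n_screens_w[active] + 1L

    dcis_present <- active & is_dcis & !is.na(dcis_lo) &
      a >= dcis_lo & a < dcis_hi
    if (any(dcis_present)) {
      dcis_misses[dcis_present] <- dcis_misses[dcis_present] + 1L
      hit <- dcis_present & dcis_misses >= trials_needed
      if (any(hit)) {
        idx <- which(hit)
        set(women, idx, "dx_age", a)
        set(women, idx, "dx_mode", "screen_dcis")
        set(women, idx, "dx_diameter", NA_real_)
        set(women, idx, "stage", "in_situ")
        # In-situ detection always cures: a progressing lesion never reaches
        # its invasive phase, so death reverts to other causes.
        set(women, idx, "death_age", ocd[idx])
        set(women, idx, "death_cause", "other")
        set(women, idx, "bc_death_age", NA_real_)
        detected[idx] <- TRUE
      }
    }

    inv_hit <- active & !detected & has_inv &
      !is.na(t_det) & a >= t_det & a < t_clin
    if (any(inv_hit)) {
      idx <- which(inv_hit)
      diam <- d0 * exp(g[idx] * (a - inv_onset[idx]))
      set(women, idx, "dx_age", rep(a, length(idx)))
      set(women, idx, "dx_mode", "screen_invasive")
      set(women, idx, "dx_diameter", diam)
      set(women, idx, "stage", stage_at_diagnosis(diam, is_dcis = FALSE))
      cured <- a < t_fatal[idx]
      ci <- idx[cured]
      set(women, ci, "death_age", ocd[ci])
      set(women, ci, "death_cause", "other")
      set(women, ci, "bc_death_age", NA_real_)
      detected[idx] <- TRUE
    }

    # Negative screens eligible for a false positive: no detection this
    # round and no (missed) DCIS lesion on board.
    n_negative_round[j] <- n_screens_round[j] -
      sum(dcis_present) - sum(inv_hit)
  }

  set(women, NULL, "n_screens", n_screens_w)
  res <- structure(
    list(women = women[],
         rounds = data.table(age = ages, n_screens = n_screens_round,
                             n_negative = n_negative_round)),
    class = "screened_outcomes")
  attr(res, "test") <- test
  attr(res, "policy") <- policy
  attr(res, "n") <- n
  res
}

#' @export
print.screened_outcomes <- function(x, ...) {
  test <- attr(x, "test")
  n <- attr(x, "n")
  cat(sprintf("<screened_outcomes> %s | n = %d women\n", test$label, n))
  cat(sprintf("  screens: %d; expected false positives: %.1f\n",
              sum(x$rounds$n_screens),
              (1 - test$specificity) * sum(x$rounds$n_negative)))
  print(table(x$women$dx_mode))
  invisible(x)
}

#' Expected number of false-positive screens
#'
#' `(1 - specificity)` times the number of negative screens of women with no
#' detectable cancer. Exactly affine in `1 - specificity` by construction.
#'
#' @param screened An [apply_screening()] result.
#' @param per Report per this many women (`NULL` for the cohort total).
#' @return Expected false positives.
#' @export
false_positive_count <- function(screened, per = NULL) {
  test <- attr(screened, "test")
  fp <- (1 - test$specificity) * sum(screened$rounds$n_negative)
  if (!is.null(per)) fp <- fp * per / attr(screened, "n")
  fp
}

#' Count cancers diagnosed in an age window, by mode and pathology
#'
#' Partitions every diagnosis with diagnosis age in the window (inclusive of
#' completed age `window[2]`, i.e. before the `window[2] + 1`-th birthday)
#' into the four cells screen-detected vs clinically/interval-detected,
#' invasive vs DCIS. False positives never enter these counts.
#'
#' @param screened An [apply_screening()] result (or any table with `dx_age`
#'   and `dx_mode`).
#' @param window Two ages bounding the counting window (default 50-74).
#' @return A `detection_counts` object: counts `invasive_screen`,
#'   `invasive_interval`, `dcis_screen`, `dcis_interval`.
#' @export
classify_cancers <- function(screened, window = c(50, 74)) {
  w <- if (inherits(screened, "screened_outcomes")) screened$women else screened
  inwin <- !is.na(w$dx_age) & w$dx_age >= window[1] & w$dx_age < window[2] + 1
  m <- w$dx_mode[inwin]
  counts <- list(
    invasive_screen   = sum(m == "screen_invasive"),
    invasive_interval = sum(m == "clinical_invasive"),
    dcis_screen       = sum(m == "screen_dcis"),
    dcis_interval     = sum(m == "clinical_dcis")
  )
  structure(counts, class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat("<detection_counts>\n")
  cat(sprintf("  invasive: %d screen / %d interval\n",
              x$invasive_screen, x$invasive_interval))
  cat(sprintf("  DCIS:     %d screen / %d interval\n",
              x$dcis_screen, x$dcis_interval))
  invisible(x)
}

#' Convert detection counts to screening sensitivities
#'
#' The proportion of cancers diagnosed in the counting window that were
#' screen-detected, separately for DCIS and invasive disease and combined,
#' as integer percentages. This is the conversion currency for comparing a
#' modeled test to externally reported test performance.
#'
#' @param counts A [classify_cancers()] result (or a list with the four
#'   fields).
#' @return Named numeric vector `c(dcis, invasive, combined)`, in percent
#'   rounded to integers. A pathology with no diagnosed cancers at all gives
#'   `NA` for its component.
#' @export
#' @examples
#' compute_sensitivities(list(invasive_screen = 499859,
#'                            invasive_interval = 280403,
#'                            dcis_screen = 211799, dcis_interval = 25736))
compute_sensitivities <- function(counts) {
  tot_inv <- counts$invasive_screen + counts$invasive_interval
  tot_dcis <- counts$dcis_screen + counts$dcis_interval
  if (tot_inv + tot_dcis == 0)
    stop("no cancers in counts: sensitivities undefined", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den)
  c(dcis = pct(counts$dcis_screen, tot_dcis),
    invasive = pct(counts$invasive_screen, tot_inv),
    combined = pct(counts$dcis_screen + counts$invasive_screen,
                   tot_inv + tot_dcis))
}
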