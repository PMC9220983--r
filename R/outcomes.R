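#' Utility table: quality-of-life adjustments for screening events and care
#'
#' Utilities are applied as additive QALY decrements, `(1 - utility) *
#' duration`, discounted to the reference age. Defaults: attending a screen
#' carries utility 0.994 for 1 week; a diagnostic workup (after a true or
#' false positive, or a clinical presentation) carries 0.895 for 5 weeks;
#' breast-cancer care carries stage-specific utilities by phase of care —
#' initial (first 12 months after diagnosis), continuous (between initial and
#' terminal), terminal (last 12 months before breast-cancer death, utility
#' 0.49 at every stage), and terminal-OCD (the final year of a woman dying of
#' another cause with a breast-cancer history).
#'
#' @param screening_utility,screening_weeks Utility and duration (weeks) per
#'   attended screen.
#' @param workup_utility,workup_weeks Utility and duration (weeks) per
#'   diagnostic workup episode.
#' @param phase_utilities 4x4 numeric matrix, rows `in_situ`, `local`,
#'   `regional`, `distant`; columns `initial`, `continuous`, `terminal`,
#'   `terminal_ocd`.
#' @return A `utility_table` object.
#' @export
#' @examples
#' utility_table()$phase_utilities
utility_table <- function(screening_utility = 0.994, screening_weeks = 1,
                          workup_utility = 0.895, workup_weeks = 5,
                          phase_utilities = default_phase_utilities()) {
  stages <- c("in_situ", "local", "regional", "distant")
  phases <- c("initial", "continuous", "terminal", "terminal_ocd")
  if (!is.matrix(phase_utilities) ||
      !identical(rownames(phase_utilities), stages) ||
      !identical(colnames(phase_utilities), phases))
    stop("phase_utilities must be a 4x4 matrix with stages as rows and ",
         "phases as columns", call. = FALSE)
  vals <- c(screening_utility, workup_utility, phase_utilities)
  if (any(vals <= 0) || any(vals > 1))
    stop("utilities must lie in (0, 1]", call. = FALSE)
  structure(list(screening_utility = screening_utility,
                 screening_weeks = screening_weeks,
                 workup_utility = workup_utility,
                 workup_weeks = workup_weeks,
                 phase_utilities = phase_utilities),
            class = "utility_table")
}

default_phase_utilities <- function() {
  matrix(c(0.90, 0.93, 0.49, 0.93,
           0.90, 0.93, 0.49, 0.93,
           0.75, 0.78, 0.49, 0.78,
           0.60, 0.62, 0.49, 0.62),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("in_situ", "local", "regional", "distant"),
                         c("initial", "continuous", "terminal",
                           "terminal_ocd")))
}

#' Read a utility table from CSV
#'
#' Long format with columns `item` (`screening`, `workup`, `care`), `stage`,
#' `phase`, `value`, `weeks`; see the packaged fixture
#' `system.file("extdata", "utility_table.csv", package = "screensim")`.
#'
#' @param path CSV path.
#' @return A [utility_table()] object.
#' @export
read_utility_table <- function(path) {
  x <- utils::read.csv(path)
  care <- x[x$item == "care", ]
  pu <- default_phase_utilities()
  pu[cbind(care$stage, care$phase)] <- care$value
  scr <- x[x$item == "screening", ]
  wk <- x[x$item == "workup", ]
  utility_table(screening_utility = scr$value, screening_weeks = scr$weeks,
                workup_utility = wk$value, workup_weeks = wk$weeks,
                phase_utilities = pu)
}

#' Discounting helpers
#'
#' `discount_factor()` is the present-value factor
#' `(1 + rate)^-(age - reference_age)` applied to an event at `age`;
#' `discounted_years()` is the closed-form present value of one year of life
#' accrued continuously over `[from, to]`. Intervals are clamped below at the
#' reference age: time lived before the reference age is neither counted nor
#' inflated.
#'
#' @param age,from,to Event age / interval bounds (years).
#' @param rate Annual discount rate (e.g. 0.03).
#' @param reference_age Age to which values are discounted (default 30).
#' @return Dimensionless factor, or discounted years.
#' @export
#' @examples
#' discount_factor(40, 0.03, 30)   # 1/1.03^10
#' discounted_years(30, 80, 0.03)  # discounted life-years, ages 30-80
discount_factor <- function(age, rate, reference_age = 30) {
  (1 + rate)^-(pmax(age, reference_age) - reference_age)
}

#' @rdname discount_factor
#' @export
discounted_years <- function(from, to, rate, reference_age = 30) {
  from <- pmax(from, reference_age)
  to <- pmax(to, from)
  if (rate == 0) return(to - from)
  (discount_factor(from, rate, reference_age) -
     discount_factor(to, rate, reference_age)) / log(1 + rate)
}

# Care-phase boundaries shared by QALY and cost accounting. Initial phase =
# first 12 months after diagnosis, terminal = last 12 months of life; when a
# woman survives less than 2 years the terminal phase takes precedence and
# the initial phase is truncated, so the three phases always partition
# diagnosis-to-death exactly.
care_phases <- function(dx_age, death_age) {
  terminal_start <- pmax(dx_age, death_age - 1)
  initial_end <- pmin(dx_age + 1, terminal_start)
  list(dx = dx_age, initial_end = initial_end,
       terminal_start = terminal_start, death = death_age)
}

#' Discounted life-years and QALYs for one universe
#'
#' Computes, for an entire cohort in either universe, discounted life-years
#' (counted from the reference age to death) and the five disaggregated QALY
#' decrement components: screen attendance, true-positive workup,
#' false-positive workup (in expectation, `1 - specificity` per eligible
#' negative screen), workup at clinical detection, and breast-cancer care by
#' stage and phase. QALYs are discounted life-years minus the summed
#' decrements.
#'
#' @param outcomes A [natural_course()] table (no-screening universe: the
#'   screening, true-positive and false-positive components are zero) or an
#'   [apply_screening()] result.
#' @param utilities A [utility_table()].
#' @param discount_rate Annual discount rate (default 0.03).
#' @param reference_age Discounting anchor and the age from which life-years
#'   are counted (default 30).
#' @return A `qaly_summary`: list with `life_years`, `decrements` (named
#'   5-vector), `qalys`, all cohort totals, plus `n`.
#' @export
compute_qalys <- function(outcomes, utilities = utility_table(),
                          discount_rate = 0.03, reference_age = 30) {
  screened <- inherits(outcomes, "screened_outcomes")
  w <- if (screened) outcomes$women else outcomes
  n <- if (screened) attr(outcomes, "n") else attr(outcomes, "n") %||% nrow(w)
  vf <- function(a) discount_factor(a, discount_rate, reference_age)

  ly <- sum(discounted_years(reference_age, w$death_age, discount_rate,
                             reference_age))

  wk_dec <- (1 - utilities$workup_utility) * utilities$workup_weeks / 52
  scr_dec <- (1 - utilities$screening_utility) * utilities$screening_weeks / 52

  dec_screening <- 0
  dec_fp <- 0
  if (screened) {
    test <- attr(outcomes, "test")
    r <- outcomes$rounds
    dec_screening <- scr_dec * sum(r$n_screens * vf(r$age))
    dec_fp <- (1 - test$specificity) * wk_dec * sum(r$n_negative * vf(r$age))
  }

  dx <- !is.na(w$dx_age)
  screen_dx <- dx & w$dx_mode %in% c("screen_invasive", "screen_dcis")
  clin_dx <- dx & w$dx_mode %in% c("clinical_invasive", "clinical_dcis")
  dec_tp <- wk_dec * sum(vf(w$dx_age[screen_dx]))
  dec_clin <- wk_dec * sum(vf(w$dx_age[clin_dx]))

  dec_care <- 0
  if (any(dx)) {
    pu <- utilities$phase_utilities
    dxa <- w$dx_age[dx]
    D <- w$death_age[dx]
    st <- w$stage[dx]
    bc <- w$death_cause[dx] == "breast_cancer"
    ph <- care_phases(dxa, D)
    u_init <- pu[st, "initial"]
    u_cont <- pu[st, "continuous"]
    u_term <- ifelse(bc, pu[st, "terminal"], pu[st, "terminal_ocd"])
    dy <- function(a, b) discounted_years(a, b, discount_rate, reference_age)
    dec_care <- sum((1 - u_init) * dy(ph$dx, ph$initial_end) +
                      (1 - u_cont) * dy(ph$initial_end, ph$terminal_start) +
                      (1 - u_term) * dy(ph$terminal_start, ph$death))
  }

  decrements <- c(screening = dec_screening, tp_followup = dec_tp,
                  fp = dec_fp, clinical_detection = dec_clin,
                  bc_care = dec_care)
  structure(list(life_years = ly, decrements = decrements,
                 qalys = ly - sum(decrements), n = n),
            class = "qaly_summary")
}

#' @export
print.qaly_summary <- function(x, ...) {
  cat(sprintf("<qaly_summary> n = %d | LY %.1f | QALY %.1f\n",
              x$n, x$life_years, x$qalys))
  cat("  decrements:", paste(sprintf("%s %.2f", names(x$decrements),
                                     x$decrements), collapse = ", "), "\n")
  invisible(x)
}

#' Breast-cancer deaths in a universe
#'
#' @param outcomes A [natural_course()] table or [apply_screening()] result.
#' @return Count of women dying of breast cancer.
#' @export
bc_deaths <- function(outcomes) {
  w <- if (inherits(outcomes, "screened_outcomes")) outcomes$women else outcomes
  sum(w$death_cause == "breast_cancer")
}

#' Breast-cancer mortality reduction
#'
#' `100 * (1 - screened deaths / control deaths)`, to one decimal. Accepts
#' either simulated universes or raw death counts.
#'
#' @param screened,control Universes (or numeric death counts).
#' @return Percent reduction, one decimal.
#' @export
#' @examples
#' mortality_reduction(750, 1000)
mortality_reduction <- function(screened, control) {
  ds <- if (is.numeric(screened)) screened else bc_deaths(screened)
  dc <- if (is.numeric(control)) control else bc_deaths(control)
  if (dc == 0)
    stop("no breast-cancer deaths in the control universe: ",
         "mortality reduction undefined", call. = FALSE)
  round(100 * (1 - ds / dc), 1)
}

#' Overdiagnoses per 1000 women
#'
#' An overdiagnosis is a diagnosis (DCIS or invasive) in the screened
#' universe of a woman whose unscreened counterpart was never clinically
#' diagnosed and died of another cause — the diagnosis could never have
#' helped her.
#'
#' @param screened An [apply_screening()] result.
#' @param control The paired [natural_course()] table.
#' @param per Denominator scale (default per 1000 women simulated).
#' @return Rate per `per` women; attribute `count` holds the raw count.
#' @export
count_overdiagnoses <- function(screened, control, per = 1000) {
  w <- screened$women
  if (!identical(w$woman_id, control$woman_id))
    stop("screened and control outcomes are not paired (contract violation)",
         call. = FALSE)
  od <- !is.na(w$dx_age) & control$dx_mode == "none" &
    control$death_cause == "other"
  structure(sum(od) * per / attr(screened, "n"), count = sum(od))
}

#' Aggregate a scenario's benefits and harms per 1000 women
#'
#' The per-1000 contrast of one screening universe against the shared
#' no-screening universe: mortality reduction, false positives,
#' overdiagnoses, discounted life-years and QALYs gained, and the screened
#' universe's disaggregated QALY decrement components.
#'
#' @param screened An [apply_screening()] result.
#' @param control The paired [natural_course()] table.
#' @param utilities A [utility_table()].
#' @param discount_rate,reference_age Passed to [compute_qalys()].
#' @param control_qalys Optional precomputed [compute_qalys()] for the
#'   control universe (saves recomputation across scenarios).
#' @return An `outcome_summary` list.
#' @export
summarize_outcomes <- function(screened, control,
                               utilities = utility_table(),
                               discount_rate = 0.03, reference_age = 30,
                               control_qalys = NULL) {
  n <- attr(screened, "n")
  q_s <- compute_qalys(screened, utilities, discount_rate, reference_age)
  q_c <- control_qalys %||%
    compute_qalys(control, utilities, discount_rate, reference_age)
  structure(list(
    mortality_reduction_pct = if (bc_deaths(control) == 0) NA_real_ else
      mortality_reduction(screened, control),
    false_positives_per_1000 = false_positive_count(screened, per = 1000),
    overdiagnoses_per_1000 = as.numeric(count_overdiagnoses(screened, control)),
    qalys_gained_per_1000 = (q_s$qalys - q_c$qalys) * 1000 / n,
    life_years_gained_per_1000 = (q_s$life_years - q_c$life_years) * 1000 / n,
    decrements_per_1000 = q_s$decrements * 1000 / n,
    qalys = q_s, control_qalys = q_c, n = n
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary> per 1000 women\n")
  cat(sprintf("  mortality reduction %.1f%% | FPs %.1f | overdiagnoses %.2f\n",
              x$mortality_reduction_pct, x$false_positives_per_1000,
              x$overdiagnoses_per_1000))
  cat(sprintf("  QALYs gained %.1f | life-years gained %.1f\n",
              x$qalys_gained_per_1000, x$life_years_gained_per_1000))
  invisible(x)
}
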