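#' Resolve the no-screening (control) universe
#'
#' Plays out every life history without any screening intervention. Invasive
#' tumors (including DCIS that progressed) surface clinically when their
#' diameter reaches the per-tumor clinical diameter; the diagnosis cures the
#' woman if and only if it happens strictly before the tumor crosses its
#' fatal diameter, otherwise breast-cancer death occurs at the
#' fatal-diameter crossing age plus the drawn post-fatal survival time,
#' censored by other-cause death. Clinically surfacing DCIS is diagnosed in
#' situ at the end of its dwell and never kills; regressing DCIS leaves no
#' trace. A tumor whose clinical diameter would be reached only after death
#' is never diagnosed.
#'
#' @param cohort A [sample_life_histories()] table.
#' @return A `data.table` of class `course_outcomes`, one row per woman:
#'   `woman_id`, `dx_age`, `dx_mode` (`none`, `clinical_invasive`,
#'   `clinical_dcis`), `dx_diameter` (cm, `NA` for DCIS/none), `stage`
#'   (`in_situ`/`local`/`regional`/`distant` or `NA`), `bc_death_age`
#'   (`NA` unless she dies of breast cancer), `death_age`, `death_cause`
#'   (`breast_cancer`/`other`), and the crossing ages `t_clinical`,
#'   `t_fatal` (`NA` where there is no invasive phase) used by the
#'   screening universe.
#' @export
#' @examples
#' cohort <- sample_life_histories(2000, natural_history_params(), seed = 1)
#' ctrl <- natural_course(cohort)
#' table(ctrl$dx_mode)
natural_course <- function(cohort) {
  stopifnot(inherits(cohort, "life_histories"))
  params <- attr(cohort, "params")
  d0 <- params$onset_diameter
  n <- nrow(cohort)

  ocd <- cohort$age_other_cause_death
  out <- data.table(
    woman_id = cohort$woman_id,
    dx_age = NA_real_, dx_mode = "none", dx_diameter = NA_real_,
    stage = NA_character_, bc_death_age = NA_real_,
    death_age = ocd, death_cause = "other",
    t_clinical = NA_real_, t_fatal = NA_real_
  )

  # Invasive phase: de-novo invasive tumors and progressing DCIS.
  inv <- which(cohort$has_tumor & !is.na(cohort$invasive_onset))
  if (length(inv)) {
    g <- cohort$growth_rate[inv]
    a0 <- cohort$invasive_onset[inv]
    t_clin <- a0 + log(cohort$d_clinical[inv] / d0) / g
    t_fatal <- a0 + log(cohort$d_fatal[inv] / d0) / g
    set(out, inv, "t_clinical", t_clin)
    set(out, inv, "t_fatal", t_fatal)

    cured <- t_clin < t_fatal
    oc <- ocd[inv]

    # Cured path: diagnosed only if clinical surfacing precedes death.
    dx <- cured & t_clin < oc
    # Fatal path: breast-cancer death clock runs from the fatal crossing.
    bc_cand <- t_fatal + cohort$survival_after_fatal[inv]
    death <- ifelse(cured, oc, pmin(oc, bc_cand))
    dx <- dx | (!cured & t_clin < death)
    cause <- ifelse(!cured & bc_cand < oc, "breast_cancer", "other")

    set(out, inv, "death_age", death)
    set(out, inv, "death_cause", cause)
    set(out, inv[cause == "breast_cancer"], "bc_death_age",
        bc_cand[cause == "breast_cancer"])
    idx <- inv[dx]
    set(out, idx, "dx_age", t_clin[dx])
    set(out, idx, "dx_mode", "clinical_invasive")
    set(out, idx, "dx_diameter", cohort$d_clinical[inv][dx])
    set(out, idx, "stage",
        stage_at_diagnosis(cohort$d_clinical[inv][dx], is_dcis = FALSE))
  }

  # DCIS surfacing clinically with symptoms: diagnosed in situ, never fatal.
  cd <- which(cohort$has_tumor & !is.na(cohort$dcis_fate) &
                cohort$dcis_fate == "clinical_dcis")
  if (length(cd)) {
    t_dx <- cohort$onset_age[cd] + cohort$dcis_dwell[cd]
    hit <- t_dx < ocd[cd]
    idx <- cd[hit]
    set(out, idx, "dx_age", t_dx[hit])
    set(out, idx, "dx_mode", "clinical_dcis")
    set(out, idx, "stage", "in_situ")
  }

  setattr(out, "n", n)
  setattr(out, "class", c("course_outcomes", class(out)))
  out[]
}

#' Stage a tumor at diagnosis from its diameter
#'
#' DCIS is staged in situ; invasive tumors are staged by size with the
#' standard T-size breakpoints, half-open and lower-inclusive: `< 2` cm
#' local, `[2, 5)` cm regional, `>= 5` cm distant. The breakpoints are
#' configurable.
#'
#' @param diameter Diameter at diagnosis, cm (vectorised).
#' @param is_dcis Logical (vectorised); `TRUE` stages in situ regardless of
#'   diameter.
#' @param breaks Two increasing size breakpoints, cm.
#' @return Character vector of stages.
#' @export
#' @examples
#' stage_at_diagnosis(c(1.9, 2, 5.5), is_dcis = FALSE)
stage_at_diagnosis <- function(diameter, is_dcis = FALSE, breaks = c(2, 5)) {
  if (length(is_dcis) == 1L) is_dcis <- rep(is_dcis, length(diameter))
  if (any(diameter < 0 & !is_dcis, na.rm = TRUE))
    stop("negative tumor diameter", call. = FALSE)
  stage <- ifelse(diameter < breaks[1], "local",
                  ifelse(diameter < breaks[2], "regional", "distant"))
  stage[is_dcis] <- "in_situ"
  stage
}

#' Export paired control/screened outcomes for audit
#'
#' Writes one CSV row per woman with the no-screening and screened courses
#' side by side (columns suffixed `_control` / `_screened`).
#'
#' @param control A [natural_course()] table.
#' @param screened An [apply_screening()] result.
#' @param path Output CSV path.
#' @export
write_outcomes_csv <- function(control, screened, path) {
  sw <- screened$women
  keep <- c("woman_id", "dx_age", "dx_mode", "stage", "bc_death_age",
            "death_age", "death_cause")
  a <- as.data.table(control)[, keep, with = FALSE]
  b <- as.data.table(sw)[, keep, with = FALSE]
  setnames(a, setdiff(keep, "woman_id"),
           paste0(setdiff(keep, "woman_id"), "_control"))
  setnames(b, setdiff(keep, "woman_id"),
           paste0(setdiff(keep, "woman_id"), "_screened"))
  fwrite(a[b, on = "woman_id"], path)
  invisible(path)
}
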