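# Shared fixtures: everything is generated in code at test time.

# A cohort built from an explicit per-woman table, for hand-computed cases.
# Fills model defaults for any column not supplied.
manual_cohort <- function(women, params = natural_history_params(),
                          seed = 0L) {
  defaults <- list(
    birth_year = 1970L, age_other_cause_death = 100, has_tumor = FALSE,
    onset_age = NA_real_, growth_rate = NA_real_, d_clinical = NA_real_,
    d_fatal = NA_real_, starts_as_dcis = NA, dcis_fate = NA_character_,
    dcis_dwell = NA_real_, invasive_onset = NA_real_,
    survival_after_fatal = NA_real_, u_detect = 0.5, u_dcis_detect = 0.5
  )
  dt <- data.table::as.data.table(women)
  if (!"woman_id" %in% names(dt)) dt[, woman_id := seq_len(.N)]
  for (nm in names(defaults)) {
    if (!nm %in% names(dt)) dt[, (nm) := defaults[[nm]]]
  }
  # invasive_onset defaults to onset_age for non-DCIS tumors, onset + dwell
  # for progressing DCIS, NA otherwise (mirrors the sampler).
  if (!"invasive_onset" %in% names(women)) {
    dt[has_tumor & !(starts_as_dcis %in% TRUE), invasive_onset := onset_age]
    dt[has_tumor & starts_as_dcis %in% TRUE &
         dcis_fate == "progress_to_invasive",
       invasive_onset := onset_age + dcis_dwell]
  }
  data.table::setcolorder(dt, c("woman_id", names(defaults)))
  data.table::setattr(dt, "params", params)
  data.table::setattr(dt, "seed", as.integer(seed))
  data.table::setattr(dt, "class", c("life_histories", class(dt)))
  dt[]
}

# One invasive tumor with fully specified biology.
one_invasive <- function(onset_age, growth_rate, d_clinical, d_fatal,
                         survival_after_fatal = 2, age_ocd = 100,
                         u_detect = 0.5) {
  data.frame(has_tumor = TRUE, onset_age = onset_age,
             growth_rate = growth_rate, d_clinical = d_clinical,
             d_fatal = d_fatal, starts_as_dcis = FALSE,
             survival_after_fatal = survival_after_fatal,
             age_other_cause_death = age_ocd, u_detect = u_detect)
}

# Small shared simulated pair used by several files (built once per run).
shared_sim <- local({
  cache <- NULL
  function(n = 20000, seed = 7) {
    if (is.null(cache)) {
      cohort <- sample_life_histories(n, natural_history_params(),
                                      seed = seed)
      cache <<- list(cohort = cohort, control = natural_course(cohort))
    }
    cache
  }
})

# An always-negative test: sees nothing, never falsely positive.
null_test <- function() test_characteristics(0, 1e6, 1.0, label = "null")
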