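#' Simulate a cohort of life histories
#'
#' Draws `n` women born in 1970. Each woman gets an other-cause death age from
#' the life table; with probability `lifetime_bc_risk` she also gets a tumor
#' with its full biology: onset age, exponential growth rate, per-tumor
#' clinical and fatal threshold diameters, the DCIS state (fraction, fate,
#' pre-clinical dwell), survival time after the fatal diameter is crossed,
#' and two uniform variates (`u_detect`, `u_dcis_detect`) that downstream
#' screening scenarios transform into the scenario-specific screen-detection
#' threshold and the DCIS screen-detection round. Storing uniforms rather
#' than realised values makes every scenario a deterministic function of the
#' same cohort: changing a test's median detection size, DCIS sensitivity or
#' specificity re-uses identical natural-history draws (common random
#' numbers), which is what makes parallel-universe contrasts exact.
#'
#' Draws come from named substreams (`mortality`, `onset`, `biology`,
#' `screening`, `survival`) derived from `seed`, so the same `(n, params,
#' seed)` always reproduces the same cohort.
#'
#' @param n Number of women (>= 1).
#' @param params An [natural_history_params()] object.
#' @param seed Integer master seed.
#' @return A `data.table` of class `life_histories`, one row per woman.
#'   Columns: `woman_id`, `birth_year`, `age_other_cause_death`, `has_tumor`,
#'   and for tumor rows `onset_age`, `growth_rate`, `d_clinical`, `d_fatal`,
#'   `starts_as_dcis`, `dcis_fate`, `dcis_dwell`, `invasive_onset` (onset age
#'   of the invasive phase: onset for invasive tumors, onset + dwell for
#'   progressing DCIS, `NA` otherwise), `survival_after_fatal`, `u_detect`,
#'   `u_dcis_detect` (non-tumor rows hold `NA`). Attributes `params` and
#'   `seed` record provenance.
#' @export
#' @examples
#' cohort <- sample_life_histories(500, natural_history_params(), seed = 1)
#' mean(cohort$has_tumor)
sample_life_histories <- function(n, params, seed = 1L) {
  if (!inherits(params, "nh_params")) params <- do.call(natural_history_params, params)
  validate_nh_params(params)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)

  age_ocd <- with_stream(seed, "mortality",
                         sample_other_cause_death(n, params$life_table))
  has_tumor <- with_stream(seed, "onset",
                           runif(n) < params$lifetime_bc_risk)
  nt <- sum(has_tumor)

  cohort <- data.table(
    woman_id = seq_len(n),
    birth_year = 1970L,
    age_other_cause_death = age_ocd,
    has_tumor = has_tumor,
    onset_age = NA_real_, growth_rate = NA_real_,
    d_clinical = NA_real_, d_fatal = NA_real_,
    starts_as_dcis = NA, dcis_fate = NA_character_, dcis_dwell = NA_real_,
    invasive_onset = NA_real_, survival_after_fatal = NA_real_,
    u_detect = NA_real_, u_dcis_detect = NA_real_
  )

  if (nt > 0L) {
    bio <- with_stream(seed, "biology", {
      onset <- rtruncnorm(nt, params$onset_age_mean, params$onset_age_sd,
                          params$onset_age_range[1], params$onset_age_range[2])
      g <- rlnorm(nt, params$growth_rate_meanlog, params$growth_rate_sdlog)
      d_clin <- pmax(rlnorm(nt, params$clinical_diameter_meanlog,
                            params$clinical_diameter_sdlog),
                     params$onset_diameter * 1.01)
      d_fat <- pmax(rlnorm(nt, params$fatal_diameter_meanlog,
                           params$fatal_diameter_sdlog),
                    params$onset_diameter * 1.01)
      dcis <- runif(nt) < params$dcis_onset_fraction
      fate_u <- runif(nt)
      fp <- params$dcis_fate_probs[c("regress", "progress_to_invasive",
                                     "clinical_dcis")]
      fate <- names(fp)[findInterval(fate_u, cumsum(fp), left.open = TRUE) + 1L]
      fate[!dcis] <- NA_character_
      dwell <- rlnorm(nt, params$dcis_dwell_meanlog, params$dcis_dwell_sdlog)
      dwell[!dcis] <- NA_real_
      u_det <- runif(nt)
      list(onset = onset, g = g, d_clin = d_clin, d_fat = d_fat,
           dcis = dcis, fate = fate, dwell = dwell, u_det = u_det)
    })
    u_dcis <- with_stream(seed, "screening", runif(nt))
    surv <- with_stream(seed, "survival",
                        rexp(nt, rate = 1 / params$survival_after_fatal_mean))

    inv_onset <- bio$onset
    inv_onset[bio$dcis] <- NA_real_
    prog <- bio$dcis & bio$fate == "progress_to_invasive"
    inv_onset[prog] <- bio$onset[prog] + bio$dwell[prog]

    idx <- which(has_tumor)
    set(cohort, idx, "onset_age", bio$onset)
    set(cohort, idx, "growth_rate", bio$g)
    set(cohort, idx, "d_clinical", bio$d_clin)
    set(cohort, idx, "d_fatal", bio$d_fat)
    set(cohort, idx, "starts_as_dcis", bio$dcis)
    set(cohort, idx, "dcis_fate", bio$fate)
    set(cohort, idx, "dcis_dwell", bio$dwell)
    set(cohort, idx, "invasive_onset", inv_onset)
    set(cohort, idx, "survival_after_fatal", surv)
    set(cohort, idx, "u_detect", bio$u_det)
    set(cohort, idx, "u_dcis_detect", u_dcis)
  }

  setattr(cohort, "params", params)
  setattr(cohort, "seed", as.integer(seed))
  setattr(cohort, "class", c("life_histories", class(cohort)))
  cohort[]
}

#' @export
print.life_histories <- function(x, ...) {
  cat(sprintf("<life_histories> %d women born 1970 (seed %s)\n",
              nrow(x), attr(x, "seed")))
  cat(sprintf("  %d with a tumor (%.1f%%), of whom %d start as DCIS\n",
              sum(x$has_tumor), 100 * mean(x$has_tumor),
              sum(x$starts_as_dcis, na.rm = TRUE)))
  NextMethod()
}

# Inverse-CDF truncated normal (exact, no rejection).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Sample death ages from a piecewise-constant annual hazard table.
sample_other_cause_death <- function(n, life_table) {
  h <- life_table$hazard
  a0 <- life_table$age[1]
  H <- c(0, cumsum(h))               # cumulative hazard at integer ages
  e <- -log(runif(n))                # unit-exponential total hazards
  k <- findInterval(e, H, rightmost.closed = FALSE)  # 1-based interval
  k <- pmin(k, length(h))
  age <- a0 + (k - 1) + (e - H[k]) / h[k]
  pmin(age, a0 + length(h))
}

#' Weibull screen-detectability thresholds
#'
#' Each tumor's screen-detectability threshold diameter is Weibull with a
#' scale chosen so that the distribution's *median* equals the screening
#' test's median detection size: `scale = median_size / log(2)^(1/shape)`.
#' `sample_detection_threshold()` draws fresh thresholds;
#' `detection_threshold_quantile()` maps a stored uniform variate to a
#' threshold (the common-random-numbers path used by [apply_screening()]);
#' `weibull_scale_from_median()` exposes the scale conversion.
#'
#' @param n Number of draws.
#' @param median_size Median detection size, cm (> 0).
#' @param shape Weibull shape (> 0).
#' @return Threshold diameters in cm.
#' @export
#' @examples
#' x <- sample_detection_threshold(1e4, median_size = 1.21, shape = 2)
#' median(x)  # ~1.21
sample_detection_threshold <- function(n, median_size, shape) {
  detection_threshold_quantile(runif(n), median_size, shape)
}

#' @rdname sample_detection_threshold
#' @param u Uniform(0,1) variates.
#' @export
detection_threshold_quantile <- function(u, median_size, shape) {
  qweibull(u, shape = shape,
           scale = weibull_scale_from_median(median_size, shape))
}

#' @rdname sample_detection_threshold
#' @export
weibull_scale_from_median <- function(median_size, shape) {
  if (any(median_size <= 0) || any(shape <= 0))
    stop("median_size and shape must be positive", call. = FALSE)
  median_size / log(2)^(1 / shape)
}

#' Tumor diameter along the exponential growth curve
#'
#' `diameter_at_age()` gives the diameter of a tumor at a given age;
#' `age_at_diameter()` is its closed-form inverse (the age at which the tumor
#' crosses a diameter). Growth is exponential in diameter from
#' `onset_diameter` at the (invasive) onset age:
#' `d(t) = onset_diameter * exp(growth_rate * (t - onset_age))`.
#'
#' @param age Age in years (vectorised); must be at or after `onset_age`.
#' @param onset_age Invasive onset age (years).
#' @param growth_rate Exponential growth rate (per year, > 0).
#' @param onset_diameter Diameter at onset, cm (default 0.01).
#' @return Diameter in cm, or age in years for the inverse.
#' @export
#' @examples
#' diameter_at_age(55, onset_age = 50, growth_rate = log(2))  # five doublings
#' age_at_diameter(1.21, onset_age = 50, growth_rate = 0.5)
diameter_at_age <- function(age, onset_age, growth_rate, onset_diameter = 0.01) {
  if (any(age < onset_age, na.rm = TRUE))
    stop("age precedes tumor onset", call. = FALSE)
  onset_diameter * exp(growth_rate * (age - onset_age))
}

#' @rdname diameter_at_age
#' @param diameter Target diameter, cm (>= `onset_diameter`).
#' @export
age_at_diameter <- function(diameter, onset_age, growth_rate,
                            onset_diameter = 0.01) {
  if (any(diameter < onset_diameter, na.rm = TRUE))
    stop("diameter below onset diameter", call. = FALSE)
  onset_age + log(diameter / onset_diameter) / growth_rate
}

#' Export a cohort as CSV
#'
#' One row per woman with the column dictionary of
#' [sample_life_histories()].
#'
#' @param cohort A `life_histories` table.
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  fwrite(as.data.table(cohort), path)
  invisible(path)
}
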