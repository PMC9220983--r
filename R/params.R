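#' Natural-history model parameters
#'
#' Bundles every parameter of the fatal-diameter natural-history model into a
#' validated configuration object. The defaults describe a 1970 birth cohort
#' of US women with a 13% lifetime risk of breast cancer; tumor onset ages,
#' growth rates, threshold diameters and the DCIS compartment are
#' parameterised by standard parametric families (truncated normal for onset
#' age, lognormal for growth rates, diameters and DCIS dwell, exponential for
#' survival after the fatal diameter is crossed). The defaults were calibrated
#' once so that a comparator test with a 1.21 cm median detection size and 91%
#' DCIS sensitivity, applied biennially at ages 50-74, screen-detects close to
#' 70% of invasive cancers and 89% of DCIS diagnosed in that age window; see
#' the methods vignette.
#'
#' @param lifetime_bc_risk Probability that a woman ever develops a breast
#'   tumor (invasive or DCIS). Default 0.13.
#' @param onset_age_mean,onset_age_sd Mean and SD (years) of the normal tumor
#'   onset-age distribution, truncated to `onset_age_range`.
#' @param onset_age_range Two ages (years) bounding tumor onset.
#' @param growth_rate_meanlog,growth_rate_sdlog Lognormal parameters of the
#'   exponential diameter growth rate (per year). The diameter of a tumor
#'   `t` years after (invasive) onset is `0.01 * exp(rate * t)` cm.
#' @param detect_threshold_shape Weibull shape of the per-tumor
#'   screen-detectability threshold diameter. The scale is set per scenario so
#'   that the Weibull median equals the test's median detection size.
#' @param clinical_diameter_meanlog,clinical_diameter_sdlog Lognormal
#'   parameters of the per-tumor clinical-diagnosis diameter (cm).
#' @param fatal_diameter_meanlog,fatal_diameter_sdlog Lognormal parameters of
#'   the per-tumor fatal diameter (cm): once the tumor passes it, detection
#'   no longer prevents breast-cancer death.
#' @param dcis_onset_fraction Probability that a tumor starts as ductal
#'   carcinoma in situ (DCIS) rather than invasive disease.
#' @param dcis_fate_probs Named probabilities (`regress`,
#'   `progress_to_invasive`, `clinical_dcis`) of the three DCIS fates; must
#'   sum to 1.
#' @param dcis_dwell_meanlog,dcis_dwell_sdlog Lognormal parameters of the
#'   pre-clinical DCIS dwell time (years) during which the lesion is
#'   screen-detectable.
#' @param survival_after_fatal_mean Mean (years) of the exponential survival
#'   time from the fatal-diameter crossing to breast-cancer death.
#' @param life_table Other-cause mortality life table: a data frame with
#'   columns `age` and `hazard` (annual hazard, piecewise constant on
#'   `[age, age + 1)`). Default [default_life_table()].
#' @param onset_diameter Tumor diameter at onset, cm. Fixed at 0.01 by the
#'   model family; changing it changes the meaning of all thresholds.
#'
#' @return An object of class `nh_params` (a named list).
#' @seealso [sample_life_histories()], [read_nh_params()]
#' @export
#' @examples
#' p <- natural_history_params()
#' p$lifetime_bc_risk
natural_history_params <- function(lifetime_bc_risk = 0.13,
                                   onset_age_mean = 52,
                                   onset_age_sd = 12,
                                   onset_age_range = c(25, 90),
                                   growth_rate_meanlog = log(0.55),
                                   growth_rate_sdlog = 0.40,
                                   detect_threshold_shape = 2,
                                   clinical_diameter_meanlog = log(2.85),
                                   clinical_diameter_sdlog = 0.35,
                                   fatal_diameter_meanlog = log(2.4),
                                   fatal_diameter_sdlog = 0.90,
                                   dcis_onset_fraction = 0.30,
                                   dcis_fate_probs = c(
                                     regress = 0.50,
                                     progress_to_invasive = 0.25,
                                     clinical_dcis = 0.25
                                   ),
                                   dcis_dwell_meanlog = log(1.5),
                                   dcis_dwell_sdlog = 0.60,
                                   survival_after_fatal_mean = 3,
                                   life_table = default_life_table(),
                                   onset_diameter = 0.01) {
  p <- list(
    lifetime_bc_risk = lifetime_bc_risk,
    onset_age_mean = onset_age_mean,
    onset_age_sd = onset_age_sd,
    onset_age_range = onset_age_range,
    growth_rate_meanlog = growth_rate_meanlog,
    growth_rate_sdlog = growth_rate_sdlog,
    detect_threshold_shape = detect_threshold_shape,
    clinical_diameter_meanlog = clinical_diameter_meanlog,
    clinical_diameter_sdlog = clinical_diameter_sdlog,
    fatal_diameter_meanlog = fatal_diameter_meanlog,
    fatal_diameter_sdlog = fatal_diameter_sdlog,
    dcis_onset_fraction = dcis_onset_fraction,
    dcis_fate_probs = dcis_fate_probs,
    dcis_dwell_meanlog = dcis_dwell_meanlog,
    dcis_dwell_sdlog = dcis_dwell_sdlog,
    survival_after_fatal_mean = survival_after_fatal_mean,
    life_table = life_table,
    onset_diameter = onset_diameter
  )
  class(p) <- "nh_params"
  validate_nh_params(p)
  p
}

validate_nh_params <- function(p) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid natural-history configuration: '%s' %s", field, msg),
         call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_cfg(field, "must be a positive number")
  }
  chk_num <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop_cfg(field, "must be a finite number")
  }
  chk_prob("lifetime_bc_risk")
  chk_prob("dcis_onset_fraction")
  chk_num("onset_age_mean"); chk_pos("onset_age_sd")
  chk_num("growth_rate_meanlog"); chk_pos("growth_rate_sdlog")
  chk_pos("detect_threshold_shape")
  chk_num("clinical_diameter_meanlog"); chk_pos("clinical_diameter_sdlog")
  chk_num("fatal_diameter_meanlog"); chk_pos("fatal_diameter_sdlog")
  chk_num("dcis_dwell_meanlog"); chk_pos("dcis_dwell_sdlog")
  chk_pos("survival_after_fatal_mean")
  chk_pos("onset_diameter")
  if (length(p$onset_age_range) != 2L || diff(p$onset_age_range) <= 0)
    stop_cfg("onset_age_range", "must be two increasing ages")
  fp <- p$dcis_fate_probs
  want <- c("regress", "progress_to_invasive", "clinical_dcis")
  if (is.null(names(fp)) || !setequal(names(fp), want))
    stop_cfg("dcis_fate_probs",
             "must be named regress / progress_to_invasive / clinical_dcis")
  if (any(fp < 0) || any(fp > 1))
    stop_cfg("dcis_fate_probs", "entries must be probabilities")
  if (abs(sum(fp) - 1) > 1e-12)
    stop_cfg("dcis_fate_probs", "must sum to 1 (within 1e-12)")
  lt <- p$life_table
  if (!is.data.frame(lt) || !all(c("age", "hazard") %in% names(lt)))
    stop_cfg("life_table", "must be a data frame with columns age, hazard")
  if (any(lt$hazard < 0) || any(diff(lt$age) != 1))
    stop_cfg("life_table", "requires consecutive integer ages and hazards >= 0")
  invisible(p)
}

#' @export
print.nh_params <- function(x, ...) {
  cat("<nh_params> fatal-diameter natural-history configuration\n")
  cat(sprintf("  lifetime risk %.3f | DCIS fraction %.2f (fates: %s)\n",
              x$lifetime_bc_risk, x$dcis_onset_fraction,
              paste(sprintf("%s %.2f", sub("_to_invasive", "",
                                           names(x$dcis_fate_probs)),
                            x$dcis_fate_probs), collapse = ", ")))
  cat(sprintf("  onset age ~ N(%.0f, %.0f) on [%g, %g]; growth rate ~ LN(%.3f, %.2f)\n",
              x$onset_age_mean, x$onset_age_sd, x$onset_age_range[1],
              x$onset_age_range[2], x$growth_rate_meanlog, x$growth_rate_sdlog))
  cat(sprintf("  clinical diameter median %.2f cm; fatal diameter median %.2f cm\n",
              exp(x$clinical_diameter_meanlog), exp(x$fatal_diameter_meanlog)))
  cat(sprintf("  life table ages %d-%d\n", min(x$life_table$age),
              max(x$life_table$age)))
  invisible(x)
}

#' Synthetic other-cause mortality life table
#'
#' Builds a Gompertz-Makeham annual-hazard life table,
#' `h(x) = makeham + b * exp(c * x)`, approximating other-cause (non breast
#' cancer) mortality for a US female birth cohort of 1970. This is a
#' synthetic stand-in parameterisation, not a published life table; the
#' defaults give a life expectancy near 80 years. The hazard at `max_age` is
#' set high enough that no simulated woman survives past `max_age + 1`.
#'
#' @param makeham Age-independent hazard component (per year).
#' @param b,c Gompertz baseline and log-slope.
#' @param max_age Last age row (death is certain in `[max_age, max_age + 1)`).
#' @return A data.frame with columns `age` (0, 1, ..., `max_age`) and
#'   `hazard` (annual hazard on `[age, age + 1)`).
#' @export
#' @examples
#' lt <- default_life_table()
#' head(lt)
default_life_table <- function(makeham = 4e-4, b = 2.6e-5, c = 0.102,
                               max_age = 109) {
  age <- 0:max_age
  hazard <- makeham + b * exp(c * age)
  hazard[length(hazard)] <- 50  # close out the table: certain death
  data.frame(age = age, hazard = hazard)
}

#' Read or write a life table as two-column CSV
#'
#' @param path CSV file with columns `age`, `hazard`.
#' @return `read_life_table()` returns the life-table data.frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "hazard") %in% names(lt)))
    stop("life table CSV must have columns 'age' and 'hazard'", call. = FALSE)
  lt[, c("age", "hazard")]
}

#' @rdname read_life_table
#' @param life_table A life-table data.frame.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table[, c("age", "hazard")], path, row.names = FALSE)
  invisible(path)
}

#' Read natural-history parameters from a YAML/JSON configuration file
#'
#' Any field of [natural_history_params()] may appear in the file; omitted
#' fields keep their defaults. A `life_table` entry, if present, must be a
#' path (relative to the config file) to a two-column CSV read by
#' [read_life_table()].
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return An `nh_params` object.
#' @export
read_nh_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(natural_history_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown natural-history configuration field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$life_table) && is.character(cfg$life_table)) {
    lt_path <- cfg$life_table
    if (!file.exists(lt_path))
      lt_path <- file.path(dirname(path), cfg$life_table)
    cfg$life_table <- read_life_table(lt_path)
  }
  if (!is.null(cfg$dcis_fate_probs)) cfg$dcis_fate_probs <- unlist(cfg$dcis_fate_probs)
  if (!is.null(cfg$onset_age_range)) cfg$onset_age_range <- unlist(cfg$onset_age_range)
  do.call(natural_history_params, cfg)
}

# Deterministic per-module random substreams: each named stream gets its own
# 32-bit seed derived from the master seed, so e.g. redrawing screening-stage
# variates never perturbs natural-history variates.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 65521L)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}
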