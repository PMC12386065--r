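#' Calibration spec for a paired-measurement cohort
#'
#' Describes one cohort of paired (manual, automatic) strain measurements by
#' its printed summary statistics: the two method means and SDs plus the SD
#' of the paired differences. Under a bivariate-normal model these five
#' numbers fix the joint distribution, since
#' `var(d) = var(m) + var(a) - 2 cov(m, a)` implies
#' `cov = (sd_manual^2 + sd_auto^2 - sd_diff^2) / 2`.
#'
#' The spec is validated for feasibility: `sd_diff` must lie between
#' `|sd_manual - sd_auto|` and `sd_manual + sd_auto`, otherwise no bivariate
#' distribution with these moments exists.
#'
#' @param label Cohort label, e.g. `"af"` or `"sinus"`.
#' @param n Number of patients.
#' @param mean_manual,sd_manual Manual-method mean and SD (%).
#' @param mean_auto,sd_auto Automatic-method mean and SD (%).
#' @param sd_diff SD of the paired differences (%).
#' @param seed Integer seed used by the generator.
#' @return Object of class `cohort_spec`.
#' @examples
#' af_cohort_spec()
#' @export
cohort_spec <- function(label, n, mean_manual, sd_manual,
                        mean_auto, sd_auto, sd_diff,
                        seed = 20250819L) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (sd_manual < 0 || sd_auto < 0 || sd_diff < 0) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  lo <- abs(sd_manual - sd_auto)
  hi <- sd_manual + sd_auto
  if (sd_diff < lo - 1e-12) {
    stop(sprintf(
      "infeasible spec: sd_diff (%g) < |sd_manual - sd_auto| (%g)",
      sd_diff, lo), call. = FALSE)
  }
  if (sd_diff > hi + 1e-12) {
    stop(sprintf(
      "infeasible spec: sd_diff (%g) > sd_manual + sd_auto (%g)",
      sd_diff, hi), call. = FALSE)
  }
  structure(
    list(label = label, n = as.integer(n),
         mean_manual = mean_manual, sd_manual = sd_manual,
         mean_auto = mean_auto, sd_auto = sd_auto,
         sd_diff = sd_diff, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default cohort calibrations
#'
#' The two study conditions the simulator emulates: an atrial-fibrillation
#' cohort with markedly reduced reservoir strain (manual 6.53 +/- 2.2%,
#' automatic 6.4 +/- 2.3%, difference SD 0.71%) and a sinus-rhythm cohort
#' with normal strain (manual 29.5 +/- 4.35%, automatic 30.3 +/- 4.68%,
#' difference SD 1.64%), 30 patients each.
#'
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
af_cohort_spec <- function(seed = 20250819L) {
  cohort_spec("af", 30, mean_manual = 6.53, sd_manual = 2.2,
              mean_auto = 6.4, sd_auto = 2.3, sd_diff = 0.71, seed = seed)
}

#' @rdname af_cohort_spec
#' @export
sinus_cohort_spec <- function(seed = 20250819L) {
  cohort_spec("sinus", 30, mean_manual = 29.5, sd_manual = 4.35,
              mean_auto = 30.3, sd_auto = 4.68, sd_diff = 1.64, seed = seed)
}

#' Correlation implied by a cohort spec
#'
#' Closed form from the summary moments:
#' `r = (sd_manual^2 + sd_auto^2 - sd_diff^2) / (2 sd_manual sd_auto)`.
#'
#' @param spec A [cohort_spec].
#' @return The implied Pearson correlation.
#' @examples
#' implied_correlation(af_cohort_spec())  # 0.951
#' @export
implied_correlation <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cov <- (spec$sd_manual^2 + spec$sd_auto^2 - spec$sd_diff^2) / 2
  cov / (spec$sd_manual * spec$sd_auto)
}

#' Generate a paired bivariate-normal cohort
#'
#' Draws `n` (manual, automatic) strain pairs from the bivariate normal
#' distribution with the spec's means, SDs and implied covariance.
#' Deterministic for a fixed seed; the global RNG state is left untouched.
#' Negative draws are kept (truncation would distort the calibrated moments);
#' a message counts them when present.
#'
#' @param spec A [cohort_spec].
#' @param n Override the spec's sample size (e.g. for convergence checks).
#' @param seed Override the spec's seed.
#' @return Data frame with columns `patient_id`, `group`, `manual_lasr_pct`,
#'   `auto_lasr_pct`.
#' @export
generate_paired_cohort <- function(spec, n = spec$n, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n == 0) {
    return(data.frame(patient_id = character(), group = character(),
                      manual_lasr_pct = numeric(),
                      auto_lasr_pct = numeric()))
  }
  rho <- implied_correlation(spec)
  sigma <- matrix(c(spec$sd_manual^2,
                    rho * spec$sd_manual * spec$sd_auto,
                    rho * spec$sd_manual * spec$sd_auto,
                    spec$sd_auto^2), 2, 2)
  draws <- .with_seed(seed, MASS::mvrnorm(
    n, mu = c(spec$mean_manual, spec$mean_auto), Sigma = sigma))
  draws <- matrix(draws, ncol = 2)  # mvrnorm drops dims at n = 1
  n_neg <- sum(draws < 0)
  if (n_neg > 0) {
    message(sprintf("%d negative simulated strain value(s) kept", n_neg))
  }
  data.frame(
    patient_id = sprintf("%s-%04d", spec$label, seq_len(n)),
    group = spec$label,
    manual_lasr_pct = draws[, 1],
    auto_lasr_pct = draws[, 2])
}

#' Calibration spec for duplicate (test-retest) measurements
#'
#' Subjects' true values are drawn from `Normal(grand_mean, sd_between^2)`;
#' each of the `m` repeats adds independent `Normal(0, sw^2)` measurement
#' noise. `sw` is the within-subject SD, related to the repeatability
#' coefficient by `RC = 1.96 * sqrt(2) * sw`.
#'
#' @param n Number of subjects.
#' @param grand_mean Population mean (%).
#' @param sd_between Between-subject SD (%).
#' @param sw Within-subject SD (%).
#' @param seed Integer seed.
#' @return Object of class `duplicate_spec`.
#' @export
duplicate_spec <- function(n, grand_mean, sd_between, sw,
                           seed = 20250819L) {
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (sd_between < 0 || sw < 0) {
    stop("`sd_between` and `sw` must be non-negative", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), grand_mean = grand_mean,
         sd_between = sd_between, sw = sw, seed = as.integer(seed)),
    class = "duplicate_spec")
}

#' Default repeatability calibrations
#'
#' Four duplicate-measurement specs for a 15-patient reproducibility subset
#' per cohort and method. Within-subject SDs are back-solved from the target
#' repeatability coefficients as `sw = RC / (1.96 * sqrt(2))`: manual / auto
#' RC of 0.82 / 0.70 in the AF cohort and 10.53 / 5.66 in sinus rhythm.
#' Between-subject SDs and grand means reuse the cohort calibrations.
#'
#' @param seed Integer seed (consecutive seeds are assigned to the four specs).
#' @return Named list of [duplicate_spec] objects:
#'   `af_manual`, `af_auto`, `sinus_manual`, `sinus_auto`.
#' @export
repeatability_specs <- function(seed = 20250819L) {
  k <- 1.96 * sqrt(2)
  list(
    af_manual = duplicate_spec(15, 6.53, 2.2, 0.82 / k, seed = seed),
    af_auto = duplicate_spec(15, 6.4, 2.3, 0.70 / k, seed = seed + 1L),
    sinus_manual = duplicate_spec(15, 29.5, 4.35, 10.53 / k, seed = seed + 2L),
    sinus_auto = duplicate_spec(15, 30.3, 4.68, 5.66 / k, seed = seed + 3L))
}

#' Generate duplicate measurements
#'
#' @param spec A [duplicate_spec].
#' @param m Number of repeats per subject, default 2.
#' @param n,seed Overrides of the spec's values.
#' @return `n x m` numeric matrix, one subject per row.
#' @export
generate_duplicates <- function(spec, m = 2L, n = spec$n, seed = spec$seed) {
  stopifnot(inherits(spec, "duplicate_spec"))
  .with_seed(seed, {
    truth <- stats::rnorm(n, spec$grand_mean, spec$sd_between)
    noise <- matrix(stats::rnorm(n * m, 0, spec$sw), n, m)
    truth + noise
  })
}

#' Attach clinical covariates to a simulated cohort
#'
#' The default scheme draws, per cohort, LAVi, EF and age from normal
#' marginals matching typical AF vs sinus clinical profiles (AF: LAVi
#' 56.7 +/- 19.7 mL/m^2, EF 47.8 +/- 10.5%, age 79.1 +/- 8.7 y; sinus: LAVi
#' 31.1 +/- 10.4, EF 60.5 +/- 1.5, age 47.4 +/- 20.9), and assigns sex
#' without replacement so that a 30-patient group contains exactly 19 males.
#' EF and age are clipped to plausible ranges (EF 10-80%, age 18-100 y).
#'
#' @param df Cohort data frame from [generate_paired_cohort()] (needs a
#'   `group` column with values `"af"` / `"sinus"`).
#' @param scheme Covariate scheme; only `"default"` is defined.
#' @param seed Integer seed.
#' @return `df` with columns `lavi_ml_m2`, `ef_pct`, `age_years`, `sex`
#'   appended.
#' @export
generate_covariates <- function(df, scheme = "default", seed = 20250819L) {
  if (!identical(scheme, "default")) {
    stop(sprintf("unknown covariate scheme \"%s\"", scheme), call. = FALSE)
  }
  if (!"group" %in% names(df)) stop("`df` needs a `group` column",
                                    call. = FALSE)
  marg <- list(
    af = list(lavi = c(56.7, 19.7), ef = c(47.8, 10.5),
              age = c(79.1, 8.7), n_male = 19L, n_total = 30L),
    sinus = list(lavi = c(31.1, 10.4), ef = c(60.5, 1.5),
                 age = c(47.4, 20.9), n_male = 19L, n_total = 30L))
  .with_seed(seed, {
    df$lavi_ml_m2 <- NA_real_
    df$ef_pct <- NA_real_
    df$age_years <- NA_real_
    df$sex <- NA_character_
    for (g in unique(df$group)) {
      if (!g %in% names(marg)) {
        stop(sprintf("no covariate marginals defined for group \"%s\"", g),
             call. = FALSE)
      }
      idx <- which(df$group == g)
      mg <- marg[[g]]
      ng <- length(idx)
      df$lavi_ml_m2[idx] <- pmax(
        stats::rnorm(ng, mg$lavi[1], mg$lavi[2]), 5)
      df$ef_pct[idx] <- pmin(pmax(
        stats::rnorm(ng, mg$ef[1], mg$ef[2]), 10), 80)
      df$age_years[idx] <- pmin(pmax(
        stats::rnorm(ng, mg$age[1], mg$age[2]), 18), 100)
      # sex sampled without replacement: exact male count per full group
      n_male <- round(mg$n_male * ng / mg$n_total)
      df$sex[idx] <- sample(rep(c("m", "f"), c(n_male, ng - n_male)))
    }
    df
  })
}

#' Back-solve caliper lengths from a target biplane strain
#'
#' Produces a four-length tuple whose biplane reservoir strain equals the
#' given value, by fixing the two systolic lengths and setting each diastolic
#' length to `Ls * (1 - s)` with `s` the target strain fraction, so both
#' planes carry the same strain. This is cosmetic plumbing for writing
#' measurement-table fixtures: the lengths are plausible, not patient data.
#'
#' @param strain_pct Target biplane strain, %.
#' @param ls4c,ls2c Fixed systolic lengths, cm (defaults 6.0 and 5.5, typical
#'   adult LA long-axis lengths).
#' @return Data frame with columns `ls4c_cm`, `ld4c_cm`, `ls2c_cm`,
#'   `ld2c_cm`. Vectorised over `strain_pct`.
#' @export
lengths_from_strain <- function(strain_pct, ls4c = 6.0, ls2c = 5.5) {
  s <- strain_pct / 100
  data.frame(ls4c_cm = rep(ls4c, length(s)),
             ld4c_cm = ls4c * (1 - s),
             ls2c_cm = rep(ls2c, length(s)),
             ld2c_cm = ls2c * (1 - s))
}

#' Write a simulated study to the measurement-table CSV schema
#'
#' Builds the full measurement table for a simulated two-cohort study:
#' caliper lengths back-solved from the simulated manual strain (see
#' [lengths_from_strain()]), the automatic reference strain, and covariates.
#' Numeric columns are written with 6 significant digits.
#'
#' @param df Cohort data frame with covariates attached.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_measurement_csv <- function(df, path) {
  lens <- lengths_from_strain(df$manual_lasr_pct)
  out <- cbind(df[c("patient_id", "group")], lens,
               df[intersect(c("auto_lasr_pct", "lavi_ml_m2", "ef_pct",
                              "age_years", "sex"), names(df))])
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write duplicate measurements in long format
#'
#' Columns: `patient_id`, `method`, `repeat_index`, `value_pct`.
#'
#' @param mats Named list of duplicate matrices (name = method label).
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_duplicates_csv <- function(mats, path) {
  rows <- lapply(names(mats), function(method) {
    x <- mats[[method]]
    data.frame(
      patient_id = rep(sprintf("%s-%04d", method, seq_len(nrow(x))),
                       ncol(x)),
      method = method,
      repeat_index = rep(seq_len(ncol(x)), each = nrow(x)),
      value_pct = signif(as.vector(x), 6))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
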