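#' Read a measurement table CSV
#'
#' Expected schema (header row required, decimal point, UTF-8): columns
#' `patient_id`, `group` (values `af` / `sinus`), the four caliper lengths
#' `ls4c_cm`, `ld4c_cm`, `ls2c_cm`, `ld2c_cm`, the automated reference
#' `auto_lasr_pct`, and optionally `lavi_ml_m2`, `ef_pct`, `age_years`,
#' `sex` (`m` / `f`) plus the planimetry/LV columns consumed by the index
#' helpers. Alternatively a precomputed `manual_lasr_pct` column may replace
#' the four lengths.
#'
#' Schema violations are collected and reported together, each with its row
#' number.
#'
#' @param path CSV file path.
#' @return Data frame with validated columns.
#' @export
read_strain_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  errors <- character()
  need <- c("patient_id", "group", "auto_lasr_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    errors <- c(errors, paste("missing required column(s):",
                              paste(miss, collapse = ", ")))
  }
  len_cols <- c("ls4c_cm", "ld4c_cm", "ls2c_cm", "ld2c_cm")
  has_lengths <- all(len_cols %in% names(df))
  if (!has_lengths && !"manual_lasr_pct" %in% names(df)) {
    errors <- c(errors, paste(
      "need either the four length columns",
      paste(len_cols, collapse = ", "), "or `manual_lasr_pct`"))
  }
  if (!length(errors)) {
    if (any(bad <- !df$group %in% c("af", "sinus"))) {
      errors <- c(errors, sprintf(
        "row %d: group \"%s\" not one of af/sinus",
        which(bad), df$group[bad]))
    }
    num_cols <- intersect(c(len_cols, "auto_lasr_pct", "manual_lasr_pct",
                            "lavi_ml_m2", "ef_pct", "age_years"), names(df))
    for (cc in num_cols) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      if (any(bad <- is.na(v) & !is.na(df[[cc]]))) {
        errors <- c(errors, sprintf("row %d: %s is not numeric (\"%s\")",
                                    which(bad), cc, df[[cc]][bad]))
      }
      df[[cc]] <- v
    }
    if (has_lengths) {
      for (cc in len_cols) {
        if (any(bad <- !is.na(df[[cc]]) & df[[cc]] <= 0)) {
          errors <- c(errors, sprintf("row %d: %s must be positive (%g)",
                                      which(bad), cc, df[[cc]][bad]))
        }
      }
    }
    if ("sex" %in% names(df) &&
        any(bad <- !df$sex %in% c("m", "f", NA))) {
      errors <- c(errors, sprintf("row %d: sex \"%s\" not one of m/f",
                                  which(bad), df$sex[bad]))
    }
  }
  if (length(errors)) {
    stop("measurement table failed validation:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Run the full validation analysis
#'
#' Orchestrates the study end-to-end: simulate the two calibrated cohorts (or
#' ingest a measurement table), compute manual biplane strain from the
#' caliper lengths, and produce per-group, overall and subgroup agreement
#' analyses plus test-retest repeatability.
#'
#' Per-group reports use the `"group"` SEM convention and the overall report
#' the `"pooled"` convention by default; both are configurable and labelled
#' in the output. The overall report adds `mdc_pct_of_mean`, the MDC95 as a
#' percentage of the grand mean strain.
#'
#' @param input Path to a measurement CSV ([read_strain_csv()] schema), or
#'   `NULL` to simulate.
#' @param specs List of [cohort_spec]s to simulate (ignored when `input` is
#'   given; exactly one of the two must be in effect). Defaults to the AF and
#'   sinus calibrations.
#' @param duplicate_specs Named list of [duplicate_spec]s for repeatability
#'   (or `NULL` to skip); defaults to [repeatability_specs()] when
#'   simulating.
#' @param seed Integer seed reassigned to the specs when simulating.
#' @param sem_mode_group,sem_mode_overall SEM conventions, see
#'   [sem_measurement()].
#' @param rc_df Degrees-of-freedom convention for RC intervals, see
#'   [rc_confidence_interval()].
#' @param z Limit-of-agreement multiplier.
#' @return Object of class `validation_bundle`: list with `data`, `groups`
#'   (named list of [agreement_report()]s), `overall`, `subgroups` (data
#'   frame), `repeatability` (named list), `config`.
#' @export
run_validation <- function(input = NULL, specs = NULL,
                           duplicate_specs = NULL,
                           seed = 20250819L,
                           sem_mode_group = "group",
                           sem_mode_overall = "pooled",
                           rc_df = "n-1", z = 1.96) {
  if (!is.null(input) && !is.null(specs)) {
    stop("give either `input` or `specs`, not both", call. = FALSE)
  }
  simulate <- is.null(input)
  if (simulate) {
    if (is.null(specs)) {
      specs <- list(af_cohort_spec(seed), sinus_cohort_spec(seed + 1L))
    }
    if (is.null(duplicate_specs)) {
      duplicate_specs <- repeatability_specs(seed + 100L)
    }
    .log("simulate", n_specs = length(specs), seed = seed)
    cohorts <- lapply(specs, generate_paired_cohort)
    df <- do.call(rbind, cohorts)
    df <- generate_covariates(df, seed = seed + 50L)
  } else {
    .log("ingest", input = input)
    df <- read_strain_csv(input)
    if (!"manual_lasr_pct" %in% names(df)) {
      df <- add_manual_strain(df)
    }
  }
  .log("strain", n = nrow(df))

  groups <- lapply(split(df, df$group), function(g)
    agreement_report(g$manual_lasr_pct, g$auto_lasr_pct,
                     sem_mode = sem_mode_group, z = z))
  overall <- agreement_report(df$manual_lasr_pct, df$auto_lasr_pct,
                              sem_mode = sem_mode_overall, z = z)
  overall$mdc_pct_of_mean <- 100 * overall$mdc95 / overall$grand_mean
  .log("agreement", groups = paste(names(groups), collapse = ","),
       n_overall = overall$n)

  covars <- c(lavi = "lavi_ml_m2", ef = "ef_pct", age = "age_years",
              sex = "sex")
  subgroups <- NULL
  strat <- names(covars)[covars %in% names(df)]
  if (length(strat)) {
    tabs <- lapply(strat, function(s) {
      tab <- withCallingHandlers(
        subgroup_agreement(df, s),
        warning = function(w) {
          message("subgroup warning: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      tab$stratifier <- s
      tab
    })
    subgroups <- do.call(rbind, tabs)
    .log("subgroups", n_strata = nrow(subgroups))
  }

  repeats <- NULL
  if (!is.null(duplicate_specs)) {
    repeats <- lapply(duplicate_specs, function(sp)
      repeatability(generate_duplicates(sp), df_convention = rc_df))
    .log("repeatability", n_sets = length(repeats))
  }

  structure(
    list(data = df, groups = groups, overall = overall,
         subgroups = subgroups, repeatability = repeats,
         config = list(input = input, seed = seed,
                       sem_mode_group = sem_mode_group,
                       sem_mode_overall = sem_mode_overall,
                       rc_df = rc_df, z = z, simulated = simulate)),
    class = "validation_bundle")
}

#' Serialize a validation bundle to JSON
#'
#' The JSON carries full-precision values alongside presentation-rounded
#' display strings (1 decimal for strain means, 2 for agreement statistics,
#' 3 for r and ICC) so that downstream consumers can compare at printed
#' precision without the rounding ever feeding back into computation.
#'
#' @param bundle A `validation_bundle` from [run_validation()].
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report_json <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "validation_bundle"))
  rep_list <- function(r) {
    vals <- r[setdiff(names(r), "coords")]
    list(values = vals, display = .display_report(r))
  }
  out <- list(
    config = bundle$config,
    groups = lapply(bundle$groups, rep_list),
    overall = rep_list(bundle$overall),
    subgroups = bundle$subgroups,
    repeatability = lapply(bundle$repeatability, unclass),
    bland_altman_coords = lapply(
      c(bundle$groups, list(overall = bundle$overall)),
      function(r) r$coords))
  # digits = I(17): enough significant digits for doubles to round-trip
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

.display_report <- function(r) {
  d <- list(
    mean_manual = sprintf("%.1f +/- %.1f", r$mean_manual, r$sd_manual),
    mean_automatic = sprintf("%.1f +/- %.1f", r$mean_automatic,
                             r$sd_automatic),
    bias = sprintf("%.2f +/- %.2f", r$bias, r$sd_diff),
    loa = sprintf("[%.2f, %.2f]", r$loa_low, r$loa_high),
    r = sprintf("%.3f", r$r),
    icc = sprintf("%.3f", r$icc),
    cv_pct = sprintf("%.1f%%", r$cv_pct),
    sem = sprintf("%.2f (%s)", r$sem, r$sem_mode),
    mdc95 = sprintf("%.2f", r$mdc95))
  if (!is.null(r$mdc_pct_of_mean)) {
    # presentation chain: the printed MDC-as-%-of-mean uses the 2-decimal MDC
    d$mdc_pct_of_mean <- sprintf(
      "%.2f%%", 100 * round(r$mdc95, 2) / r$grand_mean)
  }
  d
}

#' Render a validation bundle as aligned text tables
#'
#' @param bundle A `validation_bundle`.
#' @param file Connection or path passed to [cat()]; default stdout.
#' @return Invisibly, the lines printed.
#' @export
render_report_text <- function(bundle, file = stdout()) {
  stopifnot(inherits(bundle, "validation_bundle"))
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("Agreement between manual and automatic LA reservoir strain")
  add("==========================================================")
  for (nm in names(bundle$groups)) {
    g <- bundle$groups[[nm]]
    d <- .display_report(g)
    add("")
    add("Group: %s (n = %d)", nm, g$n)
    add("  Manual strain, %%       %s", d$mean_manual)
    add("  Automatic strain, %%    %s", d$mean_automatic)
    add("  Mean difference        %s", d$bias)
    add("  Limits of agreement    %s", d$loa)
    add("  Pearson r              %s (p %s)", d$r, .format_p(g$p_r))
    add("  ICC(2,1)               %s", d$icc)
    add("  CV of differences      %s", d$cv_pct)
    add("  SEM                    %s", d$sem)
    add("  MDC95                  %s", d$mdc95)
  }
  o <- bundle$overall
  d <- .display_report(o)
  add("")
  add("Overall (n = %d)", o$n)
  add("  Pearson r              %s (p %s)", d$r, .format_p(o$p_r))
  add("  ICC(2,1)               %s", d$icc)
  add("  CV of differences      %s", d$cv_pct)
  add("  SEM                    %s", d$sem)
  add("  MDC95                  %s", d$mdc95)
  add("  MDC as %% of mean       %s", d$mdc_pct_of_mean)
  if (!is.null(bundle$repeatability)) {
    add("")
    add("Repeatability (test-retest)")
    for (nm in names(bundle$repeatability)) {
      rr <- bundle$repeatability[[nm]]
      add("  %-14s RC %.2f%% (95%% CI %.2f-%.2f), n = %d",
          nm, rr$rc, rr$ci_low, rr$ci_high, rr$n)
    }
  }
  if (!is.null(bundle$subgroups)) {
    add("")
    add("Subgroup agreement")
    add("  %-26s %3s %10s %7s %7s", "stratum", "n", "|diff|", "r", "ICC")
    for (i in seq_len(nrow(bundle$subgroups))) {
      s <- bundle$subgroups[i, ]
      if (s$skipped) {
        add("  %-26s %3d   (skipped: too few patients)", s$stratum, s$n)
      } else {
        add("  %-26s %3d %10.2f %7.3f %7.3f",
            s$stratum, s$n, s$mean_abs_diff, s$r, s$icc)
      }
    }
  }
  cat(lines, sep = "\n", file = file)
  invisible(lines)
}

#' @export
print.validation_bundle <- function(x, ...) {
  render_report_text(x)
  invisible(x)
}

#' Export Bland-Altman plot coordinates
#'
#' Writes per-patient (average, difference) coordinates, one row per patient
#' with its group label, ready for plotting.
#'
#' @param bundle A `validation_bundle`.
#' @param path Output CSV path.
#' @return The coordinate data frame, invisibly.
#' @export
write_ba_coords_csv <- function(bundle, path) {
  stopifnot(inherits(bundle, "validation_bundle"))
  co <- bundle$overall$coords
  co$patient_id <- bundle$data$patient_id
  co$group <- bundle$data$group
  co <- co[c("patient_id", "group", "average", "difference")]
  utils::write.csv(co, path, row.names = FALSE, quote = FALSE)
  invisible(co)
}

# one structured log line per stage, to stderr; results go to stdout/files
.log <- function(stage, ...) {
  kv <- list(...)
  message(sprintf("[lasrtools] stage=%s %s", stage,
                  paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
}
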