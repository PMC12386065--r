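#' Caliper lengths for biplane left atrial strain
#'
#' Bundles the four left atrial long-axis caliper lengths needed for biplane
#' reservoir strain: maximal (end-systolic) and minimal (end-diastolic) length
#' in the apical 4-chamber view, and the same pair in the apical 2-chamber
#' view. Lengths are in centimetres, as read off the ultrasound calipers.
#'
#' A systolic length smaller than or equal to its diastolic counterpart is
#' physiologically anomalous (the atrium should be longest at ventricular end
#' systole); such input is flagged via the `anomalous` attribute and a warning,
#' but computation proceeds so the resulting negative strain remains visible
#' downstream rather than being silently clamped.
#'
#' @param ls4c,ld4c Systolic and diastolic LA length in the 4-chamber view (cm).
#' @param ls2c,ld2c Systolic and diastolic LA length in the 2-chamber view (cm).
#' @return An object of class `biplane_lengths`: a named list of the four
#'   lengths with logical attribute `anomalous`.
#' @examples
#' biplane_lengths(16.0, 14.7, 14.1, 12.9)
#' @export
biplane_lengths <- function(ls4c, ld4c, ls2c, ld2c) {
  vals <- c(ls4c = ls4c, ld4c = ld4c, ls2c = ls2c, ld2c = ld2c)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    if (v <= 0) {
      stop(sprintf("`%s` must be strictly positive (got %g)", nm, v),
           call. = FALSE)
    }
  }
  # plausibility only: the formula is unit-free, so nothing is converted
  if (any(vals < 1 | vals > 25)) {
    warning("length outside the plausible 1-25 cm range; check units",
            call. = FALSE)
  }
  anomalous <- (ls4c <= ld4c) || (ls2c <= ld2c)
  if (anomalous) {
    warning("systolic length <= diastolic length: anomalous input, ",
            "strain will be non-positive in that plane", call. = FALSE)
  }
  structure(as.list(vals), anomalous = anomalous, class = "biplane_lengths")
}

#' Single-plane left atrial reservoir strain
#'
#' Reservoir strain in one apical view, computed as the fractional lengthening
#' of the atrium relative to its maximal (end-systolic) length:
#' `(ls - ld) / ls`. The result is a dimensionless fraction; multiply by 100
#' for percent.
#'
#' A negative value (diastolic length exceeding systolic) is returned with a
#' warning rather than rejected or clamped.
#'
#' @param ls Maximal (systolic) LA length, cm. Must be strictly positive.
#' @param ld Minimal (diastolic) LA length, cm.
#' @return Strain as a dimensionless fraction. Vectorised over `ls`/`ld`.
#' @examples
#' plane_reservoir_strain(16.0, 14.7)  # 0.08125
#' @export
plane_reservoir_strain <- function(ls, ld) {
  if (any(!is.finite(ls)) || any(!is.finite(ld))) {
    stop("`ls` and `ld` must be finite", call. = FALSE)
  }
  if (any(ls <= 0)) {
    stop("`ls` (systolic length) must be strictly positive", call. = FALSE)
  }
  s <- (ls - ld) / ls
  if (any(s < 0)) {
    warning("negative strain: diastolic length exceeds systolic length",
            call. = FALSE)
  }
  s
}

#' Biplane left atrial reservoir strain
#'
#' Averages the 4-chamber and 2-chamber single-plane reservoir strains and
#' expresses the result in percent:
#' \deqn{LASr = 100 \cdot \frac{1}{2}\left(\frac{Ls_{4c}-Ld_{4c}}{Ls_{4c}} +
#'   \frac{Ls_{2c}-Ld_{2c}}{Ls_{2c}}\right)}
#'
#' The unrounded value is retained in the result; rounding to one decimal is a
#' presentation choice applied only by [format()] / [print()].
#'
#' @param lengths A [biplane_lengths] object, or `ls4c` when the four lengths
#'   are given individually.
#' @param ld4c,ls2c,ld2c Remaining lengths (cm) when not using a
#'   `biplane_lengths` object.
#' @return An object of class `strain_result`: list with `strain4c` and
#'   `strain2c` (dimensionless fractions), `biplane_pct` (percent, full
#'   precision) and `anomalous` flag.
#' @examples
#' biplane_reservoir_strain(16.0, 14.7, 14.1, 12.9)  # 8.3%
#' @export
biplane_reservoir_strain <- function(lengths, ld4c = NULL, ls2c = NULL,
                                     ld2c = NULL) {
  if (!inherits(lengths, "biplane_lengths")) {
    lengths <- biplane_lengths(lengths, ld4c, ls2c, ld2c)
  }
  s4 <- withCallingHandlers(
    plane_reservoir_strain(lengths$ls4c, lengths$ld4c),
    warning = function(w) invokeRestart("muffleWarning"))
  s2 <- withCallingHandlers(
    plane_reservoir_strain(lengths$ls2c, lengths$ld2c),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(strain4c = s4, strain2c = s2,
         biplane_pct = 100 * (s4 + s2) / 2,
         anomalous = isTRUE(attr(lengths, "anomalous"))),
    class = "strain_result")
}

#' @export
format.strain_result <- function(x, ...) {
  sprintf("Biplane LASr = %.1f%% (4C %.4f, 2C %.4f)",
          x$biplane_pct, x$strain4c, x$strain2c)
}

#' @export
print.strain_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Append manual biplane strain to a measurement table
#'
#' Computes `manual_lasr_pct` row-wise from the four caliper-length columns of
#' the standard measurement table (see [read_strain_csv()] for the schema).
#'
#' @param df Data frame with columns `ls4c_cm`, `ld4c_cm`, `ls2c_cm`,
#'   `ld2c_cm`.
#' @return `df` with columns `manual_lasr_pct` (full precision) and
#'   `anomalous` (logical) appended.
#' @export
add_manual_strain <- function(df) {
  needed <- c("ls4c_cm", "ld4c_cm", "ls2c_cm", "ld2c_cm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing length columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    suppressWarnings(biplane_reservoir_strain(
      df$ls4c_cm[i], df$ld4c_cm[i], df$ls2c_cm[i], df$ld2c_cm[i]))
  })
  df$manual_lasr_pct <- vapply(res, `[[`, numeric(1), "biplane_pct")
  df$anomalous <- vapply(res, `[[`, logical(1), "anomalous")
  df
}

#' Average replicate manual measurements
#'
#' When each patient is measured twice, the replicates can be combined either
#' by averaging the computed biplane strains (default) or by averaging the raw
#' caliper lengths before computing strain once. For the reservoir-strain
#' formula the two differ only through the nonlinearity of the per-plane ratio
#' and agree closely for small replicate differences.
#'
#' @param reps List of [biplane_lengths] objects (the replicates).
#' @param stage `"strain"` to average computed biplane strains, `"lengths"` to
#'   average lengths first.
#' @return Averaged biplane strain in percent.
#' @export
average_replicates <- function(reps, stage = c("strain", "lengths")) {
  stage <- match.arg(stage)
  if (!length(reps)) stop("no replicates supplied", call. = FALSE)
  if (stage == "strain") {
    mean(vapply(reps, function(r)
      biplane_reservoir_strain(r)$biplane_pct, numeric(1)))
  } else {
    m <- vapply(c("ls4c", "ld4c", "ls2c", "ld2c"), function(nm)
      mean(vapply(reps, `[[`, numeric(1), nm)), numeric(1))
    biplane_reservoir_strain(m[["ls4c"]], m[["ld4c"]],
                             m[["ls2c"]], m[["ld2c"]])$biplane_pct
  }
}
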