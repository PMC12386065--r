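#' Biplane area-length left atrial volume
#'
#' Volume of the left atrium from the biplane area-length method,
#' \deqn{V = \frac{8}{3\pi}\,\frac{A_1 A_2}{L}}
#' where `A1` and `A2` are the LA areas planimetered in the apical 4-chamber
#' and 2-chamber views (cm^2) and `L` is the shorter of the LA long-axis
#' lengths measured in the two views (cm). Result in mL (cm^3).
#'
#' @param a1,a2 LA areas in the 4-chamber and 2-chamber views, cm^2.
#' @param l LA long-axis length, cm. When both per-view lengths are available
#'   pass their minimum (see [shorter_length()]).
#' @return Volume in mL. Vectorised.
#' @examples
#' la_volume_biplane(20, 20, 5)  # 67.906 mL
#' @export
la_volume_biplane <- function(a1, a2, l) {
  .check_positive(a1 = a1, a2 = a2, l = l)
  (8 / (3 * pi)) * a1 * a2 / l
}

#' Shorter of the two per-view LA lengths
#'
#' The area-length formula uses the shorter of the lengths measured in the
#' 4-chamber and 2-chamber views. When only one is available it is used as is.
#'
#' @param len4c,len2c Per-view LA lengths, cm (either may be `NA`).
#' @return Element-wise shorter length.
#' @export
shorter_length <- function(len4c, len2c) {
  pmin(len4c, len2c, na.rm = TRUE)
}

#' Index a volume (or mass) to body surface area
#'
#' @param value Volume in mL (or mass in g).
#' @param bsa Body surface area, m^2; must be strictly positive.
#' @return `value / bsa`, e.g. LAVi in mL/m^2 or LVMi in g/m^2.
#' @examples
#' lavi(106.6, 1.88)
#' @export
lavi <- function(value, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("`bsa` must be strictly positive", call. = FALSE)
  }
  value / bsa
}

#' Left ventricular mass (cube formula)
#'
#' Mass from linear end-diastolic dimensions,
#' \deqn{LVM = 0.8 \cdot c \cdot [(IVS + PW + LVID)^3 - LVID^3] + 0.6\ g}
#' with septal thickness `ivs`, posterior wall thickness `pw` and internal
#' diameter `lvid` in cm.
#'
#' The default coefficient is `c = 1.4`. The widely used Devereux-corrected
#' cube formula takes `c = 1.04`; pass `coefficient = 1.04` to use it. Both
#' are exposed because reported LV mass values in the literature mix the two
#' conventions and the difference is a constant factor on the bracketed term.
#'
#' @param ivs Interventricular septal thickness at end-diastole, cm.
#' @param pw Posterior wall thickness at end-diastole, cm.
#' @param lvid LV internal diameter at end-diastole, cm.
#' @param coefficient Multiplicative constant, default 1.4.
#' @return Mass in grams. Vectorised.
#' @examples
#' lv_mass(1.0, 1.0, 5.0)                      # 245.36 g
#' lv_mass(1.0, 1.0, 5.0, coefficient = 1.04)  # 182.54 g
#' @export
lv_mass <- function(ivs, pw, lvid, coefficient = 1.4) {
  .check_positive(ivs = ivs, pw = pw, lvid = lvid)
  if (any(lvid <= pw)) {
    warning("`lvid` not greater than `pw`: implausible LV geometry",
            call. = FALSE)
  }
  0.8 * coefficient * ((ivs + pw + lvid)^3 - lvid^3) + 0.6
}

#' Relative wall thickness
#'
#' \deqn{RWT = 2\,PW / LVEDD}
#'
#' @param pw Posterior wall thickness at end-diastole, cm.
#' @param lvedd LV end-diastolic diameter, cm; must be strictly positive.
#' @return Dimensionless ratio. Vectorised.
#' @examples
#' relative_wall_thickness(1.1, 4.6)  # 0.478
#' @export
relative_wall_thickness <- function(pw, lvedd) {
  if (any(!is.finite(lvedd)) || any(lvedd <= 0)) {
    stop("`lvedd` must be strictly positive", call. = FALSE)
  }
  2 * pw / lvedd
}

#' Mosteller body surface area
#'
#' Convenience helper, `sqrt(height_cm * weight_kg / 3600)` in m^2. This is
#' plumbing for tables that carry height/weight but no BSA column; any BSA
#' supplied directly takes precedence in the pipeline.
#'
#' @param height_cm Height, cm.
#' @param weight_kg Weight, kg.
#' @return BSA in m^2. Vectorised.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  .check_positive(height_cm = height_cm, weight_kg = weight_kg)
  sqrt(height_cm * weight_kg / 3600)
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be strictly positive and finite", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
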