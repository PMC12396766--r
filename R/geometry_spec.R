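# Parametric AVF geometry: proximal/distal carotid artery, stenotic fistula
# (the 4 mm segment measured from the anastomosis), and a ballooning vein.
#
# The fistula diameter profile d(s) along arc length s (mm, s = 0 at the
# anastomosis, positive into the fistula/vein) is the sum of
#   * a plateau level dn,
#   * a Gaussian anastomosis bulge of amplitude (da - dn) and width wa,
#   * a venous-expansion smoothstep ramp from s0 that reaches the vein
#     maximum exactly at the fistula end (C1-continuous into the vein),
#   * minus a Gaussian stenosis dip of amplitude A centred at c with width w.
# The day-7 / day-21 constants below were calibrated once so that the
# analytic window statistics (mean over the first 2 mm and 4 mm, minimum,
# maxima) reproduce the reported murine diameters to better than 0.005 mm.

.preset_shapes <- list(
  day7 = list(dn = 1.000160, da = 0.951589, A = 0.539895,
              s0 = 2.413896, c = 1.291600, w = 0.378309,
              dv = 1.07, wa = 0.40),
  day21 = list(dn = 0.660435, da = 0.960269, A = 0.350841,
               s0 = 2.123445, c = 1.453071, w = 0.383587,
               dv = 1.71, wa = 0.40)
)

.preset_fields <- list(
  day7 = list(
    proximal_artery = list(diameter = 0.29, length = 3),
    distal_artery = list(diameter = 0.36, length = 3),
    fistula = list(nominal_diameter = 0.74, length = 4,
                   stenosis = list(center_s = 1.291600, min_diameter = 0.46,
                                   width = 0.378309)),
    vein = list(start_diameter = 0.74, max_diameter = 1.07, length = 2)
  ),
  day21 = list(
    proximal_artery = list(diameter = 0.39, length = 3),
    distal_artery = list(diameter = 0.46, length = 3),
    fistula = list(nominal_diameter = 0.58, length = 4,
                   stenosis = list(center_s = 1.453071, min_diameter = 0.31,
                                   width = 0.383587)),
    vein = list(start_diameter = 0.58, max_diameter = 1.71, length = 2)
  )
)

# cubic smoothstep, 0 below 0 and 1 above 1
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  3 * x^2 - 2 * x^3
}

smoothstep_deriv <- function(x) {
  ifelse(x <= 0 | x >= 1, 0, 6 * x * (1 - x))
}

#' Construct a parametric AVF geometry
#'
#' Builds the geometric specification consumed by the phantom voxelizer and
#' the flow-solver grid builders: a proximal and distal carotid artery joined
#' end-to-side by a fistula whose diameter profile carries a Gaussian
#' stenosis and a venous expansion. The `day7` and `day21` presets encode the
#' reported murine lumen diameters at 7 and 21 days after fistula creation
#' (proximal artery 0.29 / 0.39 mm; fistula 2 mm-window mean 0.74 / 0.58 mm;
#' stenosis minimum 0.46 / 0.31 mm; vein maximum 1.07 / 1.71 mm).
#'
#' @param preset `"day7"`, `"day21"`, or `"custom"`. For `"custom"` the
#'   profile is built from the supplied fields alone: a flat fistula at its
#'   nominal diameter, an optional Gaussian stenosis dip, and an optional
#'   smoothstep expansion to the vein maximum ending at the fistula end.
#' @param ... named overrides of top-level fields (`proximal_artery`,
#'   `distal_artery`, `fistula`, `vein`, `anastomosis_angle`,
#'   `inlet_extension`). Sub-lists are merged field-wise.
#' @return An object of class `avf_geometry`: a validated list with the
#'   fields above plus internal profile-shape constants. All lengths and
#'   diameters are in mm, the anastomosis angle in degrees.
#' @examples
#' g <- avf_geometry("day7")
#' g$fistula$stenosis$min_diameter  # 0.46
#' @export
avf_geometry <- function(preset = c("day7", "day21", "custom"), ...) {
  preset <- match.arg(preset)
  overrides <- list(...)
  base <- if (preset == "custom") {
    list(
      proximal_artery = list(diameter = 0.3, length = 3),
      distal_artery = list(diameter = 0.3, length = 3),
      fistula = list(nominal_diameter = 0.8, length = 4, stenosis = NULL),
      vein = list(start_diameter = 0.8, max_diameter = 0.8, length = 2)
    )
  } else {
    .preset_fields[[preset]]
  }
  base$anastomosis_angle <- 90
  base$inlet_extension <- 2

  known <- names(base)
  for (nm in names(overrides)) {
    if (!nm %in% known) abort_field(nm, "unknown field")
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      sub <- overrides[[nm]]
      bad <- setdiff(names(sub), c(names(base[[nm]]), "stenosis"))
      if (length(bad)) abort_field(paste(nm, bad[1], sep = "$"), "unknown field")
      base[[nm]] <- utils::modifyList(base[[nm]], sub)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }

  spec <- base
  spec$preset <- preset
  class(spec) <- "avf_geometry"
  validate_avf_geometry(spec)
  spec$shape <- if (preset %in% c("day7", "day21") && length(overrides) == 0) {
    .preset_shapes[[preset]]
  } else {
    .derive_shape(spec)
  }
  spec
}

# Shape constants for custom (or overridden) geometries: flat fistula at the
# nominal diameter, dip amplitude solved so the profile minimum equals the
# requested stenosis minimum, expansion ramp over the distal 45% of the
# fistula unless the vein does not widen.
.derive_shape <- function(spec) {
  f <- spec$fistula
  dn <- f$nominal_diameter
  dv <- spec$vein$max_diameter
  L <- f$length
  s0 <- if (abs(dv - dn) < 1e-12) L else 0.55 * L
  sh <- list(dn = dn, da = dn, A = 0, s0 = s0,
             c = L / 3, w = L / 10, dv = dv, wa = 0.4)
  st <- f$stenosis
  if (!is.null(st)) {
    sh$c <- st$center_s
    sh$w <- st$width
    base_at <- function(A) {
      shA <- sh; shA$A <- A
      min(.fistula_d(seq(0, L, length.out = 2001), shA, L))
    }
    # amplitude such that min(d) equals the requested minimum
    lo <- 0
    hi <- dn + abs(dv - dn)
    A <- stats::uniroot(function(A) base_at(A) - st$min_diameter,
                        c(lo, hi), tol = 1e-10)$root
    sh$A <- A
  }
  sh
}

.fistula_d <- function(s, sh, L) {
  ramp <- if (L - sh$s0 > 0 && sh$dv != sh$dn)
    (sh$dv - sh$dn) * smoothstep((s - sh$s0) / (L - sh$s0)) else 0
  d <- sh$dn + (sh$da - sh$dn) * exp(-0.5 * (s / sh$wa)^2) + ramp -
    sh$A * exp(-0.5 * ((s - sh$c) / sh$w)^2)
  d[s > L] <- sh$dv
  d
}

.fistula_d_deriv2 <- function(s, sh, L) {
  g_bulge <- exp(-0.5 * (s / sh$wa)^2)
  dd <- (sh$da - sh$dn) * g_bulge * (s^2 / sh$wa^4 - 1 / sh$wa^2)
  if (L - sh$s0 > 0 && sh$dv != sh$dn) {
    x <- (s - sh$s0) / (L - sh$s0)
    s2 <- ifelse(x <= 0 | x >= 1, 0, 6 - 12 * x)
    dd <- dd + (sh$dv - sh$dn) * s2 / (L - sh$s0)^2
  }
  g_dip <- exp(-0.5 * ((s - sh$c) / sh$w)^2)
  dd <- dd + sh$A * g_dip * (1 / sh$w^2 - (s - sh$c)^2 / sh$w^4)
  dd[s > L] <- 0
  dd
}

# analytic d^2(diameter)/ds^2, one-sided at the straight-extension junction
fistula_diameter_deriv2 <- function(spec, s) {
  .fistula_d_deriv2(s, spec$shape, spec$fistula$length)
}

.fistula_d_deriv <- function(s, sh, L) {
  rampd <- if (L - sh$s0 > 0 && sh$dv != sh$dn)
    (sh$dv - sh$dn) * smoothstep_deriv((s - sh$s0) / (L - sh$s0)) / (L - sh$s0) else 0
  dd <- (sh$da - sh$dn) * exp(-0.5 * (s / sh$wa)^2) * (-s / sh$wa^2) + rampd +
    sh$A * exp(-0.5 * ((s - sh$c) / sh$w)^2) * (s - sh$c) / sh$w^2
  dd[s > L] <- 0
  dd
}

#' Validate an AVF geometry
#'
#' Checks the structural invariants: positive diameters and lengths, stenosis
#' minimum below the fistula nominal diameter, anastomosis angle strictly
#' between 0 and 180 degrees, non-negative inlet extension. Errors name the
#' offending field.
#'
#' @param spec an `avf_geometry` object.
#' @return `spec`, invisibly, if valid.
#' @export
validate_avf_geometry <- function(spec) {
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      abort_field(field, "must be a positive finite number")
  }
  for (seg in c("proximal_artery", "distal_artery")) {
    chk_pos(spec[[seg]]$diameter, paste0(seg, "$diameter"))
    chk_pos(spec[[seg]]$length, paste0(seg, "$length"))
  }
  chk_pos(spec$fistula$nominal_diameter, "fistula$nominal_diameter")
  chk_pos(spec$fistula$length, "fistula$length")
  st <- spec$fistula$stenosis
  if (!is.null(st)) {
    chk_pos(st$min_diameter, "fistula$stenosis$min_diameter")
    chk_pos(st$width, "fistula$stenosis$width")
    if (st$min_diameter >= spec$fistula$nominal_diameter)
      abort_field("fistula$stenosis$min_diameter",
                  "must be smaller than the fistula nominal diameter")
    if (st$center_s < 0 || st$center_s > spec$fistula$length)
      abort_field("fistula$stenosis$center_s", "must lie within the fistula")
  }
  chk_pos(spec$vein$start_diameter, "vein$start_diameter")
  chk_pos(spec$vein$max_diameter, "vein$max_diameter")
  chk_pos(spec$vein$length, "vein$length")
  ang <- spec$anastomosis_angle
  if (!is.numeric(ang) || ang <= 0 || ang >= 180)
    abort_field("anastomosis_angle", "must be strictly between 0 and 180 degrees")
  if (spec$inlet_extension < 0)
    abort_field("inlet_extension", "must be non-negative")
  invisible(spec)
}

#' @export
print.avf_geometry <- function(x, ...) {
  st <- x$fistula$stenosis
  cat("AVF geometry (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  proximal artery: d = %.2f mm, L = %.1f mm\n",
              x$proximal_artery$diameter, x$proximal_artery$length))
  cat(sprintf("  distal artery:   d = %.2f mm, L = %.1f mm\n",
              x$distal_artery$diameter, x$distal_artery$length))
  cat(sprintf("  fistula:         nominal d = %.2f mm over %.1f mm\n",
              x$fistula$nominal_diameter, x$fistula$length))
  if (!is.null(st))
    cat(sprintf("    stenosis:      min d = %.2f mm at s = %.2f mm (width %.2f mm)\n",
                st$min_diameter, st$center_s, st$width))
  cat(sprintf("  vein:            max d = %.2f mm over %.1f mm\n",
              x$vein$max_diameter, x$vein$length))
  cat(sprintf("  anastomosis angle %g deg, inlet extension %g mm\n",
              x$anastomosis_angle, x$inlet_extension))
  invisible(x)
}

#' Analytic diameter along the fistula and vein
#'
#' Evaluates the ground-truth diameter profile d(s) of the fistula/vein path
#' of a geometry at arc lengths `s` (mm, s = 0 at the anastomosis, positive
#' into the fistula). Values beyond the fistula end take the vein maximum
#' diameter.
#'
#' @param spec an `avf_geometry`.
#' @param s numeric vector of arc lengths in mm (s >= 0).
#' @return diameters in mm.
#' @export
fistula_diameter <- function(spec, s) {
  .fistula_d(s, spec$shape, spec$fistula$length)
}

# d(diameter)/ds, used by the body-fitted solver mapping
fistula_diameter_deriv <- function(spec, s) {
  .fistula_d_deriv(s, spec$shape, spec$fistula$length)
}

#' Read and write geometry specifications
#'
#' Serializes an [avf_geometry()] as human-readable JSON (all fields in mm
#' and degrees). Reading reconstructs the object through the constructor, so
#' invariants are re-validated and profile-shape constants re-derived for
#' custom geometries (presets keep their calibrated constants).
#'
#' @param spec an `avf_geometry`.
#' @param path file path.
#' @return `read_geometry_json` returns an `avf_geometry`.
#' @export
write_geometry_json <- function(spec, path) {
  fields <- spec[c("preset", "proximal_artery", "distal_artery", "fistula",
                   "vein", "anastomosis_angle", "inlet_extension")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  f <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- f$preset %||% "custom"
  if (preset %in% c("day7", "day21")) return(avf_geometry(preset))
  avf_geometry("custom",
               proximal_artery = f$proximal_artery,
               distal_artery = f$distal_artery,
               fistula = f$fistula,
               vein = f$vein,
               anastomosis_angle = f$anastomosis_angle,
               inlet_extension = f$inlet_extension)
}

#' Ground-truth diameter profile of a geometry
#'
#' Samples the analytic radius function of every branch at a fixed station
#' spacing, in the plotting convention used for longitudinal lumen profiles:
#' s = 0 at the anastomosis, negative s on the artery side (both proximal
#' and distal artery are upstream branches), positive s along the
#' fistula and vein.
#'
#' @param spec an `avf_geometry`.
#' @param ds station spacing in mm.
#' @return A `diameter_profile` data frame with columns `branch`
#'   (`"PA"`, `"DA"`, `"AVF"`, `"vein"`), `s_mm`, `area_mm2`, `diameter_mm`.
#' @export
radius_profile <- function(spec, ds = 0.05) {
  if (!is.numeric(ds) || ds <= 0) stop("ds must be positive", call. = FALSE)
  shortest <- min(spec$proximal_artery$length, spec$distal_artery$length,
                  spec$fistula$length, spec$vein$length)
  if (ds > shortest)
    stop(sprintf("ds = %g mm exceeds the shortest segment (%g mm)", ds, shortest),
         call. = FALSE)
  Lf <- spec$fistula$length
  rows <- list()
  for (br in c("PA", "DA")) {
    seg <- if (br == "PA") spec$proximal_artery else spec$distal_artery
    L <- seg$length + spec$inlet_extension
    s <- -rev(seq(0, L, by = ds))
    rows[[br]] <- data.frame(branch = br, s_mm = s,
                             diameter_mm = rep(seg$diameter, length(s)))
  }
  s_avf <- seq(0, Lf, by = ds)
  rows$AVF <- data.frame(branch = "AVF", s_mm = s_avf,
                         diameter_mm = fistula_diameter(spec, s_avf))
  s_v <- seq(Lf + ds, Lf + spec$vein$length, by = ds)
  rows$vein <- data.frame(branch = "vein", s_mm = s_v,
                          diameter_mm = fistula_diameter(spec, s_v))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$area_mm2 <- pi * (out$diameter_mm / 2)^2
  new_diameter_profile(out[, c("branch", "s_mm", "area_mm2", "diameter_mm")])
}

# diameter_profile constructor enforcing area/diameter consistency
new_diameter_profile <- function(df) {
  stopifnot(all(c("s_mm", "area_mm2", "diameter_mm") %in% names(df)))
  if (any(df$area_mm2 <= 0)) stop("cross-sectional areas must be positive")
  if (any(abs(df$diameter_mm - 2 * sqrt(df$area_mm2 / pi)) > 1e-9))
    stop("diameter and area are inconsistent (d must equal 2*sqrt(A/pi))")
  class(df) <- c("diameter_profile", "data.frame")
  df
}
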