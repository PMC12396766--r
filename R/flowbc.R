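# Boundary conditions from Doppler-style velocity data: the Q = A*V flow
# estimate under the parabolic-profile assumption, Womersley number, and
# parabolic inlet construction.

#' Blood fluid properties
#'
#' Newtonian blood model: density 1040 kg/m^3 and dynamic viscosity
#' 4e-3 Pa s by default.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @return a `fluid_properties` list.
#' @export
fluid_properties <- function(density = 1040, viscosity = 4e-3) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Mean velocity from peak velocity under a parabolic profile
#'
#' For an axisymmetric parabolic (Poiseuille-like) profile the
#' cross-sectional mean is half the centerline peak; this is the standard
#' reduction applied to Doppler peak-velocity readings at low Womersley
#' number. Accepts a scalar, vector, or `flow_waveform` (applied per sample,
#' preserving the period).
#'
#' @param v_peak peak velocity (any unit), or a `flow_waveform` of kind
#'   `peak_velocity`.
#' @return mean velocity in the same unit/class.
#' @export
mean_from_peak <- function(v_peak) {
  if (inherits(v_peak, "flow_waveform")) {
    out <- v_peak
    out$value <- v_peak$value / 2
    return(out)
  }
  v_peak / 2
}

#' Volumetric flow rate Q = A * V
#'
#' @param area_m2 cross-sectional area in m^2 (> 0).
#' @param v_mean_m_s mean velocity in m/s.
#' @param units `"m3_s"` or `"ml_min"`.
#' @return flow rate.
#' @examples
#' # day-7 scale: d = 0.74 mm, v_mean = 51.6 mm/s -> about 1.33 mL/min
#' flow_rate(pi * (0.37e-3)^2, 51.6e-3, units = "ml_min")
#' @export
flow_rate <- function(area_m2, v_mean_m_s, units = c("m3_s", "ml_min")) {
  units <- match.arg(units)
  if (any(area_m2 <= 0)) stop("area must be positive")
  q <- area_m2 * v_mean_m_s
  if (units == "ml_min") m3s_to_ml_min(q) else q
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega * rho / mu)` with `omega = 2 pi f` the angular
#' heart-rate frequency. Around alpha = 1 viscous effects dominate pulsatile
#' inertia and quasi-parabolic velocity profiles are a good approximation.
#'
#' @param radius_m vessel radius in m.
#' @param heart_rate_bpm heart rate in beats per minute.
#' @param fluid a [fluid_properties()].
#' @return dimensionless Womersley number.
#' @examples
#' womersley_number(0.29e-3, 450)  # about 1
#' @export
womersley_number <- function(radius_m, heart_rate_bpm,
                             fluid = fluid_properties()) {
  if (any(radius_m < 0)) stop("radius must be non-negative")
  if (heart_rate_bpm <= 0) stop("heart rate must be positive")
  omega <- 2 * pi * bpm_to_hz(heart_rate_bpm)
  radius_m * sqrt(omega * fluid$density / fluid$viscosity)
}

#' Build a parabolic inlet condition
#'
#' Converts a waveform into a time-varying parabolic inlet profile
#' `u(r, t) = fac * v_mean(t) * (1 - (r/R)^2)` whose instantaneous integral
#' over the inlet equals `Q(t) = A * v_mean(t)` exactly. The peak factor
#' `fac` is 2 for axisymmetric (circular) inlets and 3/2 for the planar
#' (channel) reduction, where the profile is `fac * v_mean * (1 - (y/R)^2)`
#' across the half-width R.
#'
#' @param waveform a `flow_waveform`; kind `peak_velocity` (mm/s, halved to
#'   the mean via [mean_from_peak()]) or `flow_rate` (mL/min, divided by the
#'   area).
#' @param radius_m inlet radius (axisymmetric) or half-width (planar) in m.
#' @param geometry `"axisymmetric"` or `"planar"`.
#' @return an `inlet_condition` with the periodic mean-velocity function
#'   `v_mean(t)` (m/s), the profile function `profile(r_m, t)`, `radius_m`,
#'   and the source waveform.
#' @export
build_inlet <- function(waveform, radius_m,
                        geometry = c("axisymmetric", "planar")) {
  geometry <- match.arg(geometry)
  if (radius_m <= 0) stop("radius must be positive")
  kind <- attr(waveform, "kind")
  area <- if (geometry == "axisymmetric") pi * radius_m^2 else 2 * radius_m
  vmean_vals <- switch(kind,
    peak_velocity = mm_to_m(waveform$value) / 2,
    flow_rate = ml_min_to_m3s(waveform$value) / area,
    stop("unknown waveform kind"))
  if (any(vmean_vals <= 0))
    stop("inlet waveform reverses (non-positive flow); reversing inlets are not supported")
  wf_mean <- flow_waveform(waveform$time_s, vmean_vals,
                           attr(waveform, "heart_rate_bpm"),
                           kind = "peak_velocity")
  attr(wf_mean, "kind") <- "mean_velocity_m_s"
  vfun <- waveform_fun(wf_mean)
  fac <- if (geometry == "axisymmetric") 2 else 1.5
  structure(list(
    v_mean = vfun,
    profile = function(r_m, t) fac * vfun(t) * (1 - (r_m / radius_m)^2),
    radius_m = radius_m,
    geometry = geometry,
    peak_factor = fac,
    period_s = attr(waveform, "period_s"),
    waveform = waveform), class = "inlet_condition")
}

#' Study flow conditions per timepoint
#'
#' The measured hemodynamic operating points of the two timepoints: AVF
#' branch flow 1.33 mL/min at day 7 rising to 2.57 mL/min at day 21, with
#' 80% / 70% of proximal-artery flow feeding the AVF (the remainder leaves
#' through the distal artery), at a heart rate of about 450 bpm.
#'
#' @param preset `"day7"` or `"day21"`.
#' @return list with `q_avf_ml_min`, `da_split`, `heart_rate_bpm`,
#'   `pulsatility` (waveform shape default used for synthetic traces).
#' @export
avf_flow_conditions <- function(preset = c("day7", "day21")) {
  preset <- match.arg(preset)
  if (preset == "day7") {
    list(q_avf_ml_min = 1.33, da_split = 0.2, heart_rate_bpm = 450,
         pulsatility = 0.4)
  } else {
    list(q_avf_ml_min = 2.57, da_split = 0.3, heart_rate_bpm = 450,
         pulsatility = 0.4)
  }
}

#' Boundary conditions for a preset AVF simulation
#'
#' Synthesizes the pulsatile inlet for a geometry at the study operating
#' point: the waveform is scaled so that its cycle-mean flow matches the
#' timepoint's AVF (axisymmetric tube) or proximal-artery (planar junction)
#' flow rate.
#'
#' @param spec an [avf_geometry()].
#' @param preset `"day7"` or `"day21"`.
#' @param topology solver topology the inlet will drive.
#' @param pulsatility,seed waveform shape controls (see [synth_waveform()]).
#' @return list with `inlet` (an `inlet_condition`), `da_split`, and
#'   `conditions`.
#' @export
avf_boundary_conditions <- function(spec, preset = c("day7", "day21"),
                                    topology = c("axisymmetric_tube",
                                                 "planar_junction"),
                                    pulsatility = NULL, seed = 0) {
  preset <- match.arg(preset)
  topology <- match.arg(topology)
  cond <- avf_flow_conditions(preset)
  if (!is.null(pulsatility)) cond$pulsatility <- pulsatility
  if (topology == "axisymmetric_tube") {
    R <- mm_to_m(fistula_diameter(spec, 0) / 2)
    q_target <- ml_min_to_m3s(cond$q_avf_ml_min)
    geometry <- "axisymmetric"
  } else {
    R <- mm_to_m(spec$proximal_artery$diameter / 2)
    q_target <- ml_min_to_m3s(cond$q_avf_ml_min) / (1 - cond$da_split)
    geometry <- "planar"
  }
  vm_target <- q_target / (pi * R^2)
  wf <- synth_waveform(1, cond$heart_rate_bpm, cond$pulsatility, seed = seed)
  # waveform is peak velocity in mm/s; build_inlet halves it to the mean
  wf$value <- wf$value * vm_target / mean(mm_to_m(wf$value) / 2)
  list(inlet = build_inlet(wf, R, geometry = geometry),
       da_split = cond$da_split, conditions = cond)
}

#' @export
print.inlet_condition <- function(x, ...) {
  v <- x$v_mean(x$waveform$time_s)
  cat(sprintf("inlet_condition (%s): R = %.3g mm, period %.4f s, v_mean in [%.3g, %.3g] m/s\n",
              x$geometry, m_to_mm(x$radius_m), x$period_s, min(v), max(v)))
  invisible(x)
}
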