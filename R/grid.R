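# Structured staggered solver grids.
#
# Two topologies mirror the two flow physics of the AVF at desk scale:
# an axisymmetric body-fitted tube for the stenotic fistula (radius-mapped
# eta = r/R(z) coordinates), and a planar Cartesian masked T-junction for
# the flow-split physics (built in disc_planar.R).

.level_mult <- c(coarse = 1L, medium = 2L, fine = 4L)

#' Build a structured solver grid
#'
#' For `"axisymmetric_tube"`, the computational domain is the fistula/vein
#' path: z from minus the inlet extension (a straight run at the anastomosis
#' diameter that lets the parabolic inlet develop) to the end of the vein,
#' with the radius following the analytic profile of the geometry. The
#' radial coordinate is mapped (eta = r/R(z)) so the wall is a coordinate
#' surface; radial spacing is geometrically graded toward the wall
#' (neighbor ratio 1.2) to resolve wall shear. Refinement levels double the
#' resolution per axis (~4x the cells in 2D per step).
#'
#' For `"planar_junction"`, a Cartesian masked grid covers the artery
#' channel (PA inlet to DA outlet) and the fistula/vein branch with its
#' width profile; see [solve_unsteady()].
#'
#' @param spec an [avf_geometry()].
#' @param level `"coarse"`, `"medium"`, or `"fine"`.
#' @param topology grid topology.
#' @param base_nr radial cells across the (mapped) radius at coarse level.
#' @param base_nz_per_mm axial cells per mm at coarse level.
#' @param grading_ratio near-wall geometric grading ratio.
#' @return a `flow_grid` object.
#' @export
build_grid <- function(spec, level = c("coarse", "medium", "fine"),
                       topology = c("axisymmetric_tube", "planar_junction"),
                       base_nr = 8, base_nz_per_mm = 8, grading_ratio = 1.2) {
  level <- match.arg(level)
  topology <- match.arg(topology)
  mult <- .level_mult[[level]]
  if (topology == "planar_junction")
    return(.build_grid_planar(spec, level, mult))

  Lf <- spec$fistula$length
  Lv <- spec$vein$length
  ext <- spec$inlet_extension
  z0 <- -ext; z1 <- Lf + Lv              # mm along the fistula path
  Nz <- as.integer(round(base_nz_per_mm * (z1 - z0))) * mult
  Nr <- as.integer(base_nr) * mult
  if (2L * Nr < 8L)
    stop("fewer than 8 cells across the minimum lumen; increase base_nr")
  zf <- seq(z0, z1, length.out = Nz + 1)   # mm
  zc <- (zf[-1] + zf[-(Nz + 1)]) / 2
  # wall clustering by a fixed sinh stretching: the mapping is resolution-
  # independent, so refinement levels are nested samplings of one grid
  # family (neighbor spacing ratio ~1.3 at the coarse level, clustering
  # factor cosh(beta) ~ 3.8)
  beta <- 4 * log(grading_ratio) / log(1.2) * 0.5   # beta = 2 at ratio 1.2
  xi <- seq(0, 1, length.out = Nr + 1)
  etaf <- 1 - sinh(beta * (1 - xi)) / sinh(beta)
  etaf[1] <- 0; etaf[Nr + 1] <- 1
  etac <- (etaf[-1] + etaf[-(Nr + 1)]) / 2

  rad_mm <- function(s) ifelse(s < 0, fistula_diameter(spec, 0) / 2,
                               fistula_diameter(spec, s) / 2)
  radp <- function(s) ifelse(s < 0, 0, fistula_diameter_deriv(spec, s) / 2)
  # analytic curvature, one-sided at the extension junction: numerical
  # differencing across the kink would inject a huge spurious metric term
  radpp <- function(s) ifelse(s < 0, 0, fistula_diameter_deriv2(spec, s) / 2)

  g <- list(topology = topology, level = level, spec = spec,
            Nz = Nz, Nr = Nr,
            zf = mm_to_m(zf), zc = mm_to_m(zc),
            etaf = etaf, etac = etac,
            dz = mm_to_m(zf[2] - zf[1]),
            R_zf = mm_to_m(rad_mm(zf)), R_zc = mm_to_m(rad_mm(zc)),
            Rp_zf = radp(zf), Rp_zc = radp(zc),          # dimensionless dR/dz
            Rpp_zf = radpp(zf) / mm_to_m(1),             # 1/m
            Rpp_zc = radpp(zc) / mm_to_m(1),
            s_mm = zc)                                   # station arc length
  class(g) <- "flow_grid"
  g
}

#' @export
print.flow_grid <- function(x, ...) {
  if (x$topology == "axisymmetric_tube") {
    cat(sprintf("flow_grid (axisymmetric tube, %s): %d x %d cells, z in [%.1f, %.1f] mm\n",
                x$level, x$Nz, x$Nr, m_to_mm(min(x$zf)), m_to_mm(max(x$zf))))
    cat(sprintf("  radius %.3f-%.3f mm, near-wall cell %.1f um\n",
                m_to_mm(min(x$R_zc)), m_to_mm(max(x$R_zc)),
                (x$etaf[x$Nr + 1] - x$etaf[x$Nr]) * min(x$R_zc) * 1e6))
  } else {
    cat(sprintf("flow_grid (planar junction, %s): %d x %d cells (%d fluid), h = %.1f um\n",
                x$level, x$Nx, x$Ny, sum(x$fluid), x$h * 1e6))
  }
  invisible(x)
}
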