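# Voxelized contrast-CT phantoms of the AVF network.
#
# The phantom emulates an in-vivo contrast-enhanced micro-CT acquisition at
# isotropic voxel size (default 72 um): voxels whose centers fall inside the
# vessel lumen take the contrast HU value, everything else the background,
# with optional additive Gaussian noise. Scanner physics (beam hardening,
# contrast kinetics) is deliberately not modeled.

#' Construct a voxel volume
#'
#' @param values 3D numeric array of HU values.
#' @param spacing_um isotropic voxel spacing in micrometres.
#' @param origin_mm physical coordinate (mm) of the center of voxel (1,1,1).
#' @return a `voxel_volume` object.
#' @export
voxel_volume <- function(values, spacing_um, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3 || any(dim(values) < 2))
    stop("values must be a 3D array with at least 2 voxels per axis")
  if (spacing_um <= 0) stop("spacing must be positive")
  structure(list(values = values, spacing_um = spacing_um,
                 origin_mm = origin_mm),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume: %s voxels at %g um isotropic\n",
              paste(dim(x$values), collapse = " x "), x$spacing_um))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

# signed distance (mm) from points to the lumen surface; negative inside.
# Artery runs along x through the origin; the fistula/vein leaves the origin
# in the xy-plane at the anastomosis angle. A smooth-minimum of the two tube
# distance fields blends the junction with a small fillet.
.lumen_sdf <- function(spec, x, y, z, blend_mm = 0.05) {
  ext <- spec$inlet_extension
  lpa <- spec$proximal_artery$length + ext
  lda <- spec$distal_artery$length + ext
  rpa <- spec$proximal_artery$diameter / 2
  rda <- spec$distal_artery$diameter / 2
  # artery radius: PA level for x<0, DA for x>0, smooth transition near 0
  tblend <- smoothstep((x + 0.15) / 0.3)
  ra <- rpa + (rda - rpa) * tblend
  d_rad <- sqrt(y^2 + z^2) - ra
  d_cap <- pmax(-lpa - x, x - lda)  # positive beyond the artery ends
  d_art <- pmax(d_rad, d_cap)
  theta <- spec$anastomosis_angle * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  s <- x * ux + y * uy                       # arc length along the branch
  d_perp <- sqrt((x - s * ux)^2 + (y - s * uy)^2 + z^2)
  Ltot <- spec$fistula$length + spec$vein$length
  rf <- fistula_diameter(spec, pmax(pmin(s, Ltot), 0)) / 2
  d_fis <- pmax(d_perp - rf, pmax(-s, s - Ltot))
  # smooth minimum (log-sum-exp) => filleted union
  k <- blend_mm
  m <- pmin(d_art, d_fis)
  -k * log(exp(-(d_art - m) / k) + exp(-(d_fis - m) / k)) + m
}

#' Voxelize an AVF phantom
#'
#' Renders a geometry into a contrast-CT-like volume: lumen voxels take
#' `hu_vessel`, background voxels `hu_background`, plus Gaussian noise with
#' standard deviation `noise_sd` (deterministic for a fixed `seed`).
#'
#' @param spec an [avf_geometry()].
#' @param spacing_um isotropic voxel spacing (default 72, the scan
#'   resolution emulated here).
#' @param hu_vessel HU of contrast-filled lumen; must lie in the
#'   segmentation window `[300, 1000]`.
#' @param hu_background background HU; must be below 300.
#' @param noise_sd additive Gaussian noise sd in HU.
#' @param seed RNG seed for the noise.
#' @param margin_mm empty margin around the vessel bounding box.
#' @return a [voxel_volume()].
#' @export
voxelize_phantom <- function(spec, spacing_um = 72, hu_vessel = 650,
                             hu_background = 0, noise_sd = 0, seed = 0,
                             margin_mm = 0.4) {
  if (spacing_um <= 0) stop("spacing must be positive")
  if (!(hu_background < 300 && hu_vessel >= 300 && hu_vessel <= 1000))
    stop("need hu_background < 300 <= hu_vessel <= 1000 for the segmentation window")
  min_d <- min(spec$proximal_artery$diameter, spec$distal_artery$diameter,
               if (is.null(spec$fistula$stenosis)) spec$fistula$nominal_diameter
               else spec$fistula$stenosis$min_diameter)
  h <- um_to_mm(spacing_um)
  if (min_d / h < 3)
    stop(sprintf(paste0("voxel spacing %g um spans the minimum lumen diameter ",
                        "(%g mm) with fewer than 3 voxels; use finer spacing"),
                 spacing_um, min_d))
  ext <- spec$inlet_extension
  theta <- spec$anastomosis_angle * pi / 180
  Ltot <- spec$fistula$length + spec$vein$length
  rmax <- max(spec$vein$max_diameter, spec$fistula$nominal_diameter,
              spec$distal_artery$diameter) / 2
  xlim <- c(-(spec$proximal_artery$length + ext) - margin_mm,
            max(spec$distal_artery$length + ext, Ltot * cos(theta)) + margin_mm)
  ylim <- c(-rmax - margin_mm, max(Ltot * sin(theta) + rmax, rmax) + margin_mm)
  zlim <- c(-rmax - margin_mm, rmax + margin_mm)
  xs <- seq(xlim[1], xlim[2], by = h)
  ys <- seq(ylim[1], ylim[2], by = h)
  zs <- seq(zlim[1], zlim[2], by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  # evaluate the SDF slab-by-slab in z to bound memory
  vals <- array(hu_background, dim = c(nx, ny, nz))
  xg <- rep(xs, times = ny)
  yg <- rep(ys, each = nx)
  for (k in seq_len(nz)) {
    sdf <- .lumen_sdf(spec, xg, yg, rep(zs[k], nx * ny))
    vals[, , k] <- ifelse(sdf < 0, hu_vessel, hu_background)
  }
  if (noise_sd > 0) {
    rng_old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    vals <- vals + array(stats::rnorm(length(vals), sd = noise_sd), dim = dim(vals))
    if (!is.null(rng_old)) assign(".Random.seed", rng_old, envir = globalenv())
  }
  voxel_volume(vals, spacing_um, origin_mm = c(xs[1], ys[1], zs[1]))
}

#' Read/write voxel volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving the isotropic spacing (stored in the
#' NIfTI pixdim, in mm).
#'
#' @param vol a `voxel_volume` (or `lumen_mask`).
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a `voxel_volume`.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(um_to_mm(vol$spacing_um), 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing_um = sp * 1e3)
}
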