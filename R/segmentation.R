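# Lumen segmentation: HU-window thresholding followed by seeded region
# growing, mirroring the interactive threshold + region-grow chain used for
# contrast micro-CT angiography.

#' Construct a lumen mask
#'
#' @param values 3D logical (or 0/1) array.
#' @param spacing_um isotropic spacing in micrometres.
#' @param origin_mm physical coordinate of voxel (1,1,1).
#' @param provenance list recording how the mask was produced.
#' @return a `lumen_mask` object.
#' @export
lumen_mask <- function(values, spacing_um, origin_mm = c(0, 0, 0),
                       provenance = list()) {
  if (length(dim(values)) != 3) stop("mask must be a 3D array")
  values <- array(as.logical(values), dim = dim(values))
  if (!any(values)) stop("mask has no foreground voxels")
  structure(list(values = values, spacing_um = spacing_um,
                 origin_mm = origin_mm, provenance = provenance),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("lumen_mask: %s voxels at %g um, %d foreground (%.2f mm^3)\n",
              paste(dim(x$values), collapse = " x "), x$spacing_um,
              sum(x$values), sum(x$values) * um_to_mm(x$spacing_um)^3))
  invisible(x)
}

#' Threshold segmentation of a CT-like volume
#'
#' Marks as foreground every voxel whose HU value lies inside the inclusive
#' window `[lo, hi]`. The default window (300-1000 HU) isolates
#' contrast-enhanced vessels (and bone, which is removed downstream by
#' seeded region growing).
#'
#' @param volume a [voxel_volume()].
#' @param lo,hi window bounds in HU (inclusive), `lo < hi`.
#' @return a `lumen_mask`.
#' @export
threshold_segment <- function(volume, lo = 300, hi = 1000) {
  if (!(lo < hi)) stop("need lo < hi")
  m <- volume$values >= lo & volume$values <= hi
  if (!any(m))
    stop("thresholding produced an empty mask; review the HU window")
  lumen_mask(m, volume$spacing_um, volume$origin_mm,
             provenance = list(threshold = c(lo = lo, hi = hi)))
}

# neighbor offsets for 6/18/26 connectivity
.conn_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

# label connected components of a logical 3D array; returns integer array
# (0 = background). Flood fill over linear indices, vectorized frontier.
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  off <- .conn_offsets(connectivity)
  lin_off <- off$dx + off$dy * dm[1] + off$dz * dm[1] * dm[2]
  lab <- array(0L, dim = dm)
  idx_all <- which(mask)
  cur_lab <- 0L
  # coordinates are needed to reject wrap-around neighbors at array edges
  coord <- arrayInd(seq_len(prod(dm)), dm)  # heavy but fine at phantom sizes
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur_lab <- cur_lab + 1L
    lab[start] <- cur_lab
    frontier <- start
    while (length(frontier)) {
      cand <- rep(frontier, each = nrow(off)) + rep(lin_off, times = length(frontier))
      base <- rep(frontier, each = nrow(off))
      ok <- cand >= 1 & cand <= prod(dm)
      cand <- cand[ok]; base <- base[ok]
      # reject neighbors that wrapped across an array face
      keep <- abs(coord[cand, 1] - coord[base, 1]) <= 1 &
        abs(coord[cand, 2] - coord[base, 2]) <= 1 &
        abs(coord[cand, 3] - coord[base, 3]) <= 1
      cand <- unique(cand[keep])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur_lab
      frontier <- cand
    }
  }
  lab
}

#' Seeded region growing
#'
#' Keeps only the connected components of the mask that contain at least one
#' seed, removing disconnected structures (e.g., bone) that survived
#' thresholding.
#'
#' @param mask a `lumen_mask`.
#' @param seeds list (or matrix rows) of voxel index triples `(i, j, k)`;
#'   every seed must be a foreground voxel.
#' @param connectivity 6, 18, or 26 (default 26, matching the usual
#'   interactive-tool behavior).
#' @return a `lumen_mask` containing only the seeded components.
#' @export
region_grow <- function(mask, seeds, connectivity = 26) {
  if (is.matrix(seeds)) seeds <- asplit(seeds, 1)
  dm <- dim(mask$values)
  lin <- vapply(seeds, function(s) {
    s <- as.integer(s)
    if (length(s) != 3 || any(s < 1) || any(s > dm))
      stop(sprintf("seed (%s) is outside the volume", paste(s, collapse = ",")))
    s[1] + (s[2] - 1L) * dm[1] + (s[3] - 1L) * dm[1] * dm[2]
  }, integer(1))
  bad <- which(!mask$values[lin])
  if (length(bad))
    stop(sprintf("seed (%s) lies on a background voxel",
                 paste(as.integer(seeds[[bad[1]]]), collapse = ",")))
  lab <- label_components(mask$values, connectivity)
  keep <- unique(lab[lin])
  out <- array(lab %in% keep, dim = dm)
  lumen_mask(out, mask$spacing_um, mask$origin_mm,
             provenance = c(mask$provenance,
                            list(seeds = seeds, connectivity = connectivity)))
}
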