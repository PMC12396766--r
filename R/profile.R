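# Cross-sectional area / equivalent-diameter profiles along a centerline,
# window statistics, temporal comparison, and Poiseuille resistance.

#' Cross-sectional diameter profile along a centerline
#'
#' At every centerline station, intersects the lumen mask with the plane
#' normal to the local tangent, keeps the connected in-plane region
#' containing the centerline point, and reports its area and equivalent
#' diameter 2*sqrt(A/pi) (cross sections need not be circular, particularly
#' near the anastomosis).
#'
#' @param cl a [centerline()].
#' @param mask the `lumen_mask` the centerline was extracted from.
#' @param ds station spacing in mm; stations are taken from the centerline
#'   resampled at this spacing.
#' @param plane_halfwidth_mm half-width of the sampled plane window; defaults
#'   to a generous multiple of the largest expected diameter.
#' @param oversample in-plane sampling resolution relative to the voxel size.
#' @return a `diameter_profile` data frame (`s_mm`, `area_mm2`,
#'   `diameter_mm`); stations whose plane misses the mask are dropped with a
#'   warning.
#' @export
cross_section_profile <- function(cl, mask, ds = 0.05,
                                  plane_halfwidth_mm = NULL, oversample = 4) {
  if (ds <= 0) stop("ds must be positive")
  h <- um_to_mm(mask$spacing_um)
  if (is.null(plane_halfwidth_mm)) plane_halfwidth_mm <- max(1.2, 6 * h)
  # stations at uniform ds over the centerline's s range
  s_st <- seq(min(cl$s), max(cl$s), by = ds)
  pts <- sapply(1:3, function(c3) stats::approx(cl$s, cl$points[, c3], xout = s_st)$y)
  tans <- sapply(1:3, function(c3) stats::approx(cl$s, cl$tangents[, c3], xout = s_st)$y)
  tans <- tans / sqrt(rowSums(tans^2))
  hp <- h / oversample
  grid1 <- seq(-plane_halfwidth_mm, plane_halfwidth_mm, by = hp)
  ng <- length(grid1)
  uu <- rep(grid1, times = ng)
  vv <- rep(grid1, each = ng)
  dmv <- dim(mask$values)
  res <- lapply(seq_along(s_st), function(q) {
    t3 <- tans[q, ]
    # orthonormal in-plane basis
    ref <- if (abs(t3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * t3) * t3
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t3[2] * e1[3] - t3[3] * e1[2],
            t3[3] * e1[1] - t3[1] * e1[3],
            t3[1] * e1[2] - t3[2] * e1[1])
    px <- pts[q, 1] + uu * e1[1] + vv * e2[1]
    py <- pts[q, 2] + uu * e1[2] + vv * e2[2]
    pz <- pts[q, 3] + uu * e1[3] + vv * e2[3]
    # nearest-voxel lookup of the binary mask
    ii <- round((px - mask$origin_mm[1]) / h) + 1
    jj <- round((py - mask$origin_mm[2]) / h) + 1
    kk <- round((pz - mask$origin_mm[3]) / h) + 1
    ok <- ii >= 1 & ii <= dmv[1] & jj >= 1 & jj <= dmv[2] & kk >= 1 & kk <= dmv[3]
    inm <- logical(length(px))
    inm[ok] <- mask$values[cbind(ii[ok], jj[ok], kk[ok])]
    if (!any(inm)) return(NULL)
    img <- matrix(inm, ng, ng)
    ctr <- (ng + 1) / 2
    if (!img[ctr, ctr]) return(NULL)
    # keep the in-plane connected region containing the centerline point
    lab <- .label2d(img)
    area <- sum(lab == lab[ctr, ctr]) * hp^2
    c(s = s_st[q], area = area)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!all(keep))
    warning(sprintf("%d station(s) dropped: section plane missed the lumen",
                    sum(!keep)))
  if (!any(keep)) stop("no station intersected the lumen")
  m <- do.call(rbind, res[keep])
  new_diameter_profile(data.frame(
    s_mm = m[, "s"],
    area_mm2 = m[, "area"],
    diameter_mm = 2 * sqrt(m[, "area"] / pi)))
}

# 4-connected 2D component labeling (small images; frontier flood fill)
.label2d <- function(img) {
  dm <- dim(img)
  lab <- matrix(0L, dm[1], dm[2])
  idx <- which(img)
  off <- c(-1L, 1L, -dm[1], dm[1])
  cur <- 0L
  for (st in idx) {
    if (lab[st] != 0L) next
    cur <- cur + 1L
    lab[st] <- cur
    frontier <- st
    while (length(frontier)) {
      cand <- rep(frontier, each = 4L) + rep(off, times = length(frontier))
      base <- rep(frontier, each = 4L)
      ok <- cand >= 1L & cand <= length(img)
      # forbid row wrap-around for the +-1 offsets
      same_col <- ((cand - 1L) %/% dm[1]) == ((base - 1L) %/% dm[1])
      vert <- rep(c(TRUE, TRUE, FALSE, FALSE), times = length(frontier))
      ok <- ok & (!vert | same_col)
      cand <- unique(cand[ok])
      cand <- cand[img[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

#' Window statistics of a diameter profile
#'
#' Mean, minimum, and maximum equivalent diameter over an arc-length window,
#' the statistic reported per vessel segment (e.g., the first 2 mm or 4 mm of
#' the fistula).
#'
#' @param profile a `diameter_profile`.
#' @param window numeric `c(s_start, s_end)` in mm, or a list with fields
#'   `label`, `s_start`, `s_end`.
#' @param branch optional branch filter when the profile has a `branch`
#'   column (e.g., `"AVF"`).
#' @return a `segment_stats` list: `label`, `s_start`, `s_end`, `mean_mm`,
#'   `min_mm`, `max_mm`, `n_stations`.
#' @export
segment_stats <- function(profile, window, branch = NULL) {
  if (is.list(window) && !is.null(window$s_start)) {
    lab <- window$label %||% ""
    w <- c(window$s_start, window$s_end)
  } else {
    lab <- ""
    w <- as.numeric(window)
  }
  if (w[1] > w[2]) stop("window start exceeds end")
  df <- as.data.frame(profile)
  if (!is.null(branch) && "branch" %in% names(df)) df <- df[df$branch %in% branch, ]
  sel <- df$s_mm >= w[1] - 1e-9 & df$s_mm <= w[2] + 1e-9
  if (!any(sel)) stop("window contains no profile stations")
  d <- df$diameter_mm[sel]
  structure(list(label = lab, s_start = w[1], s_end = w[2],
                 mean_mm = mean(d), min_mm = min(d), max_mm = max(d),
                 n_stations = sum(sel)),
            class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf("segment %s [%g, %g] mm: mean %.3f (%.3f - %.3f) mm, %d stations\n",
              x$label, x$s_start, x$s_end, x$mean_mm, x$min_mm, x$max_mm,
              x$n_stations))
  invisible(x)
}

#' Percent change between two diameters
#'
#' `100 * (new - old) / old`: negative values are narrowing, positive values
#' expansion.
#'
#' @param old,new diameters (mm), `old > 0`.
#' @return percent change, with a `direction` attribute
#'   (`"narrowing"`, `"expansion"`, or `"unchanged"`).
#' @examples
#' percent_change(0.74, 0.58)  # -21.6
#' @export
percent_change <- function(old, new) {
  if (any(old <= 0)) stop("old diameter must be positive")
  pc <- 100 * (new - old) / old
  attr(pc, "direction") <- ifelse(pc < 0, "narrowing",
                                  ifelse(pc > 0, "expansion", "unchanged"))
  pc
}

#' Poiseuille flow resistance of a diameter profile
#'
#' Integrates the local Poiseuille resistance density `8 mu / (pi r(s)^4)`
#' over an arc-length range by the trapezoid rule on the profile stations,
#' giving the hydraulic resistance (Pa s / m^3) of the segment under fully
#' developed laminar flow.
#'
#' @param profile a `diameter_profile`.
#' @param mu dynamic viscosity in Pa s (default 4e-3, whole blood).
#' @param s_range `c(s_start, s_end)` in mm; must be covered by the profile.
#' @param branch optional branch filter.
#' @return resistance in Pa s / m^3.
#' @export
poiseuille_resistance <- function(profile, mu = 4e-3, s_range = NULL,
                                  branch = NULL) {
  df <- as.data.frame(profile)
  if (!is.null(branch) && "branch" %in% names(df)) df <- df[df$branch %in% branch, ]
  if (is.null(s_range)) s_range <- range(df$s_mm)
  if (s_range[1] < min(df$s_mm) - 1e-9 || s_range[2] > max(df$s_mm) + 1e-9)
    stop("profile does not cover s_range")
  sel <- df$s_mm >= s_range[1] - 1e-9 & df$s_mm <= s_range[2] + 1e-9
  s_m <- mm_to_m(df$s_mm[sel])
  r_m <- mm_to_m(df$diameter_mm[sel] / 2)
  if (any(r_m <= 0)) stop("all radii must be positive")
  dens <- 8 * mu / (pi * r_m^4)
  sum(diff(s_m) * (dens[-1] + dens[-length(dens)]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
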