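# Centerline extraction from lumen masks: distance-transform-weighted
# shortest paths between labeled endpoints, resampled at uniform arc length,
# with the anastomosis (the PA/DA/fistula branch point) as the arc-length
# origin.

# chamfer distance transform (voxel units): distance from each foreground
# voxel to the nearest background voxel, two-pass 3x3x3 sweep with
# (1, sqrt2, sqrt3) local weights.
chamfer_dt <- function(mask) {
  dm <- dim(mask)
  big <- sum(dm)
  d <- array(0, dim = dm)
  d[mask] <- big
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  w <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  fwd <- offs$dz < 0 | (offs$dz == 0 & (offs$dy < 0 | (offs$dy == 0 & offs$dx < 0)))
  sweep_once <- function(d, use_fwd) {
    ks <- if (use_fwd) seq_len(dm[3]) else rev(seq_len(dm[3]))
    sel <- if (use_fwd) fwd else !fwd
    o <- offs[sel, ]; ww <- w[sel]
    for (k in ks) {
      for (q in seq_len(nrow(o))) {
        kk <- k + o$dz[q]
        if (kk < 1 || kk > dm[3]) next
        xs <- max(1, 1 - o$dx[q]):min(dm[1], dm[1] - o$dx[q])
        ys <- max(1, 1 - o$dy[q]):min(dm[2], dm[2] - o$dy[q])
        cand <- d[xs + o$dx[q], ys + o$dy[q], kk] + ww[q]
        cur <- d[xs, ys, k]
        upd <- cand < cur
        if (any(upd)) {
          cur[upd] <- cand[upd]
          d[xs, ys, k] <- cur
        }
      }
    }
    d
  }
  d <- sweep_once(d, TRUE)
  d <- sweep_once(d, FALSE)
  d + 0.5  # center of a surface voxel is half a voxel from the wall
}

#' Construct a centerline
#'
#' @param points n x 3 matrix of ordered centerline points (mm).
#' @param s arc length (mm) per point, s = 0 at the anastomosis, negative
#'   toward the proximal artery.
#' @param branch character vector of branch labels per point
#'   (`"PA"`, `"DA"`, `"AVF"`, `"vein"`).
#' @return a `centerline` object with unit tangents.
#' @export
centerline <- function(points, s, branch = NULL) {
  stopifnot(nrow(points) == length(s))
  if (any(diff(s) <= 0)) stop("arc length must be strictly increasing")
  seg <- diff(s)
  tang <- matrix(NA_real_, nrow(points), 3)
  n <- nrow(points)
  tang[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tang[1, ] <- points[2, ] - points[1, ]
  tang[n, ] <- points[n, ] - points[n - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, s = s, tangents = tang, branch = branch),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, s in [%.2f, %.2f] mm\n",
              nrow(x$points), min(x$s), max(x$s)))
  invisible(x)
}

# Dijkstra path between two voxels through the mask, weighted so the path
# hugs the distance-transform ridge (weight = step length / dt^2).
.dt_weighted_path <- function(mask, dt, from, to, spacing_mm) {
  dm <- dim(mask)
  lin <- function(p) p[1] + (p[2] - 1) * dm[1] + (p[3] - 1) * dm[1] * dm[2]
  fg <- which(mask)
  id_of <- integer(prod(dm))
  id_of[fg] <- seq_along(fg)
  coord <- arrayInd(fg, dm)
  offs <- .conn_offsets(26)
  edges_i <- integer(0); edges_j <- integer(0); edges_w <- numeric(0)
  for (q in seq_len(nrow(offs))) {
    dx <- offs$dx[q]; dy <- offs$dy[q]; dz <- offs$dz[q]
    if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))) next  # undirected
    ii <- coord[, 1] + dx; jj <- coord[, 2] + dy; kk <- coord[, 3] + dz
    ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
    nb_lin <- ii[ok] + (jj[ok] - 1) * dm[1] + (kk[ok] - 1) * dm[1] * dm[2]
    keep <- mask[nb_lin]
    a <- id_of[fg[ok]][keep]
    b <- id_of[nb_lin[keep]]
    step <- sqrt(dx^2 + dy^2 + dz^2)
    wgt <- step * 0.5 * (1 / dt[fg[ok]][keep]^2 + 1 / dt[nb_lin[keep]]^2)
    edges_i <- c(edges_i, a); edges_j <- c(edges_j, b); edges_w <- c(edges_w, wgt)
  }
  g <- igraph::graph_from_edgelist(cbind(edges_i, edges_j), directed = FALSE)
  igraph::E(g)$weight <- edges_w
  vfrom <- id_of[lin(from)]; vto <- id_of[lin(to)]
  if (vfrom == 0 || vto == 0) stop("endpoint lies outside the mask")
  sp <- igraph::shortest_paths(g, vfrom, vto, output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp)) stop("endpoints lie in different connected components")
  coord[vp, , drop = FALSE]
}

# moving-average smoothing of a polyline, then uniform-ds resampling
.resample_path <- function(pts_mm, ds, smooth_win = 5) {
  n <- nrow(pts_mm)
  if (n > 2 * smooth_win + 1) {
    sm <- pts_mm
    for (c3 in 1:3) {
      x <- pts_mm[, c3]
      cs <- cumsum(c(0, x))
      i0 <- pmax(1, seq_len(n) - smooth_win)
      i1 <- pmin(n, seq_len(n) + smooth_win)
      sm[, c3] <- (cs[i1 + 1] - cs[i0]) / (i1 - i0 + 1)
    }
    sm[1, ] <- pts_mm[1, ]; sm[n, ] <- pts_mm[n, ]
    pts_mm <- sm
  }
  seg <- sqrt(rowSums((pts_mm[-1, , drop = FALSE] - pts_mm[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  stot <- cum[length(cum)]
  s_out <- seq(0, stot, by = ds)
  if (s_out[length(s_out)] < stot - 1e-9) s_out <- c(s_out, stot)
  out <- sapply(1:3, function(c3) stats::approx(cum, pts_mm[, c3], xout = s_out)$y)
  list(points = out, s = s_out)
}

# nearest distance from each row of pts to the polyline 'line' (both n x 3)
.dist_to_polyline <- function(pts, line) {
  apply(pts, 1, function(p) {
    min(sqrt(colSums((t(line) - p)^2)))
  })
}

# closest point between two fitted lines (point + unit direction each)
.line_closest_point <- function(p1, d1, p2, d2) {
  w <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * c - b^2
  if (abs(den) < 1e-12) return((p1 + p2) / 2)
  t1 <- (b * e - c * d) / den
  t2 <- (a * e - b * d) / den
  ((p1 + t1 * d1) + (p2 + t2 * d2)) / 2
}

# principal direction + centroid of a point cloud
.fit_line <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(point = ctr, dir = sv$v[, 1])
}

#' Extract a labeled centerline from a lumen mask
#'
#' Computes distance-transform-weighted shortest paths (paths of maximal
#' clearance from the wall) from the proximal-artery endpoint to the venous
#' endpoint and from the proximal to the distal artery endpoint. The
#' anastomosis is located as the branch point of the PA/DA/fistula
#' centerline graph; because ridge paths cut the corner inside the junction
#' blend, the branch point is refined as the closest approach of the artery
#' axis and the fistula axis (each fitted to the straight part of its
#' branch). Arc length s is 0 there, negative toward the proximal artery,
#' positive into the fistula and vein.
#'
#' @param mask a connected `lumen_mask`.
#' @param endpoints named list with voxel index triples `PA`, `DA`, `vein`
#'   (each inside the mask). If `DA` is `NULL`, a single PA-to-vein path is
#'   returned with s = 0 at the path start.
#' @param ds resampling station spacing in mm (default 0.05).
#' @return a [centerline()] with branches `PA`, `DA` (s < 0) and `AVF`
#'   (s > 0). The DA branch is appended after the AVF branch rows.
#' @export
extract_centerline <- function(mask, endpoints, ds = 0.05) {
  h <- um_to_mm(mask$spacing_um)
  dt <- chamfer_dt(mask$values)
  to_mm <- function(idx) sweep((idx - 1) * h, 2, mask$origin_mm, "+")
  p_main <- .dt_weighted_path(mask$values, dt, endpoints$PA, endpoints$vein, h)
  if (is.null(endpoints$DA)) {
    rs <- .resample_path(to_mm(p_main), ds)
    return(centerline(rs$points, rs$s,
                      branch = rep("AVF", length(rs$s))))
  }
  p_art <- .dt_weighted_path(mask$values, dt, endpoints$PA, endpoints$DA, h)
  main_mm <- .resample_path(to_mm(p_main), ds)
  art_mm <- .resample_path(to_mm(p_art), ds)

  # rough junction: last main-path point still on the artery ridge
  d_art <- .dist_to_polyline(main_mm$points, art_mm$points)
  on_art <- d_art < 1.5 * h
  if (!any(on_art)) stop("PA-vein and PA-DA paths do not share the artery")
  j0 <- max(which(on_art))
  s_rough <- main_mm$s[j0]

  # refine: fit the artery axis and the fistula axis away from the junction,
  # anchor s = 0 at their closest approach
  art_far <- abs(art_mm$s - art_mm$s[which.min(
    .dist_to_polyline(art_mm$points, main_mm$points[j0, , drop = FALSE]))]) > 0.8
  fis_sel <- main_mm$s > s_rough + 0.8 & main_mm$s < s_rough + 2.5
  lf <- NULL
  anchor <- if (sum(art_far) >= 5 && sum(fis_sel) >= 5) {
    la <- .fit_line(art_mm$points[art_far, , drop = FALSE])
    lf <- .fit_line(main_mm$points[fis_sel, , drop = FALSE])
    .line_closest_point(la$point, la$dir, lf$point, lf$dir)
  } else {
    main_mm$points[j0, ]
  }
  # s = 0 where the main path passes closest to the anchor
  d_anchor <- sqrt(colSums((t(main_mm$points) - anchor)^2))
  s0 <- main_mm$s[which.min(d_anchor)]
  s_main <- main_mm$s - s0
  if (!is.null(lf)) {
    # ridge paths round the junction corner, which shortens the arc length of
    # every downstream station; register the arc length to the fistula axis
    # over the straight fitting window so stations carry axis-true s
    proj <- as.vector(sweep(main_mm$points, 2, anchor) %*% lf$dir)
    if (stats::cor(proj[fis_sel], s_main[fis_sel]) < 0) proj <- -proj
    s_main <- s_main - mean(s_main[fis_sel] - proj[fis_sel])
  }
  br_main <- ifelse(s_main < 0, "PA", "AVF")

  # distal artery branch: artery-path points beyond the junction, s negative
  d_anchor_art <- sqrt(colSums((t(art_mm$points) - anchor)^2))
  ja <- which.min(d_anchor_art)
  if (ja < nrow(art_mm$points) - 2) {
    da_pts <- art_mm$points[ja:nrow(art_mm$points), , drop = FALSE]
    s_da <- -(art_mm$s[ja:nrow(art_mm$points)] - art_mm$s[ja])
    ord <- order(s_da)
    cl_da <- centerline(da_pts[ord, , drop = FALSE], s_da[ord],
                        rep("DA", length(s_da)))
  } else {
    cl_da <- NULL
  }
  cl <- centerline(main_mm$points, s_main, br_main)
  if (!is.null(cl_da)) {
    cl$da_branch <- cl_da
  }
  cl
}
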