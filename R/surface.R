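# Surface extraction from binary lumen masks.
#
# The isosurface is taken at the half-way level of the binary mask. For
# sub-voxel accuracy the binary field is first converted to a narrow-band
# signed Euclidean distance field (distance to the nearest opposite-phase
# voxel center, positive inside), whose zero level coincides with the 0.5
# level of the indicator; the level set is then triangulated by marching
# tetrahedra (six tetrahedra per cube, shared main diagonal), which is
# simpler than full marching cubes and produces watertight, consistently
# oriented meshes without an ambiguity table.

#' Construct a triangular surface mesh
#'
#' @param vertices n x 3 matrix of vertex coordinates in mm.
#' @param faces m x 3 integer matrix of vertex indices (1-based), outward
#'   oriented.
#' @return a `surface_mesh` with a `watertight` flag.
#' @export
surface_mesh <- function(vertices, faces) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  m <- structure(list(vertices = vertices, faces = faces, watertight = NA),
                 class = "surface_mesh")
  a <- mesh_areas(m)
  if (any(a < .Machine$double.eps))
    stop("mesh contains degenerate (zero-area) faces")
  m$watertight <- is_watertight(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), x$watertight))
  cat(sprintf("  area %.4f mm^2, volume %.4f mm^3\n",
              mesh_area(x), mesh_volume(x)))
  invisible(x)
}

# per-face areas
mesh_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh area, volume, and topology helpers
#'
#' `mesh_area` sums triangle areas (mm^2); `mesh_volume` uses the divergence
#' theorem on the outward-oriented faces (mm^3); `is_watertight` checks that
#' every undirected edge is shared by exactly two faces;
#' `euler_characteristic` returns V - E + F.
#'
#' @param mesh a `surface_mesh`.
#' @name mesh_props
NULL

#' @rdname mesh_props
#' @export
mesh_area <- function(mesh) sum(mesh_areas(mesh))

#' @rdname mesh_props
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

# undirected edge keys of all faces
.edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' @rdname mesh_props
#' @export
is_watertight <- function(mesh) {
  all(table(.edge_keys(mesh$faces)) == 2)
}

#' @rdname mesh_props
#' @export
euler_characteristic <- function(mesh) {
  nE <- length(unique(.edge_keys(mesh$faces)))
  nrow(mesh$vertices) - nE + nrow(mesh$faces)
}

# narrow-band signed Euclidean distance (in voxels): positive inside.
# Exact within the search radius; +-(radius) outside the band.
.signed_band_edt <- function(mask, radius = 2L) {
  dm <- dim(mask)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  dist <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  ord <- order(dist)
  offs <- offs[ord, ]; dist <- dist[ord]
  big <- radius + 1
  d_in <- array(big, dim = dm)   # distance from inside voxels to background
  d_out <- array(big, dim = dm)  # distance from outside voxels to foreground
  for (q in seq_along(dist)[-1]) {
    dx <- offs$dx[q]; dy <- offs$dy[q]; dz <- offs$dz[q]
    # shifted copy of mask: sh[i,j,k] = mask[i+dx, j+dy, k+dz] (FALSE off-grid)
    sh <- array(FALSE, dim = dm)
    xs <- max(1, 1 - dx):min(dm[1], dm[1] - dx)
    ys <- max(1, 1 - dy):min(dm[2], dm[2] - dy)
    zs <- max(1, 1 - dz):min(dm[3], dm[3] - dz)
    sh[xs, ys, zs] <- mask[xs + dx, ys + dy, zs + dz]
    upd_in <- mask & !sh & d_in > dist[q]
    d_in[upd_in] <- dist[q]
    upd_out <- !mask & sh & d_out > dist[q]
    d_out[upd_out] <- dist[q]
  }
  f <- array(0, dim = dm)
  f[mask] <- d_in[mask] - 0.5
  f[!mask] <- -(d_out[!mask] - 0.5)
  f
}

#' Extract a triangulated lumen surface
#'
#' Triangulates the half-way isosurface of a binary mask (via a narrow-band
#' signed distance field and marching tetrahedra) in physical mm
#' coordinates. The result is watertight and outward oriented for solid
#' masks.
#'
#' @param mask a `lumen_mask`.
#' @param smooth_sigma Gaussian pre-smoothing of the distance field, in
#'   voxels. The default (0.6) suppresses voxelization faceting with
#'   sub-percent area bias for structures at least ~3 voxels across (which
#'   the phantom voxelizer guarantees for the lumen); set 0 to triangulate
#'   voxel-scale detail exactly.
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(mask, smooth_sigma = 0.6) {
  m <- mask$values
  dm <- dim(m)
  if (any(m[1, , ]) || any(m[dm[1], , ]) || any(m[, 1, ]) || any(m[, dm[2], ]) ||
      any(m[, , 1]) || any(m[, , dm[3]]))
    stop("mask touches the volume border; pad or crop before surfacing")
  f <- .signed_band_edt(m)
  if (smooth_sigma > 0) f <- .gaussian_blur3(f, smooth_sigma)
  f[f == 0] <- -1e-9
  tri <- .march_tets(f)
  if (is.null(tri)) stop("no isosurface found")
  h <- um_to_mm(mask$spacing_um)
  verts_mm <- sweep((tri$vertices - 1) * h, 2, mask$origin_mm, "+")
  surface_mesh(verts_mm, tri$faces)
}

# separable Gaussian blur via FFT (sigma in voxels); fields are constant
# far from the interface so circular wrap-around is harmless
.gaussian_blur3 <- function(f, sigma) {
  dm <- dim(f)
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (x / sigma)^2)
    k / sum(k)
  }
  K <- outer(outer(k1(dm[1]), k1(dm[2])), k1(dm[3]))
  dim(K) <- dm
  Re(stats::fft(stats::fft(f) * stats::fft(K), inverse = TRUE)) / prod(dm)
}

# marching tetrahedra on scalar field f (inside where f > 0); vertices in
# 1-based voxel-index coordinates. Returns deduplicated vertices + faces.
.march_tets <- function(f) {
  dm <- dim(f)
  inside <- f > 0
  # cubes with mixed corner signs
  nx <- dm[1] - 1L; ny <- dm[2] - 1L; nz <- dm[3] - 1L
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  cnt <- array(0L, dim = c(nx, ny, nz))
  for (cc in 1:8) {
    cnt <- cnt + inside[corner_off[cc, 1] + 1:nx,
                        corner_off[cc, 2] + 1:ny,
                        corner_off[cc, 3] + 1:nz]
  }
  mixed <- which(cnt > 0L & cnt < 8L)
  if (!length(mixed)) return(NULL)
  ci <- arrayInd(mixed, c(nx, ny, nz))
  # corner values and positions for mixed cubes: lists of length 8
  Fc <- vector("list", 8); Px <- vector("list", 8)
  Py <- vector("list", 8); Pz <- vector("list", 8)
  for (cc in 1:8) {
    ii <- ci[, 1] + corner_off[cc, 1]
    jj <- ci[, 2] + corner_off[cc, 2]
    kk <- ci[, 3] + corner_off[cc, 3]
    Fc[[cc]] <- f[cbind(ii, jj, kk)]
    Px[[cc]] <- ii; Py[[cc]] <- jj; Pz[[cc]] <- kk
  }
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
  TRI <- list(); nt <- 0
  ipt <- function(a, b, sel) {
    # crossing point on edge a-b for selected cubes
    fa <- Fc[[a]][sel]; fb <- Fc[[b]][sel]
    t <- fa / (fa - fb)
    cbind(Px[[a]][sel] + t * (Px[[b]][sel] - Px[[a]][sel]),
          Py[[a]][sel] + t * (Py[[b]][sel] - Py[[a]][sel]),
          Pz[[a]][sel] + t * (Pz[[b]][sel] - Pz[[a]][sel]))
  }
  pt <- function(a, sel) cbind(Px[[a]][sel], Py[[a]][sel], Pz[[a]][sel])
  emit <- function(v1, v2, v3, ref_in, ref_out) {
    # orient each triangle so its normal points from inside toward outside
    n1 <- v2 - v1; n2 <- v3 - v1
    nx_ <- n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2]
    ny_ <- n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3]
    nz_ <- n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1]
    dirx <- ref_out[, 1] - ref_in[, 1]
    diry <- ref_out[, 2] - ref_in[, 2]
    dirz <- ref_out[, 3] - ref_in[, 3]
    flip <- (nx_ * dirx + ny_ * diry + nz_ * dirz) < 0
    tmp <- v2[flip, , drop = FALSE]
    v2[flip, ] <- v3[flip, , drop = FALSE]
    v3[flip, ] <- tmp
    nt <<- nt + 1
    TRI[[nt]] <<- cbind(v1, v2, v3)
  }
  for (tt in 1:6) {
    A <- tets[tt, 1]; B <- tets[tt, 2]; C <- tets[tt, 3]; D <- tets[tt, 4]
    ins <- cbind(Fc[[A]] > 0, Fc[[B]] > 0, Fc[[C]] > 0, Fc[[D]] > 0)
    ni <- rowSums(ins)
    vs <- c(A, B, C, D)
    # one corner inside
    for (w in 1:4) {
      sel <- which(ni == 1 & ins[, w])
      if (!length(sel)) next
      others <- vs[-w]; me <- vs[w]
      v1 <- ipt(me, others[1], sel)
      v2 <- ipt(me, others[2], sel)
      v3 <- ipt(me, others[3], sel)
      emit(v1, v2, v3, pt(me, sel), (pt(others[1], sel) + pt(others[2], sel) +
                                       pt(others[3], sel)) / 3)
    }
    # three corners inside (one outside)
    for (w in 1:4) {
      sel <- which(ni == 3 & !ins[, w])
      if (!length(sel)) next
      others <- vs[-w]; me <- vs[w]
      v1 <- ipt(others[1], me, sel)
      v2 <- ipt(others[2], me, sel)
      v3 <- ipt(others[3], me, sel)
      emit(v1, v2, v3, (pt(others[1], sel) + pt(others[2], sel) +
                          pt(others[3], sel)) / 3, pt(me, sel))
    }
    # two corners inside: quad split into two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pp in seq_len(nrow(pairs))) {
      w1 <- pairs[pp, 1]; w2 <- pairs[pp, 2]
      sel <- which(ni == 2 & ins[, w1] & ins[, w2])
      if (!length(sel)) next
      ow <- setdiff(1:4, c(w1, w2))
      a <- vs[w1]; b <- vs[w2]; c1 <- vs[ow[1]]; c2 <- vs[ow[2]]
      q1 <- ipt(a, c1, sel); q2 <- ipt(a, c2, sel)
      q3 <- ipt(b, c2, sel); q4 <- ipt(b, c1, sel)
      rin <- (pt(a, sel) + pt(b, sel)) / 2
      rout <- (pt(c1, sel) + pt(c2, sel)) / 2
      emit(q1, q2, q3, rin, rout)
      emit(q1, q3, q4, rin, rout)
    }
  }
  tri <- do.call(rbind, TRI)
  V <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
  key <- paste(round(V[, 1], 6), round(V[, 2], 6), round(V[, 3], 6))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- V[uk, , drop = FALSE]
  ntri <- nrow(tri)
  faces <- cbind(idx[seq_len(ntri)], idx[ntri + seq_len(ntri)],
                 idx[2 * ntri + seq_len(ntri)])
  # drop degenerate faces from corner-touching configurations
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

#' Volume-preserving surface smoothing
#'
#' Taubin lambda/mu smoothing with uniform weights: alternating shrink
#' (lambda = 0.5) and inflate (mu = -0.53) passes remove voxelization
#' artifacts while keeping the enclosed volume nearly unchanged (< 2% for the
#' defaults), unlike plain Laplacian smoothing, whose shrinkage would bias
#' diameter statistics.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param iterations number of lambda+mu passes.
#' @return the smoothed `surface_mesh`, with attribute `max_displacement`
#'   (mm) recording the largest vertex movement.
#' @export
smooth_surface <- function(mesh, iterations = 10) {
  if (!isTRUE(mesh$watertight))
    stop("smoothing requires a watertight mesh")
  if (iterations == 0) {
    attr(mesh, "max_displacement") <- 0
    return(mesh)
  }
  v0 <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = rep(nrow(v0), 2))
  adj@x[] <- 1  # dedupe duplicated entries to weight 1
  deg <- Matrix::rowSums(adj)
  W <- Matrix::Diagonal(x = 1 / deg) %*% adj
  v <- v0
  for (it in seq_len(iterations)) {
    v <- v + 0.5 * (as.matrix(W %*% v) - v)
    v <- v - 0.53 * (as.matrix(W %*% v) - v)
  }
  out <- mesh
  out$vertices <- v
  attr(out, "max_displacement") <- sqrt(max(rowSums((v - v0)^2)))
  out
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "lumen") {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  blocks <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(blocks, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
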