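# Planar (2D channel) masked Cartesian discretization of the T-junction:
# proximal artery inlet on the left, distal artery on the right as a
# prescribed outflow (blood in the DA flows away from the junction), and the
# fistula/vein branch rising from the junction to a zero-pressure venous
# outlet. Channel widths equal the vessel diameters; the branch width
# follows the fistula diameter profile (stenosis and venous expansion
# included). Walls are stair-stepped cell boundaries with ghost-cell no-slip.

.build_grid_planar <- function(spec, level, mult) {
  wpa <- mm_to_m(spec$proximal_artery$diameter)
  wda <- mm_to_m(spec$distal_artery$diameter)
  ext <- mm_to_m(spec$inlet_extension)
  Lpa <- mm_to_m(spec$proximal_artery$length) + ext
  Lda <- mm_to_m(spec$distal_artery$length) + ext
  Lf <- mm_to_m(spec$fistula$length)
  Lv <- mm_to_m(spec$vein$length)
  min_w <- mm_to_m(min(spec$proximal_artery$diameter, spec$distal_artery$diameter,
                       if (is.null(spec$fistula$stenosis)) spec$fistula$nominal_diameter
                       else spec$fistula$stenosis$min_diameter))
  h <- min_w / (8 * mult)
  x0 <- -Lpa; x1 <- Lda
  y0 <- -max(wpa, wda) / 2; y1 <- Lf + Lv
  Nx <- as.integer(ceiling((x1 - x0) / h))
  Ny <- as.integer(ceiling((y1 - y0) / h))
  xc <- x0 + (seq_len(Nx) - 0.5) * h
  yc <- y0 + (seq_len(Ny) - 0.5) * h

  wf_of <- function(y) mm_to_m(fistula_diameter(spec, m_to_mm(pmax(y, 0))))
  fluid <- matrix(FALSE, Nx, Ny)
  for (j in seq_len(Ny)) {
    wa <- ifelse(xc < 0, wpa, wda)
    in_art <- abs(yc[j]) <= wa / 2
    in_branch <- yc[j] > 0 & abs(xc) <= wf_of(yc[j]) / 2
    fluid[, j] <- in_art | in_branch
  }
  g <- list(topology = "planar_junction", level = level, spec = spec,
            Nx = Nx, Ny = Ny, h = h, xc = xc, yc = yc, fluid = fluid,
            wpa = wpa, wda = wda)
  class(g) <- "flow_grid"
  g
}

make_planar_disc <- function(grid, fluid_props, inlet, da_split = 0) {
  Nx <- grid$Nx; Ny <- grid$Ny; h <- grid$h
  fl <- grid$fluid
  cid <- matrix(0L, Nx, Ny)
  cid[fl] <- seq_len(sum(fl))
  Np <- sum(fl)

  # --- u faces: between horizontally adjacent cells (interior unknowns);
  # west boundary faces of column-1 fluid cells are PA inlet externals, east
  # faces of column-Nx fluid cells are DA externals ---
  ufid <- matrix(0L, Nx + 1, Ny)    # >0 unknown, -k external index
  nu <- 0L; next_ext <- 0L
  ext_rows_pa <- integer(0); ext_rows_da <- integer(0)
  for (j in seq_len(Ny)) {
    for (i in seq_len(Nx + 1)) {
      left <- i > 1 && fl[i - 1, j]
      right <- i <= Nx && fl[i, j]
      if (left && right) {
        nu <- nu + 1L; ufid[i, j] <- nu
      } else if (!left && right && i == 1) {
        next_ext <- next_ext + 1L; ufid[i, j] <- -next_ext
        ext_rows_pa <- c(ext_rows_pa, next_ext)
      } else if (left && !right && i == Nx + 1) {
        next_ext <- next_ext + 1L; ufid[i, j] <- -next_ext
        ext_rows_da <- c(ext_rows_da, next_ext)
      }
    }
  }
  Nin <- next_ext
  Nu <- nu

  # --- v faces: between vertically adjacent fluid cells + top outlet ---
  vfid <- matrix(0L, Nx, Ny + 1)
  nv <- 0L
  top_v <- integer(0)
  for (j in seq_len(Ny + 1)) {
    for (i in seq_len(Nx)) {
      below <- j > 1 && fl[i, j - 1]
      above <- j <= Ny && fl[i, j]
      if (below && above) {
        nv <- nv + 1L; vfid[i, j] <- nv
      } else if (below && j == Ny + 1) {
        nv <- nv + 1L; vfid[i, j] <- nv     # venous outlet face
        top_v <- c(top_v, nv)
      }
    }
  }
  Nv <- nv

  tri <- function() list(i = integer(0), j = integer(0), x = numeric(0))
  addq <- function(tr, i, j, x) {
    i <- rep_len(i, length(x)); j <- rep_len(j, length(x))
    keep <- x != 0
    tr$i <- c(tr$i, i[keep]); tr$j <- c(tr$j, j[keep]); tr$x <- c(tr$x, x[keep])
    tr
  }

  # --- u Laplacian + upwind x/y derivative operators ---
  tl <- tri(); te <- tri()
  txm <- tri(); txm_e <- tri(); txp <- tri(); txp_e <- tri()
  tym <- tri(); typ <- tri()
  uf_pos <- which(ufid > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(uf_pos))) {
    i <- uf_pos[q, 1]; j <- uf_pos[q, 2]; r <- ufid[i, j]
    # horizontal neighbors (x +- h): faces (i-1, j), (i+1, j)
    diag_c <- 0
    for (s in c(-1L, 1L)) {
      id <- if (i + s >= 1 && i + s <= Nx + 1) ufid[i + s, j] else 0L
      if (id > 0) {
        tl <- addq(tl, r, id, 1 / h^2); diag_c <- diag_c - 1 / h^2
      } else if (id < 0) {
        te <- addq(te, r, -id, 1 / h^2); diag_c <- diag_c - 1 / h^2
      } else {
        diag_c <- diag_c - 1 / h^2   # wall face: u = 0 one spacing away
      }
    }
    # vertical neighbors (y +- h)
    for (s in c(-1L, 1L)) {
      id <- if (j + s >= 1 && j + s <= Ny) ufid[i, j + s] else 0L
      if (id > 0) {
        tl <- addq(tl, r, id, 1 / h^2); diag_c <- diag_c - 1 / h^2
      } else {
        # wall along the cell edge at h/2: ghost = -u
        diag_c <- diag_c - 3 / h^2 + 1 / h^2
      }
    }
    tl <- addq(tl, r, r, diag_c)
    # upwind x-derivatives (minus: nodes i-2, i-1, i)
    idm1 <- if (i - 1 >= 1) ufid[i - 1, j] else 0L
    idm2 <- if (i - 2 >= 1) ufid[i - 2, j] else 0L
    if ((idm1 > 0 || idm1 < 0) && (idm2 > 0 || idm2 < 0)) {
      w <- c(0.5, -2, 1.5) / h
      for (kk in 1:2) {
        id <- c(idm2, idm1)[kk]
        if (id > 0) txm <- addq(txm, r, id, w[kk]) else txm_e <- addq(txm_e, r, -id, w[kk])
      }
      txm <- addq(txm, r, r, w[3])
    } else if (idm1 != 0L) {
      if (idm1 > 0) txm <- addq(txm, r, idm1, -1 / h) else txm_e <- addq(txm_e, r, -idm1, -1 / h)
      txm <- addq(txm, r, r, 1 / h)
    } else {
      txm <- addq(txm, r, r, 1 / h)   # wall at i-1: value 0
    }
    idp1 <- if (i + 1 <= Nx + 1) ufid[i + 1, j] else 0L
    idp2 <- if (i + 2 <= Nx + 1) ufid[i + 2, j] else 0L
    if ((idp1 != 0L) && (idp2 != 0L)) {
      w <- c(-1.5, 2, -0.5) / h
      txp <- addq(txp, r, r, w[1])
      for (kk in 1:2) {
        id <- c(idp1, idp2)[kk]
        if (id > 0) txp <- addq(txp, r, id, w[kk + 1]) else txp_e <- addq(txp_e, r, -id, w[kk + 1])
      }
    } else if (idp1 != 0L) {
      txp <- addq(txp, r, r, -1 / h)
      if (idp1 > 0) txp <- addq(txp, r, idp1, 1 / h) else txp_e <- addq(txp_e, r, -idp1, 1 / h)
    } else {
      txp <- addq(txp, r, r, -1 / h)
    }
    # upwind y-derivatives (walls at h/2 with value 0 -> ghost -u)
    idm1 <- if (j - 1 >= 1) ufid[i, j - 1] else 0L
    idm2 <- if (j - 2 >= 1) ufid[i, j - 2] else 0L
    if (idm1 > 0 && idm2 > 0) {
      tym <- addq(tym, r, c(idm2, idm1, r), c(0.5, -2, 1.5) / h)
    } else if (idm1 > 0) {
      tym <- addq(tym, r, c(idm1, r), c(-1, 1) / h)
    } else {
      tym <- addq(tym, r, r, 2 / h)   # wall at h/2 below: (u - 0)/(h/2)
    }
    idp1 <- if (j + 1 <= Ny) ufid[i, j + 1] else 0L
    idp2 <- if (j + 2 <= Ny) ufid[i, j + 2] else 0L
    if (idp1 > 0 && idp2 > 0) {
      typ <- addq(typ, r, c(r, idp1, idp2), c(-1.5, 2, -0.5) / h)
    } else if (idp1 > 0) {
      typ <- addq(typ, r, c(r, idp1), c(-1, 1) / h)
    } else {
      typ <- addq(typ, r, r, -2 / h)
    }
  }
  mk <- function(tr, nr, nc) Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                                  dims = c(nr, nc))
  Lu <- mk(tl, Nu, Nu); Eu_L <- mk(te, Nu, Nin)
  Uzm <- mk(txm, Nu, Nu); Euzm <- mk(txm_e, Nu, Nin)
  Uzp <- mk(txp, Nu, Nu); Euzp <- mk(txp_e, Nu, Nin)
  Uem <- mk(tym, Nu, Nu); Uep <- mk(typ, Nu, Nu)

  # --- v Laplacian + upwind operators ---
  tl <- tri()
  txm <- tri(); txp <- tri(); tym <- tri(); typ <- tri()
  vf_pos <- which(vfid > 0, arr.ind = TRUE)
  for (q in seq_len(nrow(vf_pos))) {
    i <- vf_pos[q, 1]; j <- vf_pos[q, 2]; r <- vfid[i, j]
    diag_c <- 0
    is_top <- j == Ny + 1
    for (s in c(-1L, 1L)) {   # horizontal neighbors
      id <- if (i + s >= 1 && i + s <= Nx) vfid[i + s, j] else 0L
      if (id > 0) {
        tl <- addq(tl, r, id, 1 / h^2); diag_c <- diag_c - 1 / h^2
      } else {
        diag_c <- diag_c - 3 / h^2 + 1 / h^2   # side wall at h/2: ghost = -v
      }
    }
    for (s in c(-1L, 1L)) {   # vertical neighbors at face spacing h
      id <- if (j + s >= 1 && j + s <= Ny + 1) vfid[i, j + s] else 0L
      if (id > 0) {
        tl <- addq(tl, r, id, 1 / h^2); diag_c <- diag_c - 1 / h^2
      } else if (s == 1L && is_top) {
        # zero-gradient ghost above the venous outlet: no contribution
      } else {
        diag_c <- diag_c - 1 / h^2   # wall face a spacing away: v = 0 there
      }
    }
    tl <- addq(tl, r, r, diag_c)
    # upwind x
    idm1 <- if (i - 1 >= 1) vfid[i - 1, j] else 0L
    idm2 <- if (i - 2 >= 1) vfid[i - 2, j] else 0L
    if (idm1 > 0 && idm2 > 0) {
      txm <- addq(txm, r, c(idm2, idm1, r), c(0.5, -2, 1.5) / h)
    } else if (idm1 > 0) {
      txm <- addq(txm, r, c(idm1, r), c(-1, 1) / h)
    } else {
      txm <- addq(txm, r, r, 2 / h)
    }
    idp1 <- if (i + 1 <= Nx) vfid[i + 1, j] else 0L
    idp2 <- if (i + 2 <= Nx) vfid[i + 2, j] else 0L
    if (idp1 > 0 && idp2 > 0) {
      txp <- addq(txp, r, c(r, idp1, idp2), c(-1.5, 2, -0.5) / h)
    } else if (idp1 > 0) {
      txp <- addq(txp, r, c(r, idp1), c(-1, 1) / h)
    } else {
      txp <- addq(txp, r, r, -2 / h)
    }
    # upwind y (neighbors at face spacing h; walls are faces with v = 0)
    idm1 <- if (j - 1 >= 1) vfid[i, j - 1] else 0L
    idm2 <- if (j - 2 >= 1) vfid[i, j - 2] else 0L
    if (idm1 > 0 && idm2 > 0) {
      tym <- addq(tym, r, c(idm2, idm1, r), c(0.5, -2, 1.5) / h)
    } else if (idm1 > 0) {
      tym <- addq(tym, r, c(idm1, r), c(-1, 1) / h)
    } else {
      tym <- addq(tym, r, r, 1 / h)
    }
    idp1 <- if (j + 1 <= Ny + 1) vfid[i, j + 1] else 0L
    idp2 <- if (j + 2 <= Ny + 1) vfid[i, j + 2] else 0L
    if (idp1 > 0 && idp2 > 0) {
      typ <- addq(typ, r, c(r, idp1, idp2), c(-1.5, 2, -0.5) / h)
    } else if (idp1 > 0) {
      typ <- addq(typ, r, c(r, idp1), c(-1, 1) / h)
    } else {
      typ <- addq(typ, r, r, -1 / h)
    }
  }
  Lv <- mk(tl, Nv, Nv)
  Vzm <- mk(txm, Nv, Nv); Vzp <- mk(txp, Nv, Nv)
  Vem <- mk(tym, Nv, Nv); Vep <- mk(typ, Nv, Nv)

  # --- interpolations ---
  tiv <- tri()
  for (q in seq_len(nrow(uf_pos))) {
    i <- uf_pos[q, 1]; j <- uf_pos[q, 2]; r <- ufid[i, j]
    ids <- c(if (i > 1) vfid[i - 1, j] else 0L,
             if (i > 1) vfid[i - 1, j + 1] else 0L,
             if (i <= Nx) vfid[i, j] else 0L,
             if (i <= Nx) vfid[i, j + 1] else 0L)
    ids <- ids[ids > 0]
    if (length(ids)) tiv <- addq(tiv, rep(r, length(ids)), ids,
                                 rep(0.25, length(ids)))
  }
  Ivu <- mk(tiv, Nu, Nv)
  tiu <- tri(); tie <- tri()
  for (q in seq_len(nrow(vf_pos))) {
    i <- vf_pos[q, 1]; j <- vf_pos[q, 2]; r <- vfid[i, j]
    for (jj in c(j - 1L, j)) {
      if (jj < 1 || jj > Ny) next
      for (ii in c(i, i + 1L)) {
        id <- ufid[ii, jj]
        if (id > 0) tiu <- addq(tiu, r, id, 0.25)
        else if (id < 0) tie <- addq(tie, r, -id, 0.25)
      }
    }
  }
  Iuv <- mk(tiu, Nv, Nu); Euv <- mk(tie, Nv, Nin)

  # --- divergence and gradients (per-depth fluxes, face area h) ---
  td_u <- tri(); td_v <- tri(); td_b <- tri()
  tgz <- tri(); tgr <- tri()
  cl_pos <- which(fl, arr.ind = TRUE)
  for (q in seq_len(nrow(cl_pos))) {
    i <- cl_pos[q, 1]; j <- cl_pos[q, 2]; cc <- cid[i, j]
    idw <- ufid[i, j]; ide <- ufid[i + 1, j]
    if (idw > 0) td_u <- addq(td_u, cc, idw, -h)
    if (idw < 0) td_b <- addq(td_b, cc, -idw, -h)
    if (ide > 0) td_u <- addq(td_u, cc, ide, h)
    if (ide < 0) td_b <- addq(td_b, cc, -ide, h)
    ids <- vfid[i, j]; idn <- vfid[i, j + 1]
    if (ids > 0) td_v <- addq(td_v, cc, ids, -h)
    if (idn > 0) td_v <- addq(td_v, cc, idn, h)
  }
  for (q in seq_len(nrow(uf_pos))) {
    i <- uf_pos[q, 1]; j <- uf_pos[q, 2]; r <- ufid[i, j]
    tgz <- addq(tgz, r, c(cid[i, j], cid[i - 1, j]), c(1, -1) / h)
  }
  for (q in seq_len(nrow(vf_pos))) {
    i <- vf_pos[q, 1]; j <- vf_pos[q, 2]; r <- vfid[i, j]
    if (j == Ny + 1) {
      tgr <- addq(tgr, r, cid[i, j - 1], -1 / (h / 2))   # outlet p = 0
    } else {
      tgr <- addq(tgr, r, c(cid[i, j], cid[i, j - 1]), c(1, -1) / h)
    }
  }
  Du <- mk(td_u, Np, Nu); Dv <- mk(td_v, Np, Nv); Bd <- mk(td_b, Np, Nin)
  Gz <- mk(tgz, Nu, Np); Gr <- mk(tgr, Nv, Np)

  # --- inlet / DA prescribed profiles (flux-exact split) ---
  pa_y <- grid$yc[vapply(ext_rows_pa, function(e) {
    w <- which(ufid[1, ] == -e); w }, integer(1))]
  da_y <- grid$yc[vapply(ext_rows_da, function(e) {
    w <- which(ufid[Nx + 1, ] == -e); w }, integer(1))]
  pa_shape_raw <- pmax(1 - (pa_y / (grid$wpa / 2))^2, 0)
  da_shape_raw <- pmax(1 - (da_y / (grid$wda / 2))^2, 0)
  pa_shape <- pa_shape_raw / (sum(pa_shape_raw) * h)   # unit per-depth flux
  da_shape <- da_shape_raw / (sum(da_shape_raw) * h)
  qp_of <- function(t) inlet$v_mean(t) * grid$wpa       # per-depth flow (m^2/s)
  inlet_profile <- function(t) {
    qp <- qp_of(t)
    uin <- numeric(Nin)
    uin[ext_rows_pa] <- qp * pa_shape                             # full inflow
    uin[ext_rows_da] <- da_split * qp * da_shape                  # DA outflow
    uin
  }
  cells_in <- cid[1, ][cid[1, ] > 0]

  nu_visc <- fluid_props$viscosity / fluid_props$density
  wmin <- h * 8  # minimum channel width by construction

  list(
    topology = "planar_junction",
    Nu = Nu, Nv = Nv, Np = Np, Nx = Nx, Ny = Ny,
    Nz = NULL, Nr = NULL,
    Lu = Lu, Eu_L = Eu_L, Lv = Lv,
    Uzm = Uzm, Uzp = Uzp, Euzm = Euzm, Euzp = Euzp, Uem = Uem, Uep = Uep,
    Vzm = Vzm, Vzp = Vzp, Vem = Vem, Vep = Vep,
    Ivu = Ivu, Iuv = Iuv, Euv = Euv,
    Du = Du, Dv = Dv, Bd = Bd, Gz = Gz, Gr = Gr,
    Vol = rep(h^2, Np), nu = nu_visc,
    a_u = numeric(Nu), Rfu = 1, a_v = numeric(Nv), Rcv = 1,
    dz = h, deta_u = h, deta_min = h,
    ufid = ufid, vfid = vfid, cid = cid, top_v = top_v,
    ext_rows_pa = ext_rows_pa, ext_rows_da = ext_rows_da,
    inlet_profile = inlet_profile,
    inlet_flux = function(uin) sum(uin[ext_rows_pa]) * h,
    outlet_flux = function(u, v) sum(v[top_v]) * h,
    outlet2_flux = function(u, v, t) sum(inlet_profile(t)[ext_rows_da]) * h,
    inlet_pressure = function(p) mean(p[cells_in]),
    u_scale = function(vmax) 1.5 * vmax * max(grid$wpa, grid$wda) / wmin,
    ce_scale = function(u_est) u_est,
    initial_state = function(vmean0) list(u = numeric(Nu), v = numeric(Nv)),
    grid = grid
  )
}
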