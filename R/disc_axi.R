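# Staggered (MAC) discretization of the incompressible Navier-Stokes
# equations on the radius-mapped axisymmetric tube grid.
#
# Coordinates: zeta = z (axial), eta = r/R(z) in [0, 1]. With
# a = -eta R'(z)/R(z), derivatives at fixed r transform as
# d/dz|r = d/dzeta + a d/deta, and d/dr = (1/R) d/deta. Unknowns:
#   u (axial) at z-faces x eta-centers, including the outlet face,
#   v (radial) at z-centers x interior eta-faces,
#   p at cell centers, with p = 0 at the outlet face.
# The discrete divergence uses exact mapped-cell face fluxes (the eta-face
# flux carries the contravariant velocity v - eta R' u), and the projection
# operator is the exact composition of divergence and correction gradient,
# so the corrected field is discretely divergence-free to solver precision.

make_axi_disc <- function(grid, fluid, inlet, da_split = 0) {
  Nz <- grid$Nz; Nr <- grid$Nr
  zf <- grid$zf; zc <- grid$zc
  etaf <- grid$etaf; etac <- grid$etac
  dz <- grid$dz
  Rf <- grid$R_zf; Rc <- grid$R_zc
  Rpf <- grid$Rp_zf; Rpc <- grid$Rp_zc
  Rppf <- grid$Rpp_zf

  zu <- zf[-1]                 # u-node axial positions (faces 2..Nz+1)
  etav <- etaf[2:Nr]           # v-node eta positions (interior faces)
  Nu <- Nz * Nr
  Nv <- Nz * (Nr - 1)
  Np <- Nz * Nr

  idx_u <- function(i, j) i + (j - 1L) * Nz
  idx_p <- idx_u
  idx_v <- function(i, j) i + (j - 1L) * Nz

  ## ---- u operators (grid: zu x etac) ----
  bc_in <- list(type = "dirichlet", pos = zf[1])
  bc_out <- list(type = "copy")
  bc_axis <- list(type = "mirror", pos = 0)
  bc_wall <- list(type = "dirichlet", pos = 1)

  Dz2u <- fd_op_1d(zu, 2, "c", bc_in, bc_out)
  Dz1u_c <- fd_op_1d(zu, 1, "c", bc_in, bc_out)
  Dz1u_m <- fd_op_1d(zu, 1, "m", bc_in, bc_out)
  Dz1u_p <- fd_op_1d(zu, 1, "p", bc_in, bc_out)
  De2u <- fd_op_1d(etac, 2, "c", bc_axis, bc_wall)
  De1u_c <- fd_op_1d(etac, 1, "c", bc_axis, bc_wall)
  De1u_m <- fd_op_1d(etac, 1, "m", bc_axis, bc_wall)
  De1u_p <- fd_op_1d(etac, 1, "p", bc_axis, bc_wall)

  # coefficient fields at u-nodes
  iu <- rep(seq_len(Nz), times = Nr)
  ju <- rep(seq_len(Nr), each = Nz)
  Rfu <- Rf[iu + 1L]; Rpfu <- Rpf[iu + 1L]; Rppfu <- Rppf[iu + 1L]
  eu <- etac[ju]
  a_u <- -eu * Rpfu / Rfu
  az_u <- -eu * (Rppfu * Rfu - Rpfu^2) / Rfu^2
  ae_u <- -Rpfu / Rfu
  c_e2 <- a_u^2 + 1 / Rfu^2
  c_e1 <- az_u + a_u * ae_u + 1 / (eu * Rfu^2)
  c_mx <- 2 * a_u

  Mz2 <- op_dim1(Dz2u$M, Nr)
  Me2 <- op_dim2(De2u$M, Nz)
  Me1 <- op_dim2(De1u_c$M, Nz)
  Mmx <- op_dim2(De1u_c$M, Nz) %*% op_dim1(Dz1u_c$M, Nr)
  Lu <- Mz2 + scale_rows(c_mx, Mmx) + scale_rows(c_e2, Me2) + scale_rows(c_e1, Me1)
  # inlet (Dirichlet) external maps: uin is a length-Nr vector
  Eu_L <- ext_dim1(Dz2u$ext_lo, Nr) +
    scale_rows(c_mx, op_dim2(De1u_c$M, Nz) %*% ext_dim1(Dz1u_c$ext_lo, Nr))

  # upwind derivative bundles for u
  Uzm <- op_dim1(Dz1u_m$M, Nr); Euzm <- ext_dim1(Dz1u_m$ext_lo, Nr)
  Uzp <- op_dim1(Dz1u_p$M, Nr); Euzp <- ext_dim1(Dz1u_p$ext_lo, Nr)
  Uem <- op_dim2(De1u_m$M, Nz)
  Uep <- op_dim2(De1u_p$M, Nz)

  ## ---- v operators (grid: zc x etav) ----
  bcv_in <- list(type = "dirichlet", pos = zf[1])   # v = 0 at the inlet face
  bcv_axis <- list(type = "dirichlet", pos = 0)     # v = 0 on the axis
  bcv_wall <- list(type = "dirichlet", pos = 1)     # no-slip wall
  Dz2v <- fd_op_1d(zc, 2, "c", bcv_in, bc_out)
  Dz1v_c <- fd_op_1d(zc, 1, "c", bcv_in, bc_out)
  Dz1v_m <- fd_op_1d(zc, 1, "m", bcv_in, bc_out)
  Dz1v_p <- fd_op_1d(zc, 1, "p", bcv_in, bc_out)
  De2v <- fd_op_1d(etav, 2, "c", bcv_axis, bcv_wall)
  De1v_c <- fd_op_1d(etav, 1, "c", bcv_axis, bcv_wall)
  De1v_m <- fd_op_1d(etav, 1, "m", bcv_axis, bcv_wall)
  De1v_p <- fd_op_1d(etav, 1, "p", bcv_axis, bcv_wall)

  iv <- rep(seq_len(Nz), times = Nr - 1)
  jv <- rep(seq_len(Nr - 1), each = Nz)
  Rcv <- Rc[iv]; Rpcv <- Rpc[iv]; Rppcv <- grid$Rpp_zc[iv]
  ev <- etav[jv]
  a_v <- -ev * Rpcv / Rcv
  az_v <- -ev * (Rppcv * Rcv - Rpcv^2) / Rcv^2
  ae_v <- -Rpcv / Rcv
  cv_e2 <- a_v^2 + 1 / Rcv^2
  cv_e1 <- az_v + a_v * ae_v + 1 / (ev * Rcv^2)
  cv_0 <- -1 / (ev^2 * Rcv^2)

  Lv <- op_dim1(Dz2v$M, Nr - 1) +
    scale_rows(2 * a_v, op_dim2(De1v_c$M, Nz) %*% op_dim1(Dz1v_c$M, Nr - 1)) +
    scale_rows(cv_e2, op_dim2(De2v$M, Nz)) +
    scale_rows(cv_e1, op_dim2(De1v_c$M, Nz)) +
    Matrix::Diagonal(x = cv_0)

  Vzm <- op_dim1(Dz1v_m$M, Nr - 1)
  Vzp <- op_dim1(Dz1v_p$M, Nr - 1)
  Vem <- op_dim2(De1v_m$M, Nz)
  Vep <- op_dim2(De1v_p$M, Nz)

  ## ---- interpolation matrices ----
  # v interpolated to u-nodes (zu x etac); v = 0 on axis/wall faces
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  addt <- function(i, j, x) {
    keep <- x != 0
    trip$i <<- c(trip$i, i[keep]); trip$j <<- c(trip$j, j[keep])
    trip$x <<- c(trip$x, x[keep])
  }
  for (j in seq_len(Nr)) {
    # eta interpolation: etac[j] between etav[j-1] and etav[j]
    jlo <- j - 1L; jhi <- j
    wlo <- if (jlo >= 1 && jhi <= Nr - 1)
      (etav[jhi] - etac[j]) / (etav[jhi] - etav[jlo]) else if (jlo < 1) 0 else 1
    whi <- if (jlo >= 1 && jhi <= Nr - 1) 1 - wlo else if (jlo < 1) 1 else 0
    if (jlo < 1) { wlo <- 0; whi <- 1 }     # axis face value 0
    if (jhi > Nr - 1) { whi <- 0 }          # wall face value 0
    for (i in seq_len(Nz)) {
      # z interpolation: zu[i] = zf[i+1] between zc[i] and zc[i+1]
      ilo <- i; ihi <- min(i + 1L, Nz)
      wz <- if (ihi == ilo) c(1, 0) else c(0.5, 0.5)
      r <- idx_u(i, j)
      if (wlo > 0 && jlo >= 1) {
        addt(c(r, r), c(idx_v(ilo, jlo), idx_v(ihi, jlo)), wlo * wz)
      }
      if (whi > 0 && jhi <= Nr - 1) {
        addt(c(r, r), c(idx_v(ilo, jhi), idx_v(ihi, jhi)), whi * wz)
      }
    }
  }
  Ivu <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(Nu, Nv))

  # u interpolated to v-nodes (zc x etav); includes inlet externals
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  tripE <- list(i = integer(0), j = integer(0), x = numeric(0))
  addE <- function(i, j, x) {
    keep <- x != 0
    tripE$i <<- c(tripE$i, i[keep]); tripE$j <<- c(tripE$j, j[keep])
    tripE$x <<- c(tripE$x, x[keep])
  }
  for (j in seq_len(Nr - 1)) {
    wlo <- (etac[j + 1] - etav[j]) / (etac[j + 1] - etac[j])
    whi <- 1 - wlo
    for (i in seq_len(Nz)) {
      r <- idx_v(i, j)
      # faces zf[i] (u index i-1; inlet if i=1) and zf[i+1] (u index i)
      for (jj in c(j, j + 1L)) {
        wgt <- if (jj == j) wlo else whi
        if (i == 1L) {
          addE(r, jj, 0.5 * wgt)                    # inlet face value
        } else {
          addt(r, idx_u(i - 1L, jj), 0.5 * wgt)
        }
        addt(r, idx_u(i, jj), 0.5 * wgt)
      }
    }
  }
  Iuv <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                              dims = c(Nv, Nu))
  Euv <- Matrix::sparseMatrix(i = tripE$i, j = tripE$j, x = tripE$x,
                              dims = c(Nv, Nr))

  ## ---- divergence (net volume outflux per cell, m^3/s) ----
  ring <- pi * (etaf[-1]^2 - etaf[-(Nr + 1)]^2)     # per j
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  tripV <- list(i = integer(0), j = integer(0), x = numeric(0))
  tripB <- list(i = integer(0), j = integer(0), x = numeric(0))
  addV <- function(i, j, x) {
    keep <- x != 0
    tripV$i <<- c(tripV$i, i[keep]); tripV$j <<- c(tripV$j, j[keep])
    tripV$x <<- c(tripV$x, x[keep])
  }
  addB <- function(i, j, x) {
    keep <- x != 0
    tripB$i <<- c(tripB$i, i[keep]); tripB$j <<- c(tripB$j, j[keep])
    tripB$x <<- c(tripB$x, x[keep])
  }
  # z-face fluxes
  for (j in seq_len(Nr)) {
    for (i in seq_len(Nz)) {
      cell <- idx_p(i, j)
      Az_e <- ring[j] * Rf[i + 1]^2
      addt(cell, idx_u(i, j), Az_e)              # east face out
      if (i > 1) {
        Az_w <- ring[j] * Rf[i]^2
        addt(cell, idx_u(i - 1L, j), -Az_w)      # west face in
      } else {
        addB(cell, j, -ring[j] * Rf[1]^2)        # inlet face (external u)
      }
    }
  }
  # interior eta-face fluxes (face between cells j and j+1 at eta = etav[j])
  for (j in seq_len(Nr - 1)) {
    # u interpolation weights to (zc[i], etav[j])
    wlo <- (etac[j + 1] - etav[j]) / (etac[j + 1] - etac[j])
    whi <- 1 - wlo
    for (i in seq_len(Nz)) {
      An <- 2 * pi * etav[j] * Rc[i] * dz
      geo <- -etav[j] * Rpc[i] * An                # coefficient of ubar
      lower <- idx_p(i, j); upper <- idx_p(i, j + 1L)
      addV(c(lower, upper), c(idx_v(i, j), idx_v(i, j)), c(An, -An))
      for (jj in c(j, j + 1L)) {
        wgt <- if (jj == j) wlo else whi
        if (i == 1L) {
          addB(c(lower, upper), c(jj, jj), c(0.5 * wgt * geo, -0.5 * wgt * geo))
        } else {
          addt(c(lower, upper), rep(idx_u(i - 1L, jj), 2),
               c(0.5 * wgt * geo, -0.5 * wgt * geo))
        }
        addt(c(lower, upper), rep(idx_u(i, jj), 2),
             c(0.5 * wgt * geo, -0.5 * wgt * geo))
      }
    }
  }
  Du <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(Np, Nu))
  Dv <- Matrix::sparseMatrix(i = tripV$i, j = tripV$j, x = tripV$x, dims = c(Np, Nv))
  Bd <- Matrix::sparseMatrix(i = tripB$i, j = tripB$j, x = tripB$x, dims = c(Np, Nr))

  ## ---- pressure gradients ----
  # cell-centered d/deta of p (centered, one-sided at wall; symmetric at axis)
  DePc <- fd_op_1d(etac, 1, "c", list(type = "mirror", pos = 0),
                   list(type = "none"))
  MePc <- op_dim2(DePc$M, Nz)
  # average cell eta-derivative to u-faces
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_len(Nr)) for (i in seq_len(Nz)) {
    r <- idx_u(i, j)
    if (i < Nz) addt(c(r, r), c(idx_p(i, j), idx_p(i + 1L, j)), c(0.5, 0.5))
    else addt(r, idx_p(Nz, j), 1)
  }
  Ifc <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(Nu, Np))
  # d/dzeta part
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_len(Nr)) for (i in seq_len(Nz)) {
    r <- idx_u(i, j)
    if (i < Nz) {
      addt(c(r, r), c(idx_p(i + 1L, j), idx_p(i, j)), c(1, -1) / dz)
    } else {
      addt(r, idx_p(Nz, j), -1 / (dz / 2))   # outlet face p = 0
    }
  }
  Gz <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(Nu, Np)) +
    scale_rows(a_u, Ifc %*% MePc)

  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_len(Nr - 1)) for (i in seq_len(Nz)) {
    r <- idx_v(i, j)
    addt(c(r, r), c(idx_p(i, j + 1L), idx_p(i, j)),
         c(1, -1) / (Rc[i] * (etac[j + 1] - etac[j])))
  }
  Gr <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(Nv, Np))

  ## ---- cell volumes, CFL scales ----
  ip <- rep(seq_len(Nz), times = Nr)
  jp <- rep(seq_len(Nr), each = Nz)
  Vol <- ring[jp] * Rc[ip]^2 * dz
  d_eta_u <- (etaf[ju + 1] - etaf[ju]) * Rfu      # physical radial spacing at u nodes

  nu_visc <- fluid$viscosity / fluid$density

  list(
    topology = "axisymmetric_tube",
    Nz = Nz, Nr = Nr, Nu = Nu, Nv = Nv, Np = Np,
    Lu = Lu, Eu_L = Eu_L, Lv = Lv,
    Uzm = Uzm, Uzp = Uzp, Euzm = Euzm, Euzp = Euzp, Uem = Uem, Uep = Uep,
    Vzm = Vzm, Vzp = Vzp, Vem = Vem, Vep = Vep,
    Ivu = Ivu, Iuv = Iuv, Euv = Euv,
    Du = Du, Dv = Dv, Bd = Bd, Gz = Gz, Gr = Gr,
    Vol = Vol, nu = nu_visc,
    a_u = a_u, Rfu = Rfu, a_v = a_v, Rcv = Rcv,
    dz = dz,
    deta_u = etaf[ju + 1] - etaf[ju],
    deta_min = min(diff(etaf)),
    ring = ring,
    # parabolic inlet is exact in mapped coordinates: u = 2 vbar (1 - eta^2)
    inlet_profile = function(t) 2 * inlet$v_mean(t) * (1 - etac^2),
    inlet_flux = function(uin) sum(uin * ring * Rf[1]^2),
    outlet_flux = function(u, v) sum(u[idx_u(Nz, seq_len(Nr))] * ring * Rf[Nz + 1]^2),
    outlet2_flux = NULL,
    inlet_pressure = function(p) sum(p[idx_p(1L, seq_len(Nr))] * ring) / sum(ring),
    u_scale = function(vmax) 2 * vmax * max(Rf[1]^2 / Rf^2),
    ce_scale = function(u_est) 2 * u_est * max(abs(Rpf) / Rf) + 1e-9,
    initial_state = function(vmean0) {
      list(u = 2 * vmean0 * (Rf[1]^2 / Rfu^2) * (1 - eu^2),
           v = numeric(Nv))
    },
    Nx = NULL, Ny = NULL,
    grid = grid
  )
}
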