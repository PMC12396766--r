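# Unsteady incompressible Navier-Stokes solver: incremental
# pressure-correction (projection) with backward Euler time stepping,
# Picard-iterated second-order upwind convection, and adaptive time steps
# keeping the advective CFL below a cap (default 0.1). Simulations run a
# fixed number of cardiac cycles (default 3); all phase snapshots of the
# final cycle are stored for metric integration. The per-step linear
# algebra runs in the compiled kernel (src/solver_kernels.cpp) on operators
# and LU factors built once per grid and time step.

.make_disc <- function(grid, fluid, inlet, da_split = 0) {
  switch(grid$topology,
         axisymmetric_tube = make_axi_disc(grid, fluid, inlet, da_split),
         planar_junction = make_planar_disc(grid, fluid, inlet, da_split),
         stop("unknown grid topology"))
}

# operator bundle in raw CSC form for the compiled kernel
.fast_ops <- function(disc) {
  nm <- c("Eu_L", "Uzm", "Uzp", "Euzm", "Euzp", "Uem", "Uep",
          "Vzm", "Vzp", "Vem", "Vep", "Ivu", "Iuv", "Euv",
          "Du", "Dv", "Bd", "Gz", "Gr")
  ops <- lapply(disc[nm], fop)
  ops$a_u <- as.numeric(disc$a_u)
  ops$Rfu <- rep_len(as.numeric(disc$Rfu), disc$Nu)
  ops$a_v <- as.numeric(disc$a_v)
  ops$Rcv <- rep_len(as.numeric(disc$Rcv), disc$Nv)
  ops
}

#' Solve unsteady incompressible flow
#'
#' Runs the projection solver on a structured grid with a pulsatile
#' parabolic inlet. For the axisymmetric tube the single inlet carries the
#' full flow; for the planar junction the proximal-artery inlet is
#' prescribed, the distal artery carries a prescribed outflow fraction
#' `da_split` of the instantaneous inlet flow (distal-artery blood flows
#' away from the junction), and the venous outlet is a zero-pressure
#' boundary. Each step solves backward-Euler momentum with Picard-iterated
#' second-order upwind convection until the iteration increment falls below
#' `tol` (relative to the peak inlet velocity scale), then projects onto the
#' discretely divergence-free space; pressure is relative to the outlet.
#'
#' @param grid a [build_grid()] result.
#' @param fluid a [fluid_properties()].
#' @param inlet an [build_inlet()] condition (positive waveform).
#' @param da_split distal-artery outflow fraction in `[0, 1)` (planar
#'   junction only).
#' @param n_cycles number of cardiac cycles (the final one is stored).
#' @param cfl_max advective CFL cap; the time step adapts to honor it.
#' @param tol nonlinear (Picard) convergence tolerance per step.
#' @param n_store stored phase snapshots per cycle.
#' @param picard_max Picard iteration cap; exceeding it errors with the
#'   residual trace.
#' @param verbose print cycle progress.
#' @return a `flow_field` object: snapshots `u`, `v`, `p` (columns = stored
#'   phases of the final cycle, snapshot `k` at phase time `k T / n_store`),
#'   per-cycle periodicity metric traces, boundary flux traces, and step
#'   diagnostics (CFL, residuals, divergence).
#' @export
solve_unsteady <- function(grid, fluid, inlet, da_split = 0, n_cycles = 3,
                           cfl_max = 0.1, tol = 1e-6, n_store = 200,
                           picard_max = 8, verbose = FALSE) {
  if (da_split < 0 || da_split >= 1) stop("da_split must be in [0, 1)")
  disc <- .make_disc(grid, fluid, inlet, da_split)
  rho <- fluid$density
  period <- inlet$period_s
  tgrid <- seq(0, period, length.out = 512)
  vmax <- max(inlet$v_mean(tgrid))
  if (min(inlet$v_mean(tgrid)) <= 0) stop("reversed inlet flow is not supported")

  uin_of <- disc$inlet_profile
  u_est <- disc$u_scale(vmax) * 1.3
  ce_est <- disc$ce_scale(u_est)
  dt0 <- cfl_max * min(disc$dz / u_est, disc$deta_min / ce_est)
  spp <- max(1L, as.integer(ceiling((period / n_store) / dt0)))
  dt <- period / (n_store * spp)

  ops <- .fast_ops(disc)
  deta_u <- rep_len(as.numeric(disc$deta_u), disc$Nu)
  factor_ops <- function(dt) {
    Mu <- Matrix::Diagonal(disc$Nu, 1 / dt) - disc$nu * disc$Lu
    Mv <- Matrix::Diagonal(disc$Nv, 1 / dt) - disc$nu * disc$Lv
    list(Mu = flu(Mu), Mv = flu(Mv))
  }
  lus <- factor_ops(dt)
  A <- disc$Du %*% disc$Gz + disc$Dv %*% disc$Gr
  lus$A <- flu(A)

  # initial condition: mass-consistent scaled profile projected onto the
  # discretely divergence-free space (first cycle is discarded regardless)
  init <- disc$initial_state(inlet$v_mean(0))
  u <- init$u; v <- init$v
  p <- numeric(disc$Np)
  uin0 <- uin_of(0)
  dv0 <- as.numeric(disc$Du %*% u + disc$Dv %*% v + disc$Bd %*% uin0)
  phi <- fsolve(lus$A, (rho / dt) * dv0)
  u <- u - (dt / rho) * as.numeric(disc$Gz %*% phi)
  v <- v - (dt / rho) * as.numeric(disc$Gr %*% phi)
  state <- list(u = u, v = v, p = p, u_prev = u, v_prev = v)

  u_ref <- max(u_est, 1e-9)
  n_phase_tot <- n_cycles * n_store
  times <- seq_len(n_store) * period / n_store
  u_hist <- matrix(NA_real_, disc$Nu, n_store)
  v_hist <- matrix(NA_real_, disc$Nv, n_store)
  p_hist <- matrix(NA_real_, disc$Np, n_store)
  cycle_metric <- matrix(NA_real_, n_store, n_cycles)
  flux_in <- matrix(NA_real_, n_store, n_cycles)
  flux_out <- matrix(NA_real_, n_store, n_cycles)
  flux_out2 <- matrix(NA_real_, n_store, n_cycles)
  resid_hist <- numeric(n_phase_tot)
  cfl_obs <- 0
  cfl_phase <- 0
  div_rel_max <- 0
  t_now <- 0

  for (ph in seq_len(n_phase_tot)) {
    # re-target the step from the CFL observed over the previous phase block
    # (phase-boundary changes keep snapshots aligned); 0.8 headroom and 25%
    # hysteresis avoid refactoring every block
    if (ph > 1 && cfl_phase > 0) {
      spp_want <- max(1L, as.integer(ceiling(spp * cfl_phase / (0.8 * cfl_max))))
      if (cfl_phase > cfl_max || spp_want > spp * 1.25 || spp_want < spp * 0.75) {
        spp <- spp_want
        dt <- period / (n_store * spp)
        lus[c("Mu", "Mv")] <- factor_ops(dt)
      }
    }
    t_sub <- t_now + seq_len(spp) * dt
    uin_mat <- vapply(t_sub, uin_of, numeric(length(uin0)))
    if (!is.matrix(uin_mat)) uin_mat <- matrix(uin_mat, nrow = 1)
    res <- run_phase_block(ops, lus, state, uin_mat, dt, rho, disc$nu,
                           tol, picard_max, u_ref, disc$dz, deta_u)
    if (isTRUE(res$failed))
      stop(sprintf(paste0("Picard iteration did not converge near t = %.5f s ",
                          "(residual %.3g after %d iterations)"),
                   t_now + (res$fail_step + 1) * dt, res$resid, picard_max))
    state <- res[c("u", "v", "p", "u_prev", "v_prev")]
    t_now <- t_sub[spp]
    cfl_phase <- res$cfl
    cfl_obs <- max(cfl_obs, res$cfl)
    resid_hist[ph] <- res$resid

    cyc <- (ph - 1L) %/% n_store + 1L
    ip <- (ph - 1L) %% n_store + 1L
    uin_now <- uin_mat[, spp]
    qin <- disc$inlet_flux(uin_now)
    dmax <- div_residual(ops, state$u, state$v, uin_now)
    div_rel_max <- max(div_rel_max, dmax / max(abs(qin), 1e-30))
    cycle_metric[ip, cyc] <- disc$inlet_pressure(state$p)
    flux_in[ip, cyc] <- qin
    flux_out[ip, cyc] <- disc$outlet_flux(state$u, state$v)
    flux_out2[ip, cyc] <- if (is.null(disc$outlet2_flux)) NA_real_
      else disc$outlet2_flux(state$u, state$v, t_now)
    if (cyc == n_cycles) {
      u_hist[, ip] <- state$u; v_hist[, ip] <- state$v; p_hist[, ip] <- state$p
    }
    if (verbose && ip == n_store)
      message(sprintf("cycle %d/%d done (dt = %.2e s, CFL max %.3f)",
                      cyc, n_cycles, dt, cfl_obs))
  }
  peak_idx <- which.max(flux_in[, n_cycles])
  structure(list(
    grid = grid, fluid = fluid, inlet = inlet, da_split = da_split,
    times = times, dt = dt, n_cycles = n_cycles, n_store = n_store,
    u = u_hist, v = v_hist, p = p_hist,
    cycle_metric = cycle_metric,
    flux_in = flux_in, flux_out = flux_out, flux_out2 = flux_out2,
    peak_idx = peak_idx,
    cfl_max_observed = cfl_obs,
    residual_hist = resid_hist,
    div_rel_max = div_rel_max,
    disc_meta = list(Nz = disc$Nz, Nr = disc$Nr,
                     Nx = disc$Nx, Ny = disc$Ny,
                     ufid = disc$ufid, vfid = disc$vfid, cid = disc$cid,
                     top_v = disc$top_v)
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field (%s, %s): %d stored phases of cycle %d, dt = %.3g s\n",
              x$grid$topology, x$grid$level, x$n_store, x$n_cycles, x$dt))
  cat(sprintf("  max CFL %.3f, max |div|/Q_in %.2e, final residual %.2e\n",
              x$cfl_max_observed, x$div_rel_max,
              x$residual_hist[length(x$residual_hist)]))
  invisible(x)
}

#' Cycle-to-cycle periodicity check
#'
#' Relative L2 difference of a per-cycle metric trace (default: the
#' cross-sectional average pressure next to the inlet) between consecutive
#' cycles; pulsatile runs are considered periodic once the deviation falls
#' below `tol`. With a steady inflow the deviation is ~0 from the first
#' cycle.
#'
#' @param field a `flow_field`.
#' @param tol convergence threshold on the relative deviation.
#' @return list with `deviations` (one per cycle pair) and `converged`.
#' @export
check_periodicity <- function(field, tol = 0.01) {
  m <- field$cycle_metric
  if (ncol(m) < 2) stop("need at least two stored cycles")
  if (any(is.na(m))) stop("cycle metric traces have mismatched phase sampling")
  dev <- vapply(seq_len(ncol(m) - 1), function(k) {
    num <- sqrt(mean((m[, k + 1] - m[, k])^2))
    den <- sqrt(mean(m[, k + 1]^2))
    if (den < 1e-300) { if (num < 1e-300) 0 else Inf } else num / den
  }, numeric(1))
  list(deviations = dev, converged = dev[length(dev)] < tol)
}
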