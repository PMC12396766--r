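test_that("grids refine by ~2x per axis and tag sane geometry", {
  spec <- avf_geometry("day7")
  gc_ <- build_grid(spec, "coarse")
  gm <- build_grid(spec, "medium")
  expect_equal(gm$Nz / gc_$Nz, 2)
  expect_equal(gm$Nr / gc_$Nr, 2)
  expect_gte(2 * gc_$Nr, 8)                     # cells across the minimum lumen
  expect_equal(min(gc_$R_zc), mm_to_m(0.46 / 2), tolerance = 0.02)
  expect_error(build_grid(spec, "coarse", base_nr = 2), "8 cells")
  gp <- build_grid(spec, "coarse", topology = "planar_junction")
  expect_equal(gp$h, mm_to_m(0.29) / 8, tolerance = 1e-12)
})

test_that("steady flow in a straight tube converges to Poiseuille", {
  run <- poiseuille_run()
  grid <- run$grid
  ff <- run$field
  u <- matrix(ff$u[, ncol(ff$u)], grid$Nz, grid$Nr)
  i_mid <- which.min(abs(grid$zf[-1] - 2e-3))
  prof <- u[i_mid, ]
  exact <- 2 * run$v_mean * (1 - grid$etac^2)
  expect_lt(max(abs(prof - exact)) / (2 * run$v_mean), 0.01)
  # centerline-to-mean ratio of the parabola (cell-center extrapolation)
  expect_equal(prof[1] / run$v_mean, 2 * (1 - grid$etac[1]^2), tolerance = 0.01)
  # outlet flux equals inlet flux within 0.1%
  nc <- ff$n_cycles
  expect_lt(abs(ff$flux_out[25, nc] / ff$flux_in[25, nc] - 1), 1e-3)
  # discrete divergence (relative to inlet flux) at solver precision
  expect_lt(ff$div_rel_max, 1e-8)
  # axial pressure drop matches 8 mu v L / R^2
  p <- matrix(ff$p[, ncol(ff$p)], grid$Nz, grid$Nr)
  ring <- pi * (grid$etaf[-1]^2 - grid$etaf[-(grid$Nr + 1)]^2)
  pbar <- as.numeric(p %*% ring) / sum(ring)
  i0 <- which.min(abs(grid$zc - 0)); i1 <- which.min(abs(grid$zc - 4e-3))
  dp <- pbar[i0] - pbar[i1]
  dp_exact <- 8 * 4e-3 * run$v_mean * (grid$zc[i1] - grid$zc[i0]) / run$radius^2
  expect_equal(dp, dp_exact, tolerance = 1e-6)
})

test_that("doubling viscosity doubles the Poiseuille pressure drop", {
  gu <- uniform_tube(0.74, L = 2, ext = 0.5)
  R <- mm_to_m(0.37)
  inl <- steady_inlet(0.03, R)
  dp_of <- function(mu) {
    grid <- build_grid(gu, "coarse")
    ff <- solve_unsteady(grid, fluid_properties(viscosity = mu), inl,
                         n_cycles = 1, n_store = 30)
    p <- matrix(ff$p[, 30], grid$Nz, grid$Nr)
    ring <- pi * (grid$etaf[-1]^2 - grid$etaf[-(grid$Nr + 1)]^2)
    pbar <- as.numeric(p %*% ring) / sum(ring)
    pbar[which.min(abs(grid$zc - 0))] - pbar[which.min(abs(grid$zc - 2e-3))]
  }
  expect_equal(dp_of(8e-3) / dp_of(4e-3), 2, tolerance = 0.01)
})

test_that("pulsatile runs settle into a periodic state", {
  ff <- preset_field("day7")
  per <- check_periodicity(ff)
  expect_length(per$deviations, 2)
  expect_lt(per$deviations[2], per$deviations[1])   # monotone settling
  expect_true(per$converged)
  expect_lte(ff$cfl_max_observed, 0.1 + 1e-9)
  expect_lt(max(tail(ff$residual_hist, 200)), 1e-6)
  # steady runs are periodic from the first cycle
  per0 <- check_periodicity(poiseuille_run()$field)
  expect_lt(per0$deviations[1], 1e-4)
  expect_false(check_periodicity(poiseuille_run()$field, tol = 0)$converged)
})

test_that("the planar junction conserves mass and honors the flow split", {
  spec <- avf_geometry("day7")
  grid <- build_grid(spec, "coarse", topology = "planar_junction")
  # steady inflow at the day-7 PA velocity; a short bookkeeping period keeps
  # the steady run brief (the split is time-independent)
  Rpa <- mm_to_m(spec$proximal_artery$diameter / 2)
  vm <- ml_min_to_m3s(1.33 / 0.8) / (pi * Rpa^2)
  wf <- synth_waveform(2 * m_to_mm(vm), heart_rate_bpm = 2700, pulsatility = 0)
  inl <- build_inlet(wf, Rpa, geometry = "planar")
  ff <- solve_unsteady(grid, fluid_properties(), inl,
                       da_split = 0.2, n_cycles = 1, n_store = 40)
  split <- flow_split(ff)
  expect_equal(unname(split["AVF"]), 0.8, tolerance = 0.005)
  expect_equal(unname(split["DA"]), 0.2, tolerance = 0.005)
  expect_equal(sum(split), 1, tolerance = 0.005)
  expect_lt(ff$div_rel_max, 1e-8)
  # junction grid exposes exactly three open boundaries
  disc <- avfcfd:::make_planar_disc(grid, fluid_properties(), inl, 0.2)
  expect_gt(length(disc$ext_rows_pa), 0)
  expect_gt(length(disc$ext_rows_da), 0)
  expect_gt(length(disc$top_v), 0)
})

test_that("reversed or invalid inlets are rejected", {
  gu <- uniform_tube()
  grid <- build_grid(gu, "coarse")
  wr <- flow_waveform(c(0, 0.05, 0.1), c(50, -10, 50), 450)
  expect_error(build_inlet(wr, 1e-3), "revers")
  inl <- steady_inlet(0.03, mm_to_m(0.37))
  expect_error(solve_unsteady(grid, fluid_properties(), inl, da_split = 1.2),
               "da_split")
})
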