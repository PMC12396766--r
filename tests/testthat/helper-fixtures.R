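# Shared fixtures: analytic masks built in code, and memoized solver runs so
# that expensive flow solutions are computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# solid sphere mask (radius in voxels), 1 mm spacing for convenient units
sphere_mask <- function(radius = 10, pad = 3, spacing_um = 1000) {
  n <- 2 * (radius + pad) + 1
  ctr <- (n + 1) / 2
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    z <- k - ctr
    arr[, , k] <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                        function(a, b) sqrt(a^2 + b^2 + z^2)) <= radius
  }
  lumen_mask(arr, spacing_um)
}

# axis-aligned solid cylinder along x (radius/length in voxels)
cylinder_mask <- function(radius = 5, length = 26, pad = 3, spacing_um = 1000) {
  nx <- length + 2 * pad
  ny <- 2 * (radius + pad) + 1
  ctr <- (ny + 1) / 2
  arr <- array(FALSE, c(nx, ny, ny))
  disk <- outer(seq_len(ny) - ctr, seq_len(ny) - ctr,
                function(a, b) sqrt(a^2 + b^2)) <= radius
  for (i in (pad + 1):(pad + length)) arr[i, , ] <- disk
  lumen_mask(arr, spacing_um)
}

new_diameter_profile_test <- function(s, d) {
  avfcfd:::new_diameter_profile(
    data.frame(s_mm = s, area_mm2 = pi * (d / 2)^2, diameter_mm = d))
}

# straight uniform tube geometry (diameter mm) for solver tests
uniform_tube <- function(d = 0.74, L = 4, ext = 1) {
  avf_geometry("custom",
               proximal_artery = list(diameter = d, length = 1),
               distal_artery = list(diameter = d, length = 1),
               fistula = list(nominal_diameter = d, stenosis = NULL, length = L),
               vein = list(start_diameter = d, max_diameter = d, length = 0.5),
               inlet_extension = ext)
}

# steady (pulsatility 0) inlet with a given mean velocity (m/s)
steady_inlet <- function(v_mean, radius_m, heart_rate = 450) {
  wf <- synth_waveform(2 * m_to_mm(v_mean), heart_rate, pulsatility = 0)
  build_inlet(wf, radius_m)
}

# memoized steady Poiseuille run on the d = 0.74 mm tube at day-7 flow
poiseuille_run <- function() {
  memo("poiseuille", {
    gu <- uniform_tube(0.74, L = 4, ext = 1)
    R <- mm_to_m(0.37)
    vm <- ml_min_to_m3s(1.33) / (pi * R^2)
    grid <- build_grid(gu, "coarse")
    list(field = solve_unsteady(grid, fluid_properties(),
                                steady_inlet(vm, R), n_cycles = 2,
                                n_store = 50),
         grid = grid, v_mean = vm, radius = R)
  })
}

# memoized day-7 phantom segmentation chain (parameter recovery)
day7_recovery <- function() {
  memo("day7_recovery", {
    spec <- avf_geometry("day7")
    vol <- voxelize_phantom(spec, spacing_um = 72)
    mask <- threshold_segment(vol)
    ep <- avfcfd:::.phantom_endpoints(spec, mask)
    cl <- extract_centerline(mask, ep)
    prof <- suppressWarnings(cross_section_profile(cl, mask))
    list(spec = spec, vol = vol, mask = mask, centerline = cl, profile = prof)
  })
}

# memoized pulsatile stenotic runs for the two presets (coarse level)
preset_field <- function(preset) {
  memo(paste0("field_", preset), {
    spec <- avf_geometry(preset)
    bc <- avf_boundary_conditions(spec, preset)
    grid <- build_grid(spec, "coarse")
    solve_unsteady(grid, fluid_properties(), bc$inlet, n_cycles = 3)
  })
}
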