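test_that("parabolic peak-to-mean reduction halves velocities", {
  expect_equal(mean_from_peak(100), 50)
  expect_equal(mean_from_peak(0), 0)
  wf <- synth_waveform(100, 450, 0.3, seed = 1)
  halved <- mean_from_peak(wf)
  expect_equal(halved$value, wf$value / 2)
  expect_equal(attr(halved, "period_s"), attr(wf, "period_s"))
})

test_that("Q = A V with unit conversion reproduces the day-7 flow scale", {
  A <- pi * (0.37e-3)^2
  expect_equal(flow_rate(A, 51.6e-3, units = "ml_min"), 1.3316, tolerance = 1e-3)
  expect_equal(flow_rate(A, 0), 0)
  expect_equal(flow_rate(2 * A, 0.05), 2 * flow_rate(A, 0.05))
  expect_error(flow_rate(-1, 1), "positive")
})

test_that("Womersley number matches the closed form and its scalings", {
  a <- womersley_number(0.29e-3, 450)
  expect_equal(a, 0.29e-3 * sqrt(2 * pi * 7.5 * 1040 / 4e-3), tolerance = 1e-12)
  expect_equal(a, 1.02, tolerance = 0.01)
  expect_equal(womersley_number(0, 450), 0)
  expect_equal(womersley_number(0.3e-3, 4 * 450) / womersley_number(0.3e-3, 450),
               2, tolerance = 1e-12)
  # dimensional sanity: mm-as-m misuse would be off by sqrt(1000) scale
  expect_equal(womersley_number(0.29e-3, 450, fluid_properties(1040, 4e-3)),
               womersley_number(0.29e-3, 450), tolerance = 1e-12)
})

test_that("parabolic inlets integrate to Q = A v_mean at every phase", {
  wf <- synth_waveform(120, 450, 0.5, seed = 9)
  R <- 0.37e-3
  inl <- build_inlet(wf, R)
  r <- seq(0, R, length.out = 4001)
  for (t in c(0, 0.03, 0.1)) {
    q_num <- sum(2 * pi * r * inl$profile(r, t)) * (r[2] - r[1])
    expect_equal(q_num, pi * R^2 * inl$v_mean(t), tolerance = 1e-3)
  }
  expect_equal(inl$profile(R, 0.05), 0)               # no-slip compatible
  expect_equal(inl$profile(0, 0.05), 2 * inl$v_mean(0.05))
  # planar reduction uses the 3/2 peak factor
  inp <- build_inlet(wf, R, geometry = "planar")
  expect_equal(inp$profile(0, 0.02), 1.5 * inp$v_mean(0.02))
  # reversing waveforms are rejected
  wr <- flow_waveform(c(0, 0.05, 0.1), c(50, -10, 50), 450)
  expect_error(build_inlet(wr, R), "revers")
})

test_that("preset boundary conditions hit the target mean flow", {
  spec <- avf_geometry("day7")
  bc <- avf_boundary_conditions(spec, "day7")
  R <- mm_to_m(fistula_diameter(spec, 0) / 2)
  tt <- seq(0, bc$inlet$period_s, length.out = 5000)
  q_mean <- m3s_to_ml_min(pi * R^2 * mean(bc$inlet$v_mean(tt)))
  expect_equal(q_mean, 1.33, tolerance = 0.005)
  expect_equal(bc$da_split, 0.2)
  bc21 <- avf_boundary_conditions(avf_geometry("day21"), "day21")
  expect_equal(bc21$da_split, 0.3)
})
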