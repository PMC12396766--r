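test_that("TAWSS time averaging matches analytic integrals", {
  n <- 200
  Tp <- 60 / 450
  tt <- seq_len(n) * Tp / n
  expect_equal(tawss(rep(2.5, n), tt, Tp), 2.5)
  tau_sin <- sin(2 * pi * tt / Tp)
  expect_equal(tawss(tau_sin, tt, Tp), 2 / pi, tolerance = 1e-3)
  # linear scaling
  expect_equal(tawss(3 * tau_sin, tt, Tp), 3 * tawss(tau_sin, tt, Tp))
  expect_error(tawss(matrix(1, 2, 1), 0.1, Tp), "phases")
})

test_that("OSI hits its analytic endpoints and interior values", {
  n <- 200
  Tp <- 60 / 450
  tt <- seq_len(n) * Tp / n
  expect_equal(osi(sin(2 * pi * tt / Tp), tt, Tp), 0.5, tolerance = 1e-12)
  expect_equal(osi(1 + 0.5 * sin(2 * pi * tt / Tp), tt, Tp), 0)
  # +1 for 3/4 of the cycle, -1 for 1/4: |mean| = 1/2, mean|.| = 1 -> 0.25
  tau <- ifelse(tt <= 0.75 * Tp, 1, -1)
  expect_equal(osi(tau, tt, Tp), 0.25, tolerance = 0.01)
  expect_warning(z <- osi(rep(0, n), tt, Tp), "zero")
  expect_equal(z, 0)
})

test_that("OSI stays in [0, 0.5] and is scale-invariant under fuzzing", {
  n <- 100
  Tp <- 0.1333
  tt <- seq_len(n) * Tp / n
  set.seed(42)
  for (k in 1:50) {
    tau <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.01, 3))
    val <- osi(tau, tt, Tp)
    expect_gte(val, 0)
    expect_lte(val, 0.5)
    expect_equal(osi(runif(1, 0.1, 10) * tau, tt, Tp), val, tolerance = 1e-9)
  }
})

test_that("Q-criterion distinguishes rotation, shear, and translation", {
  n <- 21
  x <- seq(-1, 1, length.out = n)
  h <- x[2] - x[1]
  X <- matrix(x, n, n); Y <- t(X)
  Om <- 0.7
  Q_rot <- q_criterion_field(-Om * Y, Om * X, h, h)
  inner <- 3:(n - 2)
  expect_equal(Q_rot[inner, inner], matrix(Om^2, length(inner), length(inner)),
               tolerance = 1e-10)
  Q_shear <- q_criterion_field(2 * Y, 0 * X, h, h)
  expect_equal(max(abs(Q_shear[inner, inner])), 0, tolerance = 1e-10)
  Q_trans <- q_criterion_field(matrix(1, n, n), matrix(2, n, n), h, h)
  expect_equal(max(abs(Q_trans)), 0, tolerance = 1e-12)
})

test_that("TAWSS-diameter power-law fit recovers the Poiseuille exponent", {
  s <- seq(0, 4, by = 0.05)
  d <- 0.6 + 0.3 * sin(s)            # arbitrary smooth diameter variation
  Q <- ml_min_to_m3s(1.33)
  tw <- 4 * 4e-3 * Q / (pi * mm_to_m(d / 2)^3)
  fit <- correlate_tawss_diameter(data.frame(s_mm = s, avg = tw),
                                  new_diameter_profile_test(s, d))
  expect_equal(fit$exponent, -3, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.9999)
  # constant TAWSS -> zero exponent
  fit0 <- correlate_tawss_diameter(data.frame(s_mm = s, avg = rep(2, length(s))),
                                   new_diameter_profile_test(s, d))
  expect_equal(fit0$exponent, 0, tolerance = 1e-9)
  expect_error(correlate_tawss_diameter(data.frame(s_mm = 1:3, avg = 1:3),
                                        new_diameter_profile_test(1:3, c(1, 1, 1))),
               "5 matched")
})

test_that("steady Poiseuille wall shear matches 4 mu Q / (pi R^3)", {
  run <- poiseuille_run()
  rec <- wall_shear_stress(run$field)
  Q <- pi * run$radius^2 * run$v_mean
  wss_exact <- 4 * 4e-3 * Q / (pi * run$radius^3)
  mid <- rec$s_mm > -0.5 & rec$s_mm < 4
  expect_lt(max(abs(rec$tau[mid, 25] / wss_exact - 1)), 0.01)
  # TAWSS of a steady run equals the instantaneous WSS
  tw <- tawss(rec)
  expect_equal(tw[mid], rec$tau[mid, 25], tolerance = 1e-6)
  # steady unidirectional flow has zero OSI
  expect_equal(max(osi(rec)[mid]), 0, tolerance = 1e-9)
})

test_that("flow split, mass conservation, and pressure drop on a tube", {
  run <- poiseuille_run()
  split <- flow_split(run$field)
  expect_equal(unname(split["AVF"]), 1, tolerance = 1e-6)
  # linear pressure drop: fraction = distance / length
  frac <- pressure_drop_localization(run$field, 1.5, s_end = 4)
  expect_equal(frac, 1.5 / 4, tolerance = 0.02)
  expect_error(pressure_drop_localization(run$field, 1.5, phase = 10, s_end = 0),
               "zero total")
  # cross-sectional max >= avg everywhere
  vel <- metric_profile(run$field, "velocity")
  expect_true(all(vel$max >= vel$avg - 1e-12))
  # windowed average of a constant profile is the constant
  const_prof <- vel
  const_prof$max <- const_prof$avg <- 2
  expect_equal(windowed_average(const_prof, c(0, 4)), 2)
})
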