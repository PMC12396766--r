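# Centerline extraction and cross-sectional diameter profiling.

test_that("straight cylinder centerline is collinear with the axis", {
  gu <- uniform_tube(0.74, L = 4, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72)
  mask <- threshold_segment(vol)
  h <- um_to_mm(72)
  to_idx <- function(p) round((p - mask$origin_mm) / h) + 1
  # single path up the fistula branch (along +y)
  cl <- extract_centerline(mask, list(PA = to_idx(c(0, 0.3, 0)),
                                      DA = NULL,
                                      vein = to_idx(c(0, 4.2, 0))))
  dev <- sqrt(cl$points[, 1]^2 + cl$points[, 3]^2)
  expect_lt(max(dev), h)                        # < 1 voxel off axis
  len <- max(cl$s) - min(cl$s)
  expect_lt(abs(len - 3.9), 2 * h)              # endpoint-to-endpoint length
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$points)))
})

test_that("an L-shaped path is longer than the endpoint distance", {
  gu <- uniform_tube(0.74, L = 4, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72)
  mask <- threshold_segment(vol)
  h <- um_to_mm(72)
  to_idx <- function(p) round((p - mask$origin_mm) / h) + 1
  a <- c(-0.8, 0, 0); b <- c(0, 3.5, 0)
  cl <- extract_centerline(mask, list(PA = to_idx(a), DA = NULL,
                                      vein = to_idx(b)))
  arc <- max(cl$s) - min(cl$s)
  expect_gt(arc, sqrt(sum((a - b)^2)))
})

test_that("cross sections of a cylinder recover its diameter everywhere", {
  gu <- uniform_tube(0.74, L = 4, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72)
  mask <- threshold_segment(vol)
  h <- um_to_mm(72)
  to_idx <- function(p) round((p - mask$origin_mm) / h) + 1
  cl <- extract_centerline(mask, list(PA = to_idx(c(0, 0.4, 0)), DA = NULL,
                                      vein = to_idx(c(0, 4.1, 0))))
  prof <- cross_section_profile(cl, mask, ds = 0.1)
  expect_true(all(abs(prof$diameter_mm - 0.74) < h))
  expect_equal(prof$diameter_mm, 2 * sqrt(prof$area_mm2 / pi), tolerance = 1e-9)
})

test_that("elliptical cross sections give the equivalent diameter 2 sqrt(ab)", {
  # elliptic cylinder along x with semi-axes 0.4 / 0.2 mm at 50 um spacing
  h <- 0.05
  nx <- 40; ny <- 21; nz <- 13
  arr <- array(FALSE, c(nx, ny, nz))
  yc <- ((1:ny) - (ny + 1) / 2) * h
  zc <- ((1:nz) - (nz + 1) / 2) * h
  el <- outer(yc, zc, function(y, z) (y / 0.4)^2 + (z / 0.2)^2) <= 1
  for (i in 3:(nx - 2)) arr[i, , ] <- el
  mask <- lumen_mask(arr, spacing_um = 50,
                     origin_mm = c(0, yc[1], zc[1]))
  cl <- centerline(cbind(seq(0.3, (nx - 3) * h, by = 0.05), 0, 0),
                   s = seq(0.3, (nx - 3) * h, by = 0.05))
  prof <- suppressWarnings(cross_section_profile(cl, mask, ds = 0.2))
  d_eq <- 2 * sqrt(0.4 * 0.2)
  mid <- prof$s_mm > 0.5 & prof$s_mm < 1.4
  expect_true(all(abs(prof$diameter_mm[mid] - d_eq) < 2 * h))
})

test_that("segment statistics behave on constant and windowed profiles", {
  rp <- radius_profile(uniform_tube(0.8), ds = 0.05)
  st <- segment_stats(rp, c(0, 2), branch = "AVF")
  expect_equal(st$mean_mm, 0.8)
  expect_equal(st$min_mm, st$max_mm)
  expect_error(segment_stats(rp, c(90, 95)), "no profile stations")
  # resampling invariance
  rp2 <- radius_profile(avf_geometry("day7"), ds = 0.01)
  rp3 <- radius_profile(avf_geometry("day7"), ds = 0.04)
  s2 <- segment_stats(rp2, c(0, 2), branch = "AVF")
  s3 <- segment_stats(rp3, c(0, 2), branch = "AVF")
  expect_lt(abs(s2$mean_mm / s3$mean_mm - 1), 0.01)
})

test_that("Poiseuille resistance matches closed forms and scalings", {
  mu <- 4e-3
  rp <- radius_profile(uniform_tube(0.88), ds = 0.01)
  R <- poiseuille_resistance(rp, mu, s_range = c(0, 4), branch = "AVF")
  R_exact <- 8 * mu * 4e-3 / (pi * (0.44e-3)^4)
  expect_equal(R, R_exact, tolerance = 1e-6)
  expect_equal(R_exact, 1.09e9, tolerance = 0.01)
  # halving the diameter raises resistance 16-fold
  rp_half <- radius_profile(uniform_tube(0.44), ds = 0.01)
  R_half <- poiseuille_resistance(rp_half, mu, s_range = c(0, 4), branch = "AVF")
  expect_equal(R_half / R, 16, tolerance = 1e-6)
  # series additivity for a piecewise two-diameter tube
  d1 <- 0.8; d2 <- 0.5
  prof <- new_diameter_profile_test(c(seq(0, 2, 0.01), seq(2.01, 4, 0.01)),
                                    c(rep(d1, 201), rep(d2, 200)))
  R_piece <- poiseuille_resistance(prof, mu, s_range = c(0, 4))
  R_sum <- 8 * mu * 2e-3 / (pi * (d1 / 2000)^4) +
    8 * mu * 2e-3 / (pi * (d2 / 2000)^4)
  expect_equal(R_piece, R_sum, tolerance = 0.02)
  # monotone: any pointwise diameter increase lowers resistance
  rp_big <- radius_profile(uniform_tube(0.9), ds = 0.01)
  expect_lt(poiseuille_resistance(rp_big, mu, s_range = c(0, 4), branch = "AVF"),
            R)
  expect_error(poiseuille_resistance(rp, mu, s_range = c(-100, 0)), "cover")
})
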