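test_that("thresholding uses inclusive bounds and reproduces the lumen", {
  gu <- uniform_tube(0.6, L = 3, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72, hu_vessel = 650,
                          hu_background = 0)
  mask <- threshold_segment(vol, 300, 1000)
  expect_identical(mask$values, vol$values >= 300)
  # inclusive boundary: a voxel at exactly the lower bound is foreground
  v2 <- vol
  idx <- which(vol$values == 0)[1]
  v2$values[idx] <- 300
  m2 <- threshold_segment(v2, 300, 1000)
  expect_true(m2$values[idx])
  expect_error(threshold_segment(vol, 1000, 300), "lo < hi")
  expect_error(threshold_segment(vol, 2000, 3000), "empty")
})

test_that("thresholding is idempotent and monotone in the window", {
  vol <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90,
                          noise_sd = 120, seed = 2)
  narrow <- threshold_segment(vol, 400, 900)
  wide <- threshold_segment(vol, 300, 1000)
  expect_true(all(wide$values[narrow$values]))   # narrow subset of wide
})

test_that("a bone-like block survives thresholding and is removed by growing", {
  gu <- uniform_tube(0.6, L = 3, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72, hu_vessel = 650)
  # synthetic bone block in a corner, inside the HU window
  vol$values[2:6, 2:6, 2:6] <- 900
  mask <- threshold_segment(vol)
  lab <- avfcfd:::label_components(mask$values, 26)
  expect_identical(max(lab), 2L)
  seed_vox <- round((c(0, 1, 0) - mask$origin_mm) / um_to_mm(72)) + 1
  grown <- region_grow(mask, list(seed_vox))
  expect_false(any(grown$values[2:6, 2:6, 2:6]))
  expect_true(grown$values[seed_vox[1], seed_vox[2], seed_vox[3]])
  # fixed point: growing again changes nothing
  again <- region_grow(grown, list(seed_vox))
  expect_identical(again$values, grown$values)
})

test_that("region growing respects connectivity for diagonal contacts", {
  arr <- array(FALSE, c(3, 3, 3))
  arr[1, 1, 1] <- TRUE
  arr[2, 2, 2] <- TRUE     # touches (1,1,1) only through a corner
  m <- lumen_mask(arr, 1000)
  g6 <- region_grow(m, list(c(1, 1, 1)), connectivity = 6)
  expect_identical(sum(g6$values), 1L)
  g26 <- region_grow(m, list(c(1, 1, 1)), connectivity = 26)
  expect_identical(sum(g26$values), 2L)
  expect_error(region_grow(m, list(c(3, 3, 3))), "background")
})

test_that("surface extraction recovers sphere area and closed topology", {
  mesh <- extract_surface(sphere_mask(10))
  expect_true(is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 100) - 1), 0.03)
  expect_lt(abs(abs(mesh_volume(mesh)) / (4 / 3 * pi * 1000) - 1), 0.05)
})

test_that("a single voxel yields a small closed surface", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  mesh <- extract_surface(lumen_mask(one, 1000), smooth_sigma = 0)
  expect_true(is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2)
})

test_that("cylinder surface bounding box matches the cylinder length", {
  mesh <- extract_surface(cylinder_mask(5, 26))
  len <- diff(range(mesh$vertices[, 1]))
  expect_lt(abs(len - 26), 1)   # within one voxel spacing (1 mm here)
})

test_that("masks touching the volume border are rejected", {
  arr <- array(FALSE, c(5, 5, 5)); arr[1, 3, 3] <- TRUE
  expect_error(extract_surface(lumen_mask(arr, 1000)), "border")
})

test_that("Taubin smoothing preserves volume and is identity at 0 iterations", {
  mesh <- extract_surface(sphere_mask(8), smooth_sigma = 0)  # faceted input
  s0 <- smooth_surface(mesh, 0)
  expect_identical(s0$vertices, mesh$vertices)
  s20 <- smooth_surface(mesh, 20)
  expect_lt(mesh_area(s20), mesh_area(mesh))      # irregularity removed
  expect_lt(abs(mesh_volume(s20) / mesh_volume(mesh) - 1), 0.02)
  expect_true(is.finite(attr(s20, "max_displacement")))
  # already-smooth surface barely moves
  smooth_in <- extract_surface(cylinder_mask(5, 20))
  s2 <- smooth_surface(smooth_in, 20)
  expect_lt(attr(s2, "max_displacement"), 0.5)    # < half a voxel (1 mm)
  open_mesh <- mesh
  open_mesh$faces <- open_mesh$faces[-1, ]
  open_mesh$watertight <- FALSE
  expect_error(smooth_surface(open_mesh, 5), "watertight")
})
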