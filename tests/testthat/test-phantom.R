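test_that("voxelized straight tube matches the analytic cylinder volume", {
  gu <- uniform_tube(0.74, L = 4, ext = 0)
  vol <- voxelize_phantom(gu, spacing_um = 72, noise_sd = 0)
  mask <- vol$values >= 300
  h <- um_to_mm(72)
  # artery 2 mm (1 mm per side) + branch 4.5 mm, minus the half-Steinmetz
  # junction overlap of the two equal cylinders
  v_analytic <- pi * 0.37^2 * (2 + 4.5) - 8 / 3 * 0.37^3
  v_voxel <- sum(mask) * h^3
  expect_lt(abs(v_voxel / v_analytic - 1), 0.10)
})

test_that("noise-free phantom HU histogram has exactly two values", {
  vol <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90,
                          hu_vessel = 650, hu_background = 0, noise_sd = 0)
  expect_setequal(unique(as.numeric(vol$values)), c(0, 650))
})

test_that("phantom noise is deterministic for a fixed seed", {
  a <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90, noise_sd = 20,
                        seed = 5)
  b <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90, noise_sd = 20,
                        seed = 5)
  c2 <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90, noise_sd = 20,
                         seed = 6)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c2$values))
})

test_that("voxelization refuses spacing too coarse for the minimum lumen", {
  expect_error(voxelize_phantom(avf_geometry("day7"), spacing_um = 200),
               "finer spacing")
  expect_error(voxelize_phantom(avf_geometry("day7"), spacing_um = 72,
                                hu_vessel = 200), "window")
})

test_that("NIfTI round trip preserves values and spacing", {
  vol <- voxelize_phantom(avf_geometry("day7"), spacing_um = 90)
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- read_volume_nifti(path)
  expect_equal(back$values, vol$values, ignore_attr = TRUE)
  expect_equal(back$spacing_um, 90, tolerance = 1e-6)
  unlink(path)
})
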