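test_that("presets reproduce the reported murine diameter statistics", {
  targets <- list(
    day7 = c(pa = 0.29, mean2 = 0.74, min = 0.46, max2 = 0.95,
             mean4 = 0.88, max4 = 1.07),
    day21 = c(pa = 0.39, mean2 = 0.58, min = 0.31, max2 = 0.96,
              mean4 = 0.86, max4 = 1.71)
  )
  for (preset in names(targets)) {
    spec <- avf_geometry(preset)
    rp <- radius_profile(spec, ds = 0.005)
    avf <- rp[rp$branch %in% c("AVF"), ]
    st2 <- segment_stats(rp, c(0, 2), branch = "AVF")
    st4 <- segment_stats(rp, c(0, 4), branch = "AVF")
    tg <- targets[[preset]]
    expect_equal(spec$proximal_artery$diameter, unname(tg["pa"]))
    expect_equal(st2$mean_mm, unname(tg["mean2"]), tolerance = 0.005 / tg["mean2"])
    expect_equal(st2$min_mm, unname(tg["min"]), tolerance = 0.005 / tg["min"])
    expect_equal(st2$max_mm, unname(tg["max2"]), tolerance = 0.005 / tg["max2"])
    expect_equal(st4$mean_mm, unname(tg["mean4"]), tolerance = 0.005 / tg["mean4"])
    expect_equal(st4$max_mm, unname(tg["max4"]), tolerance = 0.005 / tg["max4"])
    # stenosis minimum matches the stored field and sits in the first 2 mm
    expect_equal(min(avf$diameter_mm), spec$fistula$stenosis$min_diameter,
                 tolerance = 0.005)
    expect_lt(avf$s_mm[which.min(avf$diameter_mm)], 2)
  }
})

test_that("the fistula radius function is continuous into the vein", {
  for (preset in c("day7", "day21")) {
    spec <- avf_geometry(preset)
    s <- seq(0, spec$fistula$length + 1, by = 1e-4)
    d <- fistula_diameter(spec, s)
    expect_true(all(is.finite(d)) && all(d > 0))
    expect_lt(max(abs(diff(d))), 1e-3)  # no jumps at the 1e-4 mm scale
  }
})

test_that("custom uniform tube yields a constant radius profile", {
  gu <- avf_geometry("custom",
                     fistula = list(nominal_diameter = 0.88, stenosis = NULL),
                     vein = list(start_diameter = 0.88, max_diameter = 0.88))
  d <- fistula_diameter(gu, seq(0, 5, by = 0.01))
  expect_equal(d, rep(0.88, length(d)))
})

test_that("custom stenosis dip is calibrated to the requested minimum", {
  gu <- avf_geometry("custom",
                     fistula = list(nominal_diameter = 0.8,
                                    stenosis = list(center_s = 1.5,
                                                    min_diameter = 0.4,
                                                    width = 0.3)))
  d <- fistula_diameter(gu, seq(0, 4, by = 1e-3))
  expect_equal(min(d), 0.4, tolerance = 1e-6)
})

test_that("geometry validation names the offending field", {
  expect_error(avf_geometry("day7", anastomosis_angle = 190), "anastomosis_angle")
  expect_error(avf_geometry("day7", proximal_artery = list(diameter = -1)),
               "proximal_artery\\$diameter")
  expect_error(avf_geometry("day7", nonsense = 1), "nonsense")
  expect_error(
    avf_geometry("custom",
                 fistula = list(nominal_diameter = 0.5,
                                stenosis = list(center_s = 1, min_diameter = 0.6,
                                                width = 0.2))),
    "min_diameter")
})

test_that("radius_profile validates the station spacing", {
  spec <- avf_geometry("day7")
  expect_error(radius_profile(spec, ds = -0.1), "positive")
  expect_error(radius_profile(spec, ds = 10), "shortest segment")
  rp <- radius_profile(spec, 0.05)
  expect_equal(rp$diameter_mm, 2 * sqrt(rp$area_mm2 / pi), tolerance = 1e-12)
})

test_that("percent change reports direction and reproduces reported values", {
  expect_equal(as.numeric(round(percent_change(0.74, 0.58), 1)), -21.6)
  expect_equal(as.numeric(round(percent_change(0.46, 0.31), 1)), -32.6)
  expect_equal(as.numeric(round(percent_change(1.07, 1.71), 1)), 59.8)
  expect_equal(as.numeric(percent_change(1, 1)), 0)
  expect_identical(attr(percent_change(0.74, 0.58), "direction"), "narrowing")
  expect_error(percent_change(0, 1), "positive")
})
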