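test_that("ROI extraction returns the field value on constant volumes", {
  ph <- generate_vertebra_phantom(small_spec())
  flat <- ct_volume(array(120, dim = dim(ph$ct$data)), spacing = ph$ct$spacing)
  expect_equal(extract_roi_hu(flat, ph$labels, roi_spec(1)), 120)

  ph80 <- generate_vertebra_phantom(small_spec(trabecular_hu = 80))
  expect_equal(extract_roi_hu(ph80$ct, ph80$labels, roi_spec(1)), 80)

  expect_error(extract_roi_hu(ph$ct, ph$labels, roi_spec(77)), "not present")
  expect_error(roi_spec(1, height_fraction = 0), "\\(0, 1\\]")
})

test_that("phantom calibration evaluates the two-point line exactly", {
  cal <- calibration_phantom(hu_water = 30, hu_bone = 430)
  expect_equal(calibrate_bmd(30, cal), 0)
  expect_equal(calibrate_bmd(430, cal), 200)
  expect_equal(calibrate_bmd(100, calibration_phantom(0, 400)), 50)
  expect_error(calibration_phantom(hu_water = 5, hu_bone = 5), "degenerate")
})

test_that("QCT conversion is the printed affine map", {
  expect_equal(to_qct(0), -11)
  expect_equal(to_qct(100), 58)
  pts <- c(10, 120, 250)
  expect_equal(unname(coef(lm(to_qct(pts) ~ pts))[2]), 0.69)
})

test_that("the calibration chain is affine end to end", {
  cal <- calibration_phantom(12, 385)
  hu <- c(-20, 100, 310)
  q <- to_qct(calibrate_bmd(hu, cal))
  # three points on a line: slope is the same between consecutive pairs
  s1 <- (q[2] - q[1]) / (hu[2] - hu[1])
  s2 <- (q[3] - q[2]) / (hu[3] - hu[2])
  expect_equal(s1, s2)
})

test_that("density rendering and densitometry are mutually inverse", {
  cal <- calibration_phantom()
  for (target in c(40, 100, 160)) {
    hu <- hu_from_bmd(mdct_from_qct(target), cal)
    expect_equal(to_qct(calibrate_bmd(hu, cal)), target)
  }
})

test_that("BMD ratio follows the triplet-over-lumbar definition", {
  expect_equal(bmd_ratio(c(50, 60, 70), c(50, 60, 70)), 1)
  expect_equal(bmd_ratio(c(60, 60, 60), c(80, 80, 80)), 0.75)
  expect_error(bmd_ratio(numeric(0), c(1, 2)), "non-empty")
  expect_error(bmd_ratio(c(1, 2), c(-1, 1)), "undefined")
})

test_that("measure_bmd tabulates all requested vertebrae", {
  ph <- generate_fsu_phantom(small_spec(), 3)
  tab <- measure_bmd(ph$ct, ph$labels, c(L1 = 1, L2 = 2, L3 = 3),
                     calibration_phantom())
  expect_equal(nrow(tab), 3)
  expect_equal(tab$hu_mean, rep(120, 3))
  expect_equal(tab$bmd_qct, to_qct(calibrate_bmd(tab$hu_mean,
                                                 calibration_phantom())))
})
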