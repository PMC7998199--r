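test_that("noiseless phantom renders exact compartment attenuations", {
  ph <- generate_vertebra_phantom(small_spec(), calibration_phantom())
  expect_identical(unique(as.vector(ph$ct$data[ph$labels$data == 1])), 120)
  expect_identical(unique(as.vector(ph$ct$data[ph$labels$data == 101])), 600)
  expect_identical(unique(as.vector(ph$ct$data[ph$labels$data == 901])), 0)
  expect_identical(unique(as.vector(ph$ct$data[ph$labels$data == 902])), 400)
})

test_that("phantom generation is deterministic in the seed", {
  sp <- small_spec(noise_sd = 10)
  a <- generate_vertebra_phantom(sp)
  b <- generate_vertebra_phantom(sp)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$labels$data, b$labels$data)
  c <- generate_vertebra_phantom(sp, seed = 99L)
  expect_false(identical(a$ct$data, c$ct$data))
})

test_that("additive noise preserves the trabecular mean at the CLT rate", {
  sp <- phantom_spec(half_axes = c(16, 12), body_height = 25,
                     shell_thickness = 1.5, spacing = 1, noise_sd = 10,
                     seed = 42L)
  ph <- generate_vertebra_phantom(sp)
  vals <- ph$ct$data[ph$labels$data == 1]
  expect_gt(length(vals), 1e4)
  expect_lt(abs(mean(vals) - sp$trabecular_hu), 3 * 10 / sqrt(length(vals)))
})

test_that("FSU stacks carry the expected per-region labels", {
  ph <- generate_fsu_phantom(small_spec(), n_vertebrae = 3)
  present <- sort(unique(as.vector(ph$labels$data)))
  expect_true(all(c(1:3, 101:103, 301:302, 401:402) %in% present))
  expect_false(any(c(4, 303, 403) %in% present))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(small_spec(ivd_height = 0), "positive")
  expect_error(small_spec(nucleus_radius_fraction = 1), "nucleus_radius_fraction")
  expect_error(small_spec(noise_sd = -1), "noise_sd")
  expect_error(small_spec(shell_thickness = 7), "shell")
})

test_that("labelled disc volume matches analytic geometry to a voxel shell", {
  sp <- phantom_spec(half_axes = c(14, 10), body_height = 12,
                     shell_thickness = 1.5, ivd_height = 6, spacing = 1,
                     noise_sd = 0)
  ph <- generate_fsu_phantom(sp, n_vertebrae = 3)
  vv <- prod(sp$spacing)
  disc_vox <- sum(ph$labels$data %in% c(301, 302, 401, 402))
  analytic <- 2 * pi * sp$half_axes[1] * sp$half_axes[2] * sp$ivd_height
  # one-voxel surface shell: two end faces plus the lateral band
  a <- sp$half_axes[1]; b <- sp$half_axes[2]
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  shell <- 2 * (2 * pi * a * b + perim * sp$ivd_height) * max(sp$spacing)
  expect_lt(abs(disc_vox * vv - analytic), shell)
})

test_that("cohort draws honour the requested correlation structure", {
  sim0 <- simulate_cohort(
    cohort_spec(n_subjects = 200, fracture_site_correlation = 0,
                covariate_effect = 0, seed = 3),
    small_spec(), render = FALSE)
  r0 <- cor(sim0$truth$lumbar_bmd_qct, sim0$truth$fracture_bmd_qct)
  expect_lt(abs(r0), 0.2)  # Fisher-z bound at n = 200

  sim1 <- simulate_cohort(
    cohort_spec(n_subjects = 50, fracture_site_correlation = 1,
                covariate_effect = 0, seed = 3),
    small_spec(), render = FALSE)
  expect_equal(cor(sim1$truth$lumbar_bmd_qct, sim1$truth$fracture_bmd_qct), 1)

  expect_error(cohort_spec(fracture_site_correlation = 1.2), "\\[-1, 1\\]")
  expect_error(cohort_spec(n_subjects = 3), ">= 4")
})

test_that("an 11-subject cohort renders end to end", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 11, seed = 5), small_spec(),
                         render = TRUE)
  expect_length(sim$subjects, 11)
  expect_equal(nrow(sim$truth), 11)
  expect_s3_class(sim$subjects[[1]]$ct, "ct_volume")
})

test_that("volumes survive a NIfTI round trip", {
  ph <- generate_vertebra_phantom(small_spec())
  tmp <- tempfile(fileext = ".nii.gz")
  write_volume(ph$ct, tmp)
  back <- read_volume(tmp)
  expect_equal(back$data, ph$ct$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$spacing, ph$ct$spacing)
  unlink(tmp)
})
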