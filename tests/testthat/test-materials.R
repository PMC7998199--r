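test_that("density mappings evaluate the printed relations", {
  expect_equal(hu_to_apparent_density(0), 47)
  expect_equal(hu_to_apparent_density(100), 159.2)
  expect_equal(diff(hu_to_apparent_density(c(10, 11))), 1.122)
  expect_equal(apparent_to_ash(100), 60)
  expect_equal(apparent_to_ash(0), 0)
})

test_that("elastic constants follow the transversely isotropic ratios", {
  e <- elastic_constants(100)
  expect_equal(e$E_z, 233)
  expect_equal(e$E_x, 77.589)
  expect_equal(e$E_y, e$E_x)
  rho <- seq(80, 400, by = 40)
  ee <- elastic_constants(rho)
  expect_equal(ee$E_x / ee$E_z, rep(0.333, length(rho)))
  expect_equal(ee$G_xy / ee$E_z, rep(0.121, length(rho)))
  expect_equal(ee$G_xz / ee$E_z, rep(0.157, length(rho)))
  expect_equal(ee$nu_xz, ee$nu_yz)
  # clipping at the floor for densities where the affine law goes negative
  expect_equal(elastic_constants(0, floor = 0.01)$E_z, 0.01)
  expect_error(elastic_constants(100, floor = 0), "positive")
})

test_that("strength laws use the piecewise branches in g/cm^3", {
  s <- strength_limits(1)
  expect_equal(s$sigma_max, 114)
  expect_equal(s$sigma_min, 65.1)
  expect_equal(strength_limits(0)$eps_plastic, -0.00315)
  # the branch point belongs to the high-density branch
  expect_equal(strength_limits(0.317)$sigma_max, 114 * 0.317^1.72)
  # near-continuity across the branch point
  expect_lt(abs(137 * 0.317^1.88 - 114 * 0.317^1.72), 0.1)
  expect_lt(abs(strength_limits(0.317 - 1e-9)$sigma_max -
                strength_limits(0.317 + 1e-9)$sigma_max), 0.1)
  expect_error(strength_limits(-0.1), ">= 0")
})

test_that("the full HU chain is monotone and positive definite", {
  hu <- seq(0, 800, by = 50)
  cards <- material_cards(hu)
  up <- material_cards(hu + 50)
  raw_ez <- -349 + 5.82 * cards$rho_app
  pre_floor <- raw_ez > 0.01
  expect_true(all(up$E_z[pre_floor] > cards$E_z[pre_floor]))
  expect_true(all(up$sigma_max > cards$sigma_max))
  expect_true(all(up$sigma_min > cards$sigma_min))
  expect_true(all(up$eps_plastic > cards$eps_plastic))
  # assembled stiffness is positive definite for every card
  C0 <- osteofea:::bone_unit_stiffness()
  for (ez in range(cards$E_z))
    expect_true(all(eigen(ez * C0, symmetric = TRUE)$values > 0))
})

test_that("disc material constants are fixed", {
  expect_equal(ivd_material("annulus"), list(region = "annulus", E = 500, nu = 0.3))
  expect_equal(ivd_material("nucleus"),
               list(region = "nucleus", E = 1, nu = 0.475))
  expect_error(ivd_material("ligament"))
})

test_that("element material assignment samples the parent voxel field", {
  lv <- cuboid_labels(3, 3, 4)
  vol <- ct_volume(array(100, dim = dim(lv$data)), spacing = lv$spacing)
  mesh <- mask_to_tet_mesh(lv, 1)
  cards <- assign_element_materials(mesh, vol)
  expect_equal(nrow(cards), nrow(mesh$tets))
  expect_equal(unique(cards$rho_app), 159.2)
  # raising all attenuations raises every pre-floor axial modulus
  vol2 <- ct_volume(vol$data + 50, spacing = lv$spacing)
  cards2 <- assign_element_materials(mesh, vol2)
  expect_true(all(cards2$E_z > cards$E_z))
})

test_that("generic HU sampling falls back to interpolation off-grid", {
  vol <- ct_volume(array(rep(c(80, 120), each = 8), dim = c(2, 2, 4)))
  mesh <- mask_to_tet_mesh(label_volume(array(1L, c(2, 2, 4))), 1)
  mesh$voxel_id <- NULL  # force the generic sampling path
  hu <- osteofea:::sample_tet_hu(mesh, vol)
  expect_length(hu, nrow(mesh$tets))
  expect_true(all(hu >= 80 & hu <= 120))
})
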