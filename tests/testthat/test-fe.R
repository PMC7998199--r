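test_that("the elastic cuboid matches the closed-form bar solution", {
  mesh <- cuboid_mesh(4, 4, 8, spacing = 1)
  E <- 1000; A <- 16; L <- 8
  prog <- load_program(0.04, 4)
  cv <- solve_compression(assemble_homogeneous(mesh, E, nu = 0, prog))
  expect_equal(cv$force[1], 0)
  expect_equal(cv$force[-1], E * A * prog / L, tolerance = 1e-8)
  # linearity: doubling the modulus doubles the reaction
  cv2 <- solve_compression(assemble_homogeneous(mesh, 2 * E, nu = 0, prog))
  expect_equal(cv2$force, 2 * cv$force, tolerance = 1e-10)
  # equilibrium: reactions on fixed and driven surfaces cancel
  expect_lt(attr(cv, "force_balance"), 1e-6)
})

test_that("solves are bit-identical across repeated runs", {
  mesh <- cuboid_mesh(3, 3, 5)
  mdl <- assemble_homogeneous(mesh, 500, 0.3, load_program(0.05, 5))
  expect_identical(solve_compression(mdl)$force, solve_compression(mdl)$force)
})

test_that("model assembly enforces its boundary-condition contracts", {
  mesh <- cuboid_mesh(3, 3, 5)
  cards <- material_cards(rep(150, nrow(mesh$tets)))
  mdl <- assemble_single_vertebra(mesh, cards, load_program(0.05, 10))
  expect_length(intersect(mdl$fixed_nodes, mdl$driven_nodes), 0)
  expect_length(mdl$program, 10)
  cv <- solve_compression(mdl, stop_ratio = 0)  # full schedule, no early stop
  expect_equal(nrow(cv), 11)
  expect_error(load_program(-1, 5), "u_max > 0")
  expect_error(assemble_single_vertebra(
    mask_to_tet_mesh(cuboid_labels(3, 3, 1), 1), cards[1:54, ],
    load_program(0.05, 5)), "flat")
})

test_that("a two-region stack with one material behaves as a single block", {
  arr <- array(0L, dim = c(3, 3, 6))
  arr[, , 1:3] <- 1L; arr[, , 4:6] <- 2L
  lv <- label_volume(arr)
  prog <- load_program(0.03, 3)
  whole <- solve_compression(assemble_homogeneous(
    mask_to_tet_mesh(label_volume(array(1L, c(3, 3, 6))), 1), 800, 0.2, prog))
  mg <- osteofea:::merge_meshes(list(mask_to_tet_mesh(lv, 1),
                                     mask_to_tet_mesh(lv, 2)))
  stacked <- solve_compression(assemble_homogeneous(mg$mesh, 800, 0.2, prog))
  expect_equal(stacked$force, whole$force, tolerance = 1e-10)
})

test_that("FSU assembly ties conforming interfaces and rejects detached ones", {
  ph <- generate_fsu_phantom(small_spec(), 3)
  vm <- lapply(1:3, function(v)
    extract_surface_sets(mask_to_tet_mesh(ph$labels, c(v, 100 + v))))
  dm <- lapply(1:2, function(j)
    list(annulus = mask_to_tet_mesh(ph$labels, 300 + j),
         nucleus = mask_to_tet_mesh(ph$labels, 400 + j)))
  vc <- lapply(vm, function(m) assign_element_materials(m, ph$ct))
  mdl <- assemble_fsu(vm, dm, vc, load_program(0.1, 2))
  n_regions <- sum(vapply(vm, function(m) nrow(m$nodes), 0)) +
    sum(vapply(dm, function(d) nrow(d$annulus$nodes) + nrow(d$nucleus$nodes), 0))
  expect_lt(nrow(mdl$nodes), n_regions)  # interfaces merged
  expect_equal(nrow(mdl$tets),
               sum(vapply(vm, function(m) nrow(m$tets), 0)) +
               sum(vapply(dm, function(d) nrow(d$annulus$tets) +
                                          nrow(d$nucleus$tets), 0)))
  # detached disc: translate one disc far away -> non-conforming
  dm_bad <- dm
  dm_bad[[1]]$annulus$nodes <- dm_bad[[1]]$annulus$nodes + 1000
  dm_bad[[1]]$annulus$corner_key <- NULL
  dm_bad[[1]]$nucleus$nodes <- dm_bad[[1]]$nucleus$nodes + 1000
  dm_bad[[1]]$nucleus$corner_key <- NULL
  expect_error(assemble_fsu(vm, dm_bad, vc, load_program(0.1, 2)),
               "not connected to the vertebrae")
})

test_that("yielding produces a load peak and softening on dense programs", {
  ph <- generate_vertebra_phantom(small_spec())
  mesh <- extract_surface_sets(mask_to_tet_mesh(ph$labels, c(1, 101)))
  cards <- assign_element_materials(mesh, ph$ct)
  cv <- solve_compression(assemble_single_vertebra(
    mesh, cards, load_program(0.015 * 10, 15)))
  fl <- extract_failure(cv)
  expect_false(fl$no_softening)
  expect_gt(fl$failure_load, 0)
  expect_lt(fl$failure_displacement, max(cv$displacement) + 1e-12)
  expect_equal(fl$failure_load, max(cv$force))
})

test_that("failure extraction follows the peak rule with tie-breaking", {
  cv <- data.frame(displacement = c(0, .1, .2, .3, .4),
                   force = c(0, 10, 25, 22, 18))
  fl <- extract_failure(cv, "fixture")
  expect_equal(fl$failure_load, 25)
  expect_equal(fl$failure_displacement, 0.2)
  expect_false(fl$no_softening)
  # strictly increasing: last point, flagged
  inc <- data.frame(displacement = c(0, .1, .2), force = c(0, 5, 9))
  expect_true(extract_failure(inc)$no_softening)
  expect_equal(extract_failure(inc)$failure_load, 9)
  # tie at the peak: earliest displacement wins
  tie <- data.frame(displacement = c(0, .1, .2, .3), force = c(0, 7, 7, 3))
  expect_equal(extract_failure(tie)$failure_displacement, 0.1)
  expect_error(extract_failure(data.frame()), "empty")
})
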