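test_that("a unit voxel decomposes into 6 conforming positive tets", {
  mesh <- mask_to_tet_mesh(cuboid_labels(1, 1, 1, spacing = 1), 1)
  expect_equal(nrow(mesh$tets), 6)
  vols <- osteofea:::tet_volumes(mesh)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 1)
})

test_that("mesh volume equals the labelled voxel volume", {
  for (dims in list(c(3, 2, 4), c(5, 5, 2))) {
    lv <- cuboid_labels(dims[1], dims[2], dims[3], spacing = 1.3)
    mesh <- mask_to_tet_mesh(lv, 1)
    nvox <- prod(dims)
    expect_equal(nrow(mesh$tets), 6 * nvox)
    expect_equal(sum(osteofea:::tet_volumes(mesh)), nvox * 1.3^3,
                 tolerance = 1e-9)
  }
  expect_error(mask_to_tet_mesh(cuboid_labels(2, 2, 2), 9), "no voxels")
})

test_that("loading surface sets match the structured grid", {
  k <- 4
  mesh <- cuboid_mesh(k, k, 6)
  expect_length(mesh$node_sets$superior_surface, (k + 1)^2)
  expect_length(mesh$node_sets$inferior_surface, (k + 1)^2)
  expect_length(intersect(mesh$node_sets$superior_surface,
                          mesh$node_sets$inferior_surface), 0)
  # equivariance: shifting the volume origin translates the sets' nodes only
  lv <- cuboid_labels(k, k, 6)
  lv$origin <- c(5, -3, 10)
  shifted <- extract_surface_sets(mask_to_tet_mesh(lv, 1))
  expect_equal(shifted$node_sets, mesh$node_sets)
  expect_error(extract_surface_sets(mask_to_tet_mesh(cuboid_labels(3, 3, 1), 1)),
               "flat")
})

test_that("adjacent regions mesh conformly and merge node-for-node", {
  arr <- array(0L, dim = c(3, 3, 6))
  arr[, , 1:3] <- 1L
  arr[, , 4:6] <- 2L
  lv <- label_volume(arr)
  m1 <- mask_to_tet_mesh(lv, 1)
  m2 <- mask_to_tet_mesh(lv, 2)
  mg <- osteofea:::merge_meshes(list(m1, m2))
  expect_equal(mg$n_duplicates, 16)  # (3+1)^2 shared interface nodes
  expect_equal(nrow(mg$mesh$nodes), nrow(m1$nodes) + nrow(m2$nodes) - 16)
  expect_equal(sum(osteofea:::tet_volumes(mg$mesh)), 3 * 3 * 6)
})

test_that("quality metrics reflect the translational symmetry of the grid", {
  q <- mesh_quality(mask_to_tet_mesh(cuboid_labels(3, 3, 3), 1))
  expect_equal(q$volume, 27)
  expect_equal(q$aspect_min, q$aspect_mean)
  expect_gt(q$min_dihedral_deg, 0)
  expect_gt(q$min_tet_volume, 0)
})

test_that("mesh exports write inspectable text decks", {
  mesh <- cuboid_mesh(2, 2, 3)
  inp <- tempfile(fileext = ".inp")
  vtk <- tempfile(fileext = ".vtk")
  write_inp(mesh, inp)
  write_vtk(mesh, vtk, cell_data = list(ez = seq_len(nrow(mesh$tets))))
  expect_true(any(grepl("^\\*Element, type=C3D4", readLines(inp))))
  expect_true(any(grepl("CELL_TYPES", readLines(vtk))))
  unlink(c(inp, vtk))
})
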