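# Shared fixtures: a compact phantom geometry that keeps meshes small enough
# for repeated FE solves, and a cuboid label volume for analytic oracles.

small_spec <- function(...) {
  args <- utils::modifyList(
    list(half_axes = c(8, 6), body_height = 10, shell_thickness = 1.6,
         ivd_height = 4, spacing = 2, noise_sd = 0, seed = 1L),
    list(...))
  do.call(phantom_spec, args)
}

cuboid_labels <- function(nx = 4, ny = 4, nz = 8, spacing = 1) {
  label_volume(array(1L, dim = c(nx, ny, nz)), spacing = spacing)
}

cuboid_mesh <- function(nx = 4, ny = 4, nz = 8, spacing = 1) {
  extract_surface_sets(mask_to_tet_mesh(cuboid_labels(nx, ny, nz, spacing), 1))
}
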