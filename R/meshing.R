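# Structured tetrahedral meshing of label volumes.  Every labelled voxel is
# split into 6 tetrahedra by the Kuhn decomposition around the voxel's main
# diagonal; the decomposition is translation-invariant, so faces shared by
# adjacent voxels (and by adjacent regions of the same grid) are triangulated
# identically and the meshes conform node-for-node.  Mesh volume equals the
# labelled voxel volume exactly.

# Kuhn decomposition of the unit cube: one tet per permutation of the axis
# step order, all sharing the main diagonal (0,0,0)-(1,1,1).  Rows are local
# corner indices into the 8 voxel corners ordered by (dx, dy, dz) bits with
# dx fastest: corner index = 1 + dx + 2*dy + 4*dz.
kuhn_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  step <- c(1L, 2L, 4L)  # corner-index increment for a step along x, y, z
  out <- matrix(0L, 6, 4)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    v <- c(1L, 0L, 0L, 0L)
    v[2] <- v[1] + step[p[1]]
    v[3] <- v[2] + step[p[2]]
    v[4] <- v[3] + step[p[3]]
    # odd permutations give negative volume; swap last two nodes to fix
    sgn <- sign(det(diag(3)[p, ]))
    out[t, ] <- if (sgn > 0) v else v[c(1, 2, 4, 3)]
  }
  out
}

#' Tetrahedral mesh of a labelled region
#'
#' Decomposes every voxel carrying one of `label_ids` into 6 conforming
#' tetrahedra.  Node coordinates are voxel-corner world coordinates; each
#' tetrahedron records its parent voxel so material sampling can use the
#' voxel attenuation directly.
#'
#' @param labels a [label_volume()].
#' @param label_ids one or more label ids forming the region.
#' @param region_tag tag stored on the mesh (defaults to the first id).
#' @return An object of class `ofea_mesh`: list with `nodes` (n x 3, mm),
#'   `tets` (m x 4, 1-based, positively oriented), `region_tag`, `voxel_id`
#'   (parent voxel linear index per tet), `corner_key` (global grid corner id
#'   per node, used for conforming assembly), `spacing`, and `node_sets`.
#' @export
mask_to_tet_mesh <- function(labels, label_ids, region_tag = label_ids[1]) {
  stopifnot(inherits(labels, "label_volume"))
  mask <- labels$data %in% as.integer(label_ids)
  vox <- which(mask)
  if (length(vox) == 0) stop("no voxels carry label(s) ", paste(label_ids, collapse = ","))
  dm <- dim(labels$data)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  ijk <- arrayInd(vox, dm)  # 1-based voxel indices

  # global corner grid: (nx+1) x (ny+1) x (nz+1), linear id with x fastest
  cnx <- nx + 1L; cny <- ny + 1L
  corner0 <- (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * cnx +
    (ijk[, 3] - 1L) * cnx * cny + 1L
  off <- integer(8)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    off[1 + dx + 2 * dy + 4 * dz] <- dx + dy * cnx + dz * cnx * cny
  corners <- outer(corner0, off, "+")  # nvox x 8 global corner ids

  kt <- kuhn_tets()
  nvox <- length(vox)
  tets_g <- matrix(0L, 6L * nvox, 4L)
  for (t in 1:6)
    tets_g[seq.int(t, by = 6L, length.out = nvox), ] <- corners[, kt[t, ], drop = FALSE]
  voxel_id <- rep(vox, each = 6L)

  used <- sort(unique(as.vector(tets_g)))
  tets <- matrix(match(tets_g, used), ncol = 4L)

  u0 <- used - 1L
  ci <- u0 %% cnx
  cj <- (u0 %/% cnx) %% cny
  ck <- u0 %/% (cnx * cny)
  nodes <- cbind(labels$origin[1] + ci * labels$spacing[1],
                 labels$origin[2] + cj * labels$spacing[2],
                 labels$origin[3] + ck * labels$spacing[3])
  colnames(nodes) <- c("x", "y", "z")

  structure(list(nodes = nodes, tets = tets,
                 region_tag = as.integer(region_tag),
                 voxel_id = voxel_id, corner_key = used,
                 spacing = labels$spacing, node_sets = list()),
            class = "ofea_mesh")
}

#' @export
print.ofea_mesh <- function(x, ...) {
  cat(sprintf("<ofea_mesh> region %d: %d nodes, %d tets, volume %.3f mm^3\n",
              x$region_tag, nrow(x$nodes), nrow(x$tets), sum(tet_volumes(x))))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

# Signed volumes of all tets (positive for valid orientation).
tet_volumes <- function(mesh) {
  n <- mesh$nodes; tt <- mesh$tets
  a <- n[tt[, 2], , drop = FALSE] - n[tt[, 1], , drop = FALSE]
  b <- n[tt[, 3], , drop = FALSE] - n[tt[, 1], , drop = FALSE]
  d <- n[tt[, 4], , drop = FALSE] - n[tt[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Extract loading surface node sets
#'
#' Adds `inferior_surface` (nodes within half a voxel of the minimal Z
#' coordinate) and `superior_surface` (maximal Z) to the mesh's node sets.
#' These are the fixed and displacement-driven sets of the compression
#' models.
#'
#' @param mesh an `ofea_mesh`.
#' @return the mesh with populated `node_sets`.
#' @export
extract_surface_sets <- function(mesh) {
  stopifnot(inherits(mesh, "ofea_mesh"))
  z <- mesh$nodes[, 3]
  half <- mesh$spacing[3] / 2
  if (diff(range(z)) <= mesh$spacing[3])
    stop("mesh is flat along Z; cannot define loading surfaces")
  inf_set <- which(z <= min(z) + half)
  sup_set <- which(z >= max(z) - half)
  mesh$node_sets$inferior_surface <- inf_set
  mesh$node_sets$superior_surface <- sup_set
  mesh
}

#' Mesh quality metrics
#'
#' Reports element volumes and shape measures: min/mean edge-length aspect
#' ratio (longest/shortest edge per tet), the minimum dihedral angle over all
#' elements (degrees), and total volume.
#'
#' @param mesh an `ofea_mesh`.
#' @return list with `n_nodes`, `n_tets`, `volume`, `min_tet_volume`,
#'   `aspect_min`, `aspect_mean`, `min_dihedral_deg`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "ofea_mesh"))
  n <- mesh$nodes; tt <- mesh$tets
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  el <- sapply(seq_len(6), function(p) {
    d <- n[tt[, pairs[p, 1]], , drop = FALSE] - n[tt[, pairs[p, 2]], , drop = FALSE]
    sqrt(rowSums(d^2))
  })
  if (is.null(dim(el))) el <- matrix(el, nrow = 1)
  aspect <- apply(el, 1, max) / apply(el, 1, min)
  vols <- tet_volumes(mesh)

  # minimum dihedral angle: angle between faces sharing each edge
  min_dih <- 180
  face_of_edge <- list(c(3, 4), c(2, 4), c(2, 3), c(1, 4), c(1, 3), c(1, 2))
  faces <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  normals <- lapply(1:4, function(f) {
    a <- n[tt[, faces[f, 2]], , drop = FALSE] - n[tt[, faces[f, 1]], , drop = FALSE]
    b <- n[tt[, faces[f, 3]], , drop = FALSE] - n[tt[, faces[f, 1]], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    # orient outward: away from the opposite vertex f
    to_face <- n[tt[, faces[f, 1]], , drop = FALSE] - n[tt[, f], , drop = FALSE]
    nrm * sign(rowSums(nrm * to_face))
  })
  for (e in 1:6) {
    f <- face_of_edge[[e]]
    cosang <- rowSums(normals[[f[1]]] * normals[[f[2]]])
    dih <- acos(pmin(pmax(-cosang, -1), 1)) * 180 / pi
    min_dih <- min(min_dih, min(dih))
  }
  list(n_nodes = nrow(n), n_tets = nrow(tt), volume = sum(vols),
       min_tet_volume = min(vols), aspect_min = min(aspect),
       aspect_mean = mean(aspect), min_dihedral_deg = min_dih)
}

# Merge a list of conforming region meshes into one node-shared mesh.
# Nodes are identified by their global grid corner key (exact), falling back
# to coordinates rounded to `tol` when keys are unavailable.  Returns the
# merged mesh plus, per region, the map from local to merged node indices.
merge_meshes <- function(meshes, tol = 1e-6) {
  keys <- lapply(meshes, function(m) {
    if (!is.null(m$corner_key)) as.character(m$corner_key)
    else apply(round(m$nodes / tol) * tol, 1, paste, collapse = "_")
  })
  all_keys <- unlist(keys, use.names = FALSE)
  uk <- unique(all_keys)
  maps <- lapply(keys, match, uk)

  nodes <- matrix(NA_real_, length(uk), 3)
  for (i in seq_along(meshes)) nodes[maps[[i]], ] <- meshes[[i]]$nodes
  colnames(nodes) <- c("x", "y", "z")

  tets <- do.call(rbind, lapply(seq_along(meshes), function(i)
    matrix(maps[[i]][meshes[[i]]$tets], ncol = 4)))
  region <- rep(seq_along(meshes), vapply(meshes, function(m) nrow(m$tets), 0L))
  voxel_id <- unlist(lapply(meshes, function(m)
    if (is.null(m$voxel_id)) rep(NA_integer_, nrow(m$tets)) else m$voxel_id))

  merged <- structure(list(nodes = nodes, tets = tets,
                           region_tag = NA_integer_, voxel_id = voxel_id,
                           corner_key = NULL, spacing = meshes[[1]]$spacing,
                           node_sets = list(), region = region),
                      class = "ofea_mesh")
  list(mesh = merged, node_maps = maps,
       n_duplicates = length(all_keys) - length(uk))
}

#' Write a mesh as a legacy ASCII VTK file
#'
#' @param mesh an `ofea_mesh`.
#' @param path output `.vtk` path.
#' @param cell_data optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "osteofea mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a mesh as a minimal Abaqus-style input deck
#'
#' Nodes, C3D4 elements and any node sets, for external inspection.
#'
#' @param mesh an `ofea_mesh`.
#' @param path output `.inp` path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*Node", con)
  writeLines(sprintf("%d, %g, %g, %g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*Element, type=C3D4", con)
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  for (nm in names(mesh$node_sets)) {
    writeLines(sprintf("*Nset, nset=%s", nm), con)
    idx <- mesh$node_sets[[nm]]
    for (chunk in split(idx, ceiling(seq_along(idx) / 12)))
      writeLines(paste(chunk, collapse = ", "), con)
  }
  invisible(path)
}
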