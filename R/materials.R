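# HU -> density -> elasticity/strength mapping for vertebral bone, and the
# fixed isotropic properties of the intervertebral disc regions.  Bone is
# transversely isotropic about the cranio-caudal (Z) axis: the in-plane
# moduli, shear moduli and Poisson ratios are fixed fractions of the axial
# modulus E_z, so each element's stiffness is a scalar multiple of one unit
# stiffness matrix.

#' Apparent density from attenuation
#'
#' `rho_app = 47 + 1.122 * HU` (kg/m^3).
#'
#' @param hu attenuation (HU).
#' @return apparent density, kg/m^3.
#' @export
hu_to_apparent_density <- function(hu) 47 + 1.122 * hu

#' Ash density from apparent density
#'
#' `rho_ash = 0.6 * rho_app` (kg/m^3).
#'
#' @param rho_app apparent density, kg/m^3.
#' @return ash density, kg/m^3.
#' @export
apparent_to_ash <- function(rho_app) 0.6 * rho_app

#' Transversely isotropic elastic constants from apparent density
#'
#' Axial modulus `E_z = -349 + 5.82 * rho_app` (MPa), floored at a small
#' positive value so that the element stiffness stays positive definite at
#' very low densities; in-plane moduli `E_x = E_y = 0.333 E_z`, shear moduli
#' `G_xy = 0.121 E_z`, `G_xz = G_yz = 0.157 E_z`, Poisson ratios
#' `nu_xy = 0.381`, `nu_xz = nu_yz = 0.104`.
#'
#' @param rho_app apparent density, kg/m^3 (vectorised).
#' @param floor minimum axial modulus, MPa (> 0).
#' @return data.frame with columns `E_z`, `E_x`, `E_y`, `G_xy`, `G_xz`,
#'   `G_yz`, `nu_xy`, `nu_xz`, `nu_yz`.
#' @export
elastic_constants <- function(rho_app, floor = 0.01) {
  if (floor <= 0) stop("modulus floor must be positive")
  e_z <- pmax(-349 + 5.82 * rho_app, floor)
  data.frame(
    E_z = e_z, E_x = 0.333 * e_z, E_y = 0.333 * e_z,
    G_xy = 0.121 * e_z, G_xz = 0.157 * e_z, G_yz = 0.157 * e_z,
    nu_xy = 0.381, nu_xz = 0.104, nu_yz = 0.104
  )
}

#' Strength limits and plastic strain from ash density
#'
#' Piecewise power law for the maximum principal stress limit,
#' `sigma = 137 * rho_ash^1.88` below the branch point 0.317 g/cm^3 and
#' `sigma = 114 * rho_ash^1.72` above it (the branch point itself uses the
#' high-density branch; the two branches agree there to < 0.1 MPa); power law
#' `sigma_min = 65.1 * rho_ash^1.93` for the minimum principal stress limit;
#' affine plastic strain `eps_AB = -0.00315 + 0.0728 * rho_ash`.  All laws
#' take ash density in g/cm^3, the unit in which the 0.317 threshold is
#' meaningful (divide a kg/m^3 value by 1000).
#'
#' @param rho_ash_cgs ash density in g/cm^3 (vectorised, >= 0).
#' @return data.frame with columns `sigma_max`, `sigma_min` (MPa) and
#'   `eps_plastic` (dimensionless).
#' @export
strength_limits <- function(rho_ash_cgs) {
  if (any(rho_ash_cgs < 0)) stop("ash density must be >= 0")
  sigma_max <- ifelse(rho_ash_cgs < 0.317,
                      137 * rho_ash_cgs^1.88,
                      114 * rho_ash_cgs^1.72)
  data.frame(
    sigma_max = sigma_max,
    sigma_min = 65.1 * rho_ash_cgs^1.93,
    eps_plastic = -0.00315 + 0.0728 * rho_ash_cgs
  )
}

#' Full material card chain from attenuation
#'
#' Applies the complete mapping HU -> apparent density -> ash density ->
#' elastic constants and strength limits, one row per input value.
#'
#' @param hu attenuation values (HU).
#' @param floor minimum axial modulus, MPa.
#' @return data.frame of material cards: densities (`rho_app`, `rho_ash_si`
#'   in kg/m^3, `rho_ash_cgs` in g/cm^3), elastic constants and strength
#'   limits.
#' @export
material_cards <- function(hu, floor = 0.01) {
  rho_app <- hu_to_apparent_density(hu)
  rho_ash_si <- apparent_to_ash(rho_app)
  rho_ash_cgs <- rho_ash_si / 1000
  out <- cbind(
    data.frame(hu = hu, rho_app = rho_app,
               rho_ash_si = rho_ash_si, rho_ash_cgs = rho_ash_cgs),
    elastic_constants(rho_app, floor),
    strength_limits(pmax(rho_ash_cgs, 0))
  )
  attr(out, "floor") <- floor
  out
}

#' Intervertebral disc material constants
#'
#' Isotropic linear-elastic constants of the disc regions: annulus
#' `E = 500` MPa, `nu = 0.3`; nucleus `E = 1` MPa, `nu = 0.475`.  No strength
#' limits are assigned to disc tissue.
#'
#' @param region `"annulus"` or `"nucleus"`.
#' @return list with elements `region`, `E` (MPa), `nu`.
#' @export
ivd_material <- function(region = c("annulus", "nucleus")) {
  region <- match.arg(region)
  if (region == "annulus") list(region = region, E = 500, nu = 0.3)
  else list(region = region, E = 1, nu = 0.475)
}

# 6x6 stiffness (Voigt order xx, yy, zz, yz, xz, xy; engineering shear) of
# transversely isotropic bone with unit axial modulus; element stiffness is
# E_z times this.  Engineering-constant convention: S_ij = -nu_ij / E_i.
bone_unit_stiffness <- function() {
  e <- elastic_constants(0, floor = 1)  # floored to E_z = 1: ratio structure
  S <- diag(c(1 / e$E_x, 1 / e$E_y, 1 / e$E_z,
              1 / e$G_yz, 1 / e$G_xz, 1 / e$G_xy))
  S[1, 2] <- S[2, 1] <- -e$nu_xy / e$E_x
  S[1, 3] <- S[3, 1] <- -e$nu_xz / e$E_x
  S[2, 3] <- S[3, 2] <- -e$nu_yz / e$E_y
  solve(S)
}

# Isotropic 6x6 stiffness (same Voigt order).
iso_stiffness <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3][diag(3) == 0] <- lam
  C
}

#' Assign material cards to mesh elements from an image volume
#'
#' Samples the attenuation of each tetrahedron and maps it through
#' [material_cards()].  For structured voxel meshes (from
#' [mask_to_tet_mesh()]) each element inherits the HU of its parent voxel,
#' which equals the mean over voxel centers contained in the element; for
#' general meshes the mean of voxel centers strictly inside each element is
#' used, falling back to trilinear interpolation at the element centroid when
#' no center falls inside.
#'
#' @param mesh a mesh from [mask_to_tet_mesh()].
#' @param volume the [ct_volume()] the mesh is embedded in.
#' @param floor minimum axial modulus, MPa.
#' @return data.frame of per-element material cards (one row per
#'   tetrahedron).
#' @export
assign_element_materials <- function(mesh, volume, floor = 0.01) {
  stopifnot(inherits(mesh, "ofea_mesh"), inherits(volume, "ct_volume"))
  lim <- dim(volume$data) * volume$spacing + volume$origin
  if (any(mesh$nodes < matrix(volume$origin - 1e-9, nrow(mesh$nodes), 3, byrow = TRUE)) ||
      any(mesh$nodes > matrix(lim + 1e-9, nrow(mesh$nodes), 3, byrow = TRUE)))
    stop("mesh extends outside the image volume")
  hu <- if (!is.null(mesh$voxel_id)) {
    as.numeric(volume$data[mesh$voxel_id])
  } else {
    sample_tet_hu(mesh, volume)
  }
  material_cards(hu, floor)
}

# Generic HU sampling: mean of voxel centers inside each tet (inclusive
# faces), trilinear at the centroid as fallback.
sample_tet_hu <- function(mesh, volume) {
  m <- nrow(mesh$tets)
  hu <- numeric(m)
  sp <- volume$spacing; orig <- volume$origin; dm <- dim(volume$data)
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$tets[e, ], ]
    lo <- pmax(ceiling((apply(X, 2, min) - orig) / sp + 0.5), 1)
    hi <- pmin(floor((apply(X, 2, max) - orig) / sp + 0.5), dm)
    vals <- NULL
    if (all(lo <= hi)) {
      g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
      ctr <- sweep(sweep(g - 0.5, 2, sp, "*"), 2, orig, "+")
      inside <- in_tet(ctr, X)
      if (any(inside)) vals <- volume$data[g[inside, , drop = FALSE]]
    }
    hu[e] <- if (!is.null(vals)) mean(vals)
             else trilinear_at(colMeans(X), volume)
  }
  hu
}

# Barycentric point-in-tet test, inclusive within tolerance.
in_tet <- function(P, X, tol = 1e-9) {
  M <- t(X[2:4, , drop = FALSE]) - X[1, ]
  b <- t(solve(M, t(P) - X[1, ]))
  b4 <- 1 - rowSums(b)
  rowSums(b < -tol) == 0 & b4 >= -tol
}

trilinear_at <- function(p, volume) {
  sp <- volume$spacing; orig <- volume$origin; dm <- dim(volume$data)
  f <- (p - orig) / sp + 0.5
  i0 <- pmin(pmax(floor(f), 1), dm - 1)
  w <- pmin(pmax(f - i0, 0), 1)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    acc <- acc + wt * volume$data[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  acc
}

#' Export material cards as an Abaqus-style material block
#'
#' Writes one `*Material` block per element card (engineering-constant
#' elasticity), for external inspection of the mapped properties.
#'
#' @param cards data.frame from [material_cards()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_material_inp <- function(cards, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cards))) {
    r <- cards[i, ]
    writeLines(c(
      sprintf("*Material, name=MAT-%d", i),
      "*Elastic, type=ENGINEERING CONSTANTS",
      sprintf("%g, %g, %g, %g, %g, %g, %g, %g",
              r$E_x, r$E_y, r$E_z, r$nu_xy, r$nu_xz, r$nu_yz,
              r$G_xy, r$G_xz),
      sprintf("%g", r$G_yz)
    ), con)
  }
  invisible(path)
}
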