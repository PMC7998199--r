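# Synthetic CT phantoms: elliptic-cylinder vertebral bodies (cortical shell +
# trabecular core), optional posterior elements, intervertebral discs split
# into annulus and nucleus, and a two-compartment calibration insert rendered
# into the same volume.  All geometry is analytic so labelled volumes can be
# checked against closed-form solid volumes.

#' Label ids used by the phantom generator
#'
#' Returns the label scheme for a stack of `n_vertebrae` bodies:
#' trabecular compartments are `1..n`, cortical shells `100 + (1..n)`,
#' posterior elements `200 + (1..n)`, disc annuli `300 + (1..n-1)`,
#' disc nuclei `400 + (1..n-1)`, and the calibration phantom water and bone
#' compartments 901 and 902.
#'
#' @param n_vertebrae number of vertebral bodies in the stack.
#' @return named list of integer label vectors.
#' @export
phantom_labels <- function(n_vertebrae = 1) {
  k <- seq_len(n_vertebrae)
  j <- seq_len(max(n_vertebrae - 1, 0))
  list(
    trabecular = k,
    cortical = 100L + k,
    posterior = 200L + k,
    annulus = if (length(j)) 300L + j else integer(0),
    nucleus = if (length(j)) 400L + j else integer(0),
    phantom_water = 901L,
    phantom_bone = 902L
  )
}

#' Phantom geometry and appearance specification
#'
#' Describes one synthetic vertebra (and, for stacks, the discs between
#' bodies).  The vertebral body is an elliptic cylinder of half-axes
#' `half_axes` (X = left-right, Y = anterior-posterior) and height
#' `body_height` along the cranio-caudal Z axis, with a cortical shell of
#' thickness `shell_thickness` and a trabecular core.  Discs share the body
#' cross-section; the nucleus is a central circular cylinder whose radius is
#' `nucleus_radius_fraction` of the smaller half-axis.  Attenuation is
#' piecewise constant plus optional additive white Gaussian noise.
#'
#' @param half_axes in-plane half-axes of the body (mm), length 2.
#' @param body_height body height (mm).
#' @param shell_thickness cortical shell thickness (mm).
#' @param posterior_elements render a simplified rectangular posterior arch?
#' @param ivd_height disc height (mm); must be positive for stacks.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the smaller
#'   half-axis, in (0, 1).
#' @param trabecular_hu,cortical_hu,ivd_hu,background_hu noiseless attenuation
#'   of each compartment (HU).
#' @param noise_sd standard deviation of additive Gaussian noise (HU); 0
#'   disables noise.
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(half_axes = c(15, 11), body_height = 22,
                         shell_thickness = 1.5, posterior_elements = TRUE,
                         ivd_height = 6, nucleus_radius_fraction = 0.5,
                         trabecular_hu = 120, cortical_hu = 600,
                         ivd_hu = 60, background_hu = -50,
                         noise_sd = 10, spacing = 1, seed = 1L) {
  half_axes <- rep_len(as.numeric(half_axes), 2)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(c(half_axes, body_height, shell_thickness, ivd_height, spacing) <= 0))
    stop("all phantom lengths must be positive")
  if (nucleus_radius_fraction <= 0 || nucleus_radius_fraction >= 1)
    stop("nucleus_radius_fraction must lie in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (shell_thickness >= min(half_axes))
    stop("cortical shell thicker than the body half-axes")
  structure(list(
    half_axes = half_axes, body_height = body_height,
    shell_thickness = shell_thickness,
    posterior_elements = isTRUE(posterior_elements),
    ivd_height = ivd_height,
    nucleus_radius_fraction = nucleus_radius_fraction,
    trabecular_hu = trabecular_hu, cortical_hu = cortical_hu,
    ivd_hu = ivd_hu, background_hu = background_hu,
    noise_sd = noise_sd, spacing = spacing, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a single-vertebra CT phantom
#'
#' Renders one vertebral body plus the two calibration-phantom compartments
#' (cylindrical inserts posterior to the body, spanning the full stack
#' height) into an HU volume and a matching label volume.
#'
#' @param spec a [phantom_spec()].
#' @param calib a [calibration_phantom()]; its `hu_water` / `hu_bone` are the
#'   noiseless attenuations of the insert compartments.
#' @param seed optional override of `spec$seed`.
#' @return list with elements `ct` ([ct_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_vertebra_phantom <- function(spec, calib = calibration_phantom(),
                                      seed = NULL) {
  generate_fsu_phantom(spec, n_vertebrae = 1L, calib = calib, seed = seed)
}

#' Generate a stacked functional-spinal-unit phantom
#'
#' Stacks `n_vertebrae` vertebral bodies separated by `n_vertebrae - 1`
#' intervertebral discs, each disc split into an outer annulus and a central
#' nucleus label.  Per-vertebra trabecular attenuation can be overridden to
#' render bodies at prescribed densities (used by [simulate_cohort()]).
#'
#' @inheritParams generate_vertebra_phantom
#' @param n_vertebrae number of bodies (>= 1).
#' @param trabecular_hu optional vector of per-vertebra trabecular HU,
#'   recycled to `n_vertebrae`; defaults to `spec$trabecular_hu`.
#' @return list with elements `ct` and `labels`.
#' @export
generate_fsu_phantom <- function(spec, n_vertebrae = 3L,
                                 calib = calibration_phantom(),
                                 trabecular_hu = NULL, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_vertebrae >= 1)
  n_vertebrae <- as.integer(n_vertebrae)
  tb_hu <- rep_len(if (is.null(trabecular_hu)) spec$trabecular_hu
                   else as.numeric(trabecular_hu), n_vertebrae)
  labs <- phantom_labels(n_vertebrae)
  sx <- spec$spacing[1]; sy <- spec$spacing[2]; sz <- spec$spacing[3]
  ax <- spec$half_axes[1]; ay <- spec$half_axes[2]

  margin <- 2 * max(spec$spacing)          # clearance around all solids
  post_depth <- if (spec$posterior_elements) 0.4 * ay else 0
  r_ins <- 4                               # calibration insert radius, mm
  gap_ins <- margin                        # body/arch to insert clearance

  stack_h <- n_vertebrae * spec$body_height +
    (n_vertebrae - 1) * spec$ivd_height
  ext_x <- 2 * ax + 2 * margin
  ext_y <- 2 * ay + post_depth + gap_ins + 2 * r_ins + 2 * margin
  ext_z <- stack_h + 2 * margin
  nx <- ceiling(ext_x / sx); ny <- ceiling(ext_y / sy); nz <- ceiling(ext_z / sz)
  if (nx * ny * nz > 5e7) stop("phantom grid too large; coarsen spacing")

  cx <- margin + ax                        # body centre (world mm)
  cy <- margin + ay
  z0 <- margin                             # stack base

  xc <- (seq_len(nx) - 0.5) * sx
  yc <- (seq_len(ny) - 0.5) * sy
  zc <- (seq_len(nz) - 0.5) * sz

  hu <- array(spec$background_hu, dim = c(nx, ny, nz))
  lab <- array(0L, dim = c(nx, ny, nz))

  # in-plane masks (nx x ny), reused for every body / disc
  XY_x <- matrix(xc, nx, ny) - cx
  XY_y <- matrix(yc, nx, ny, byrow = TRUE) - cy
  ell_out <- (XY_x / ax)^2 + (XY_y / ay)^2 <= 1
  t <- spec$shell_thickness
  ell_in <- (XY_x / (ax - t))^2 + (XY_y / (ay - t))^2 <= 1
  r_nuc <- spec$nucleus_radius_fraction * min(ax, ay)
  nuc <- XY_x^2 + XY_y^2 <= r_nuc^2
  post <- if (spec$posterior_elements) {
    abs(XY_x) <= ax / 2 & XY_y > ay & XY_y <= ay + post_depth
  } else matrix(FALSE, nx, ny)

  paint <- function(mask_xy, z_sel, value, label) {
    ij <- which(mask_xy)
    for (k in which(z_sel)) {
      pg <- ij + (k - 1L) * nx * ny
      hu[pg] <<- value
      lab[pg] <<- label
    }
  }

  for (v in seq_len(n_vertebrae)) {
    zb <- z0 + (v - 1) * (spec$body_height + spec$ivd_height)
    zsel <- zc > zb & zc < zb + spec$body_height
    paint(ell_out & !ell_in, zsel, spec$cortical_hu, labs$cortical[v])
    paint(ell_in, zsel, tb_hu[v], labs$trabecular[v])
    if (spec$posterior_elements)
      paint(post, zsel, spec$cortical_hu, labs$posterior[v])
    if (v < n_vertebrae) {
      zd <- zb + spec$body_height
      dsel <- zc > zd & zc < zd + spec$ivd_height
      paint(ell_out & !nuc, dsel, spec$ivd_hu, labs$annulus[v])
      paint(nuc, dsel, spec$ivd_hu, labs$nucleus[v])
    }
  }

  # calibration inserts: cylinders along Z, posterior to the arch
  y_ins <- cy + ay + post_depth + gap_ins + r_ins
  zsel_ins <- zc > z0 & zc < z0 + stack_h
  for (comp in 1:2) {
    x_ins <- cx + (if (comp == 1) -1 else 1) * (ax / 2 + r_ins / 4)
    mask <- (XY_x + cx - x_ins)^2 + (XY_y + cy - y_ins)^2 <= r_ins^2
    value <- if (comp == 1) calib$hu_water else calib$hu_bone
    label <- if (comp == 1) labs$phantom_water else labs$phantom_bone
    paint(mask, zsel_ins, value, label)
  }
  if (y_ins + r_ins + margin > ny * sy) stop("insert exceeds volume extent")

  if (spec$noise_sd > 0) {
    s <- if (is.null(seed)) spec$seed else as.integer(seed)
    hu <- hu + local_seed(s, array(stats::rnorm(length(hu), 0, spec$noise_sd),
                                   dim = dim(hu)))
  }
  list(ct = ct_volume(hu, spacing = spec$spacing),
       labels = label_volume(lab, spacing = spec$spacing))
}

#' Cohort simulation specification
#'
#' Parameters of a synthetic patient cohort.  Each subject carries two
#' vertebral segments: a lumbar reference segment (L1-L3) and a
#' fracture-site segment centred on the incidentally fractured level.  Their
#' QCT-scale trabecular densities are drawn from a bivariate normal
#' distribution with correlation `fracture_site_correlation`; an independent
#' standard-normal factor scaled by `covariate_effect * density_sd` perturbs
#' the fracture-site density, creating between-subject variation in the
#' fracture/lumbar BMD ratio that the partial-correlation analysis adjusts
#' for.
#'
#' @param n_subjects number of subjects (>= 4; partial correlation needs
#'   `n - 3 >= 1` degrees of freedom).
#' @param density_mean mean QCT-scale trabecular vBMD (mg/mL).
#' @param density_sd between-subject SD of vBMD (mg/mL).
#' @param fracture_site_correlation correlation between lumbar and
#'   fracture-site densities, in \[-1, 1\].
#' @param covariate_effect scale of the ratio-perturbing factor
#'   (dimensionless, >= 0).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 11, density_mean = 65, density_sd = 12,
                        fracture_site_correlation = 0.7,
                        covariate_effect = 0.3, seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (abs(fracture_site_correlation) > 1)
    stop("fracture_site_correlation must lie in [-1, 1]")
  if (density_sd < 0 || covariate_effect < 0)
    stop("density_sd and covariate_effect must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 density_mean = density_mean, density_sd = density_sd,
                 fracture_site_correlation = fracture_site_correlation,
                 covariate_effect = covariate_effect, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of spine phantoms with known ground truth
#'
#' Draws per-subject (lumbar, fracture-site) density pairs from the bivariate
#' normal model of [cohort_spec()], converts QCT-scale densities to rendering
#' attenuations through the inverse calibration chain, and (optionally)
#' renders each subject as a 6-vertebra stack: vertebrae 1-3 form the lumbar
#' L1-L3 segment, vertebrae 4-6 the fracture-site segment with vertebra 5 the
#' fractured level.
#'
#' @param cohort a [cohort_spec()].
#' @param spec a [phantom_spec()] for the per-subject geometry.
#' @param calib a [calibration_phantom()].
#' @param render render image volumes (`TRUE`) or return ground truth only?
#' @return list with `truth` (data.frame of drawn densities per subject) and,
#'   when `render = TRUE`, `subjects`, a list of per-subject phantom lists as
#'   returned by [generate_fsu_phantom()].
#' @export
simulate_cohort <- function(cohort, spec = phantom_spec(),
                            calib = calibration_phantom(), render = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(spec, "phantom_spec"))
  n <- cohort$n_subjects
  rho <- cohort$fracture_site_correlation
  truth <- local_seed(cohort$seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    w <- stats::rnorm(n)
    data.frame(
      subject = seq_len(n),
      lumbar_bmd_qct = cohort$density_mean + cohort$density_sd * z1,
      fracture_bmd_qct = cohort$density_mean + cohort$density_sd * z2 +
        cohort$covariate_effect * cohort$density_sd * w,
      ratio_factor = w
    )
  })
  out <- list(truth = truth)
  if (render) {
    out$subjects <- lapply(seq_len(n), function(i) {
      hu_l <- hu_from_bmd(mdct_from_qct(truth$lumbar_bmd_qct[i]), calib)
      hu_f <- hu_from_bmd(mdct_from_qct(truth$fracture_bmd_qct[i]), calib)
      generate_fsu_phantom(spec, n_vertebrae = 6L, calib = calib,
                           trabecular_hu = c(hu_l, hu_l, hu_l, hu_f, hu_f, hu_f),
                           seed = cohort$seed + 1000L + i)
    })
  }
  out
}
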