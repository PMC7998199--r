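# Displacement-controlled compression of tetrahedral bone/disc assemblies.
#
# Small-strain linear C3D4 elements.  Bone elements are transversely
# isotropic with stiffness E_z * C0 (C0 the unit stiffness from
# bone_unit_stiffness()); disc elements are isotropic and linear.  Bone
# nonlinearity follows a principal-stress criterion: when an element's
# maximum principal stress exceeds sigma_max (tension) or its minimum
# principal stress drops below -sigma_min (compression), its secant modulus
# is scaled back so the stress sits on the limit surface
# (elastic--perfectly-plastic response); once the accumulated post-yield
# strain exceeds the element's plastic-strain capacity eps_AB the element
# fails and its modulus collapses to the configured floor, which is what
# produces softening and a load peak.  The applied displacement is ramped in
# equal increments; inside each increment the secant state is iterated to
# self-consistency.

#' Displacement load program
#'
#' Monotonically increasing schedule of applied axial compressive
#' displacement.
#'
#' @param u_max final applied displacement (mm, > 0).
#' @param n_steps number of equal increments (>= 1; >= 20 recommended for
#'   failure analyses).
#' @return numeric vector of applied displacements, excluding 0.
#' @export
load_program <- function(u_max, n_steps = 25) {
  stopifnot(u_max > 0, n_steps >= 1)
  seq_len(n_steps) / n_steps * u_max
}

# Low-level model constructor shared by the assemblers (and by tests that
# build analytic geometries directly).
new_fe_model <- function(nodes, tets, groups, group, scale,
                         sigma_max, sigma_min, eps_ab, floor_mod,
                         fixed_nodes, driven_nodes, program, label = "model") {
  m <- nrow(tets)
  stopifnot(length(group) == m, length(scale) == m,
            length(fixed_nodes) > 0, length(driven_nodes) > 0)
  if (length(intersect(fixed_nodes, driven_nodes)) > 0)
    stop("fixed and driven node sets must be disjoint")
  if (any(diff(program) <= 0) || program[1] <= 0)
    stop("load program must be strictly increasing and positive")
  structure(list(
    nodes = nodes, tets = tets, groups = groups, group = group,
    scale = scale, sigma_max = sigma_max, sigma_min = sigma_min,
    eps_ab = eps_ab, floor_mod = floor_mod,
    fixed_nodes = as.integer(fixed_nodes),
    driven_nodes = as.integer(driven_nodes),
    program = program, label = label
  ), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> '%s': %d nodes, %d tets, %d groups\n",
              x$label, nrow(x$nodes), nrow(x$tets), length(x$groups)))
  cat(sprintf("  fixed %d nodes, driven %d nodes, %d increments to %.3f mm\n",
              length(x$fixed_nodes), length(x$driven_nodes),
              length(x$program), max(x$program)))
  invisible(x)
}

#' Single-vertebra compression model
#'
#' Builds the compression model of one vertebral body: all degrees of freedom
#' of the inferior surface are fixed, the axial (Z) displacement of the
#' superior surface is prescribed (transverse components left free), and each
#' element carries the material card mapped from the image.
#'
#' @param mesh an `ofea_mesh` with surface sets (see
#'   [extract_surface_sets()]; added automatically when missing).
#' @param cards per-element material cards from [assign_element_materials()].
#' @param program displacement schedule from [load_program()].
#' @param label model label carried into results.
#' @return an `fe_model`.
#' @export
assemble_single_vertebra <- function(mesh, cards, program, label = "vertebra") {
  stopifnot(inherits(mesh, "ofea_mesh"), nrow(cards) == nrow(mesh$tets))
  if (is.null(mesh$node_sets$superior_surface) ||
      is.null(mesh$node_sets$inferior_surface))
    mesh <- extract_surface_sets(mesh)
  if (length(mesh$node_sets$superior_surface) == 0 ||
      length(mesh$node_sets$inferior_surface) == 0)
    stop("empty loading surface set")
  floor_mod <- attr(cards, "floor") %||% 0.01
  new_fe_model(
    nodes = mesh$nodes, tets = mesh$tets,
    groups = list(bone = list(C = bone_unit_stiffness())),
    group = rep(1L, nrow(mesh$tets)),
    scale = cards$E_z,
    sigma_max = cards$sigma_max, sigma_min = cards$sigma_min,
    eps_ab = cards$eps_plastic, floor_mod = rep(floor_mod, nrow(cards)),
    fixed_nodes = mesh$node_sets$inferior_surface,
    driven_nodes = mesh$node_sets$superior_surface,
    program = program, label = label
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Homogeneous isotropic compression model
#'
#' Builds a compression model of a single mesh with one isotropic
#' linear-elastic material and no failure.  Mainly used to verify the solver
#' against the closed-form bar solution `F = E * A * u / L` (exact for
#' `nu = 0`).
#'
#' @param mesh an `ofea_mesh`.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param program displacement schedule from [load_program()].
#' @param label model label.
#' @return an `fe_model`.
#' @export
assemble_homogeneous <- function(mesh, E, nu, program, label = "block") {
  if (is.null(mesh$node_sets$superior_surface))
    mesh <- extract_surface_sets(mesh)
  m <- nrow(mesh$tets)
  new_fe_model(
    nodes = mesh$nodes, tets = mesh$tets,
    groups = list(iso = list(C = iso_stiffness(E, nu))),
    group = rep(1L, m), scale = rep(1, m),
    sigma_max = rep(NA_real_, m), sigma_min = rep(NA_real_, m),
    eps_ab = rep(NA_real_, m), floor_mod = rep(0.01, m),
    fixed_nodes = mesh$node_sets$inferior_surface,
    driven_nodes = mesh$node_sets$superior_surface,
    program = program, label = label
  )
}

#' Functional-spinal-unit compression model
#'
#' Assembles alternating vertebra and disc meshes into one model.  The
#' vertebra-disc and annulus-nucleus interfaces are tied by merging
#' coincident nodes (the structured meshes conform exactly); the inferior
#' surface of the bottom vertebra is fixed and the superior surface of the
#' top vertebra is driven axially.  Disc regions are isotropic linear
#' elastic with no failure.
#'
#' @param vertebra_meshes list of vertebral body meshes, bottom to top.
#' @param ivd_meshes list of `length(vertebra_meshes) - 1` discs, each a list
#'   with elements `annulus` and `nucleus` (meshes).
#' @param vertebra_cards list of per-element card data.frames, parallel to
#'   `vertebra_meshes`.
#' @param program displacement schedule from [load_program()].
#' @param floor_mod failed-element modulus floor (MPa).
#' @param label model label.
#' @return an `fe_model`.
#' @export
assemble_fsu <- function(vertebra_meshes, ivd_meshes, vertebra_cards,
                         program, floor_mod = 0.01, label = "FSU") {
  nv <- length(vertebra_meshes)
  stopifnot(nv >= 2, length(ivd_meshes) == nv - 1,
            length(vertebra_cards) == nv)
  regions <- list(); rtype <- character(0); cards <- list()
  for (i in seq_len(nv)) {
    regions <- c(regions, list(vertebra_meshes[[i]]))
    rtype <- c(rtype, "bone")
    cards <- c(cards, list(vertebra_cards[[i]]))
    if (i < nv) {
      regions <- c(regions, list(ivd_meshes[[i]]$annulus),
                   list(ivd_meshes[[i]]$nucleus))
      rtype <- c(rtype, "annulus", "nucleus")
      cards <- c(cards, list(NULL), list(NULL))
    }
  }
  mg <- merge_meshes(regions)
  if (mg$n_duplicates == 0)
    stop("region meshes share no nodes; interfaces are non-conforming")
  # every disc region must share interface nodes with the vertebrae
  bone_nodes <- unlist(mg$node_maps[rtype == "bone"])
  for (i in which(rtype != "bone")) {
    if (length(intersect(mg$node_maps[[i]], bone_nodes)) == 0)
      stop("disc region ", i, " is not connected to the vertebrae")
  }

  grp_def <- list(bone = list(C = bone_unit_stiffness()),
                  annulus = list(C = iso_stiffness(ivd_material("annulus")$E,
                                                   ivd_material("annulus")$nu)),
                  nucleus = list(C = iso_stiffness(ivd_material("nucleus")$E,
                                                   ivd_material("nucleus")$nu)))
  gid <- match(rtype, names(grp_def))
  m <- nrow(mg$mesh$tets)
  group <- rep(gid, vapply(regions, function(r) nrow(r$tets), 0L))
  scale <- numeric(m); smax <- rep(NA_real_, m); smin <- rep(NA_real_, m)
  eab <- rep(NA_real_, m)
  pos <- cumsum(c(0, vapply(regions, function(r) nrow(r$tets), 0L)))
  for (i in seq_along(regions)) {
    idx <- (pos[i] + 1):pos[i + 1]
    if (rtype[i] == "bone") {
      scale[idx] <- cards[[i]]$E_z
      smax[idx] <- cards[[i]]$sigma_max
      smin[idx] <- cards[[i]]$sigma_min
      eab[idx] <- cards[[i]]$eps_plastic
    } else scale[idx] <- 1
  }

  bottom <- extract_surface_sets(vertebra_meshes[[1]])
  top <- extract_surface_sets(vertebra_meshes[[nv]])
  fixed <- mg$node_maps[[1]][bottom$node_sets$inferior_surface]
  top_region_index <- length(regions) - 0L  # last region is the top vertebra
  driven <- mg$node_maps[[top_region_index]][top$node_sets$superior_surface]

  new_fe_model(
    nodes = mg$mesh$nodes, tets = mg$mesh$tets, groups = grp_def,
    group = group, scale = scale, sigma_max = smax, sigma_min = smin,
    eps_ab = eab, floor_mod = rep(floor_mod, m),
    fixed_nodes = fixed, driven_nodes = driven,
    program = program, label = label
  )
}

# --- element precomputation ------------------------------------------------

# Per-element strain-displacement operators and unit stiffness triplets.
# Returns B (list of 6 m x 12 matrices, Voigt order xx,yy,zz,yz,xz,xy with
# engineering shear), element volumes, dof index matrix (m x 12), and the
# 144-per-element unit stiffness values (scale = 1).
precompute_elements <- function(model) {
  nodes <- model$nodes; tets <- model$tets
  m <- nrow(tets)
  vols <- numeric(m)
  B <- lapply(1:6, function(i) matrix(0, m, 12))
  kvals <- numeric(144 * m)
  dofmat <- matrix(0L, m, 12)
  Cs <- lapply(model$groups, `[[`, "C")

  for (e in seq_len(m)) {
    vid <- tets[e, ]
    X <- nodes[vid, , drop = FALSE]
    M <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
    detM <- det(M)
    vols[e] <- detM / 6
    # gradients of shape functions: dN_i/dx
    Minv <- solve(M)
    g <- cbind(-rowSums(Minv), Minv)  # 3 x 4: column i = grad N_i
    Be <- matrix(0, 6, 12)
    for (i in 1:4) {
      c0 <- 3 * (i - 1)
      Be[1, c0 + 1] <- g[1, i]
      Be[2, c0 + 2] <- g[2, i]
      Be[3, c0 + 3] <- g[3, i]
      Be[4, c0 + 2] <- g[3, i]; Be[4, c0 + 3] <- g[2, i]  # gamma_yz
      Be[5, c0 + 1] <- g[3, i]; Be[5, c0 + 3] <- g[1, i]  # gamma_xz
      Be[6, c0 + 1] <- g[2, i]; Be[6, c0 + 2] <- g[1, i]  # gamma_xy
    }
    for (r in 1:6) B[[r]][e, ] <- Be[r, ]
    Ke <- vols[e] * crossprod(Be, Cs[[model$group[e]]] %*% Be)
    kvals[(144 * (e - 1) + 1):(144 * e)] <- Ke
    dofmat[e, ] <- as.integer(rep(3 * (vid - 1), each = 3) + rep(1:3, 4))
  }
  if (any(vols <= 0)) stop("non-positive element volume; mesh is inverted")
  # kvals stores Ke column-major per element: entry (r,c) at 12*(c-1)+r;
  # build matching triplet index vectors per element
  ridx <- rep(1:12, times = 12); cidx <- rep(1:12, each = 12)
  ii <- integer(144 * m); jj <- integer(144 * m)
  for (e in seq_len(m)) {
    d <- dofmat[e, ]
    ii[(144 * (e - 1) + 1):(144 * e)] <- d[ridx]
    jj[(144 * (e - 1) + 1):(144 * e)] <- d[cidx]
  }
  list(B = B, vols = vols, dofmat = dofmat, kvals = kvals, ii = ii, jj = jj)
}

# Vectorised eigenvalues (max and min) of symmetric 3x3 tensors given in
# Voigt component columns (xx, yy, zz, yz, xz, xy).
principal_values <- function(S) {
  sxx <- S[, 1]; syy <- S[, 2]; szz <- S[, 3]
  syz <- S[, 4]; sxz <- S[, 5]; sxy <- S[, 6]
  p1 <- sxy^2 + sxz^2 + syz^2
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  smax <- numeric(length(q)); smin <- numeric(length(q))
  diagonal <- p < 1e-12 * pmax(abs(q), 1e-300) | p == 0
  if (any(diagonal)) {
    dmax <- pmax(sxx, syy, szz)[diagonal]
    dmin <- pmin(sxx, syy, szz)[diagonal]
    smax[diagonal] <- dmax; smin[diagonal] <- dmin
  }
  gd <- !diagonal
  if (any(gd)) {
    bxx <- (sxx[gd] - q[gd]) / p[gd]; byy <- (syy[gd] - q[gd]) / p[gd]
    bzz <- (szz[gd] - q[gd]) / p[gd]
    bxy <- sxy[gd] / p[gd]; bxz <- sxz[gd] / p[gd]; byz <- syz[gd] / p[gd]
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    smax[gd] <- q[gd] + 2 * p[gd] * cos(phi)
    smin[gd] <- q[gd] + 2 * p[gd] * cos(phi + 2 * pi / 3)
  }
  cbind(max = smax, min = smin)
}

# --- solver ----------------------------------------------------------------

#' Solve a displacement-controlled compression analysis
#'
#' Ramps the prescribed axial displacement through the model's load program,
#' iterating the secant material state (yield by principal-stress limits,
#' element failure at exhausted plastic strain) to self-consistency inside
#' every increment, and records the axial reaction force on the driven
#' surface.
#'
#' @param model an `fe_model`.
#' @param max_state_iter cap on state iterations per increment.
#' @param tol_yield relative overshoot of the principal-stress limit surface
#'   accepted by the secant iteration (stress state converged when every
#'   element sits within `(1 + tol_yield)` of its limit).
#' @param stop_ratio stop ramping once the reaction has softened below this
#'   fraction of the running peak (the collapse is then complete and further
#'   increments only stretch failed elements); set to 0 to always run the
#'   full program.
#' @param verbose print per-increment progress?
#' @return A `load_displacement_curve`: data.frame with columns
#'   `displacement` (mm, starting at 0) and `force` (N, compressive
#'   positive), with attributes `element_state` (final per-element secant
#'   scale factors), `converged`, and `label`.
#' @export
solve_compression <- function(model, max_state_iter = 50, tol_yield = 1e-3,
                              stop_ratio = 0.1, verbose = FALSE) {
  stopifnot(inherits(model, "fe_model"))
  pre <- precompute_elements(model)
  m <- nrow(model$tets)
  ndof <- 3L * nrow(model$nodes)

  fixed_dofs <- as.vector(rbind(3 * (model$fixed_nodes - 1) + 1,
                                3 * (model$fixed_nodes - 1) + 2,
                                3 * model$fixed_nodes))
  driven_z <- 3L * model$driven_nodes
  con_dofs <- c(fixed_dofs, driven_z)
  free <- setdiff(seq_len(ndof), con_dofs)
  if (length(free) == 0) stop("model has no free degrees of freedom")

  # secant state: s in (0, 1], multiplying the elastic element stiffness
  s <- rep(1, m)
  failed <- rep(FALSE, m)
  eps_yield <- rep(NA_real_, m)   # equivalent strain at first yield
  can_fail <- !is.na(model$eps_ab)
  elem_scale0 <- model$scale       # elastic scale (E_z for bone, 1 for disc)
  floor_scale <- ifelse(elem_scale0 > 0, model$floor_mod / elem_scale0, 1)

  base_vals <- pre$kvals
  # assemble once to fix the sparsity pattern, then update values in place
  # through a triplet -> CSC-slot map (rowsum accumulates duplicates)
  K <- Matrix::sparseMatrix(i = pre$ii, j = pre$jj,
                            x = base_vals * rep(elem_scale0, each = 144),
                            dims = c(ndof, ndof))
  entry_key <- (rep(seq_len(ndof), diff(K@p)) - 1) * ndof + (K@i + 1)
  slot_of <- match((pre$jj - 1) * ndof + pre$ii, entry_key)
  # accumulation operator: CSC slot value = sum of its triplet contributions
  acc <- Matrix::sparseMatrix(i = slot_of, j = seq_along(slot_of), x = 1,
                              dims = c(length(K@x), length(slot_of)))
  elem_of_trip <- rep(seq_len(m), each = 144)
  assembleK <- function(sc) {
    K@x <- as.numeric(acc %*% (base_vals * (elem_scale0 * sc)[elem_of_trip]))
    K
  }

  disp <- c(0, model$program)
  force <- numeric(length(disp))
  conv <- TRUE
  balance <- numeric(length(model$program))
  fact <- NULL; Kfc <- NULL; state_dirty <- TRUE
  u <- numeric(ndof)

  elem_strain <- function(u) {
    U <- matrix(u[pre$dofmat], m, 12)
    out <- matrix(0, m, 6)
    for (r in 1:6) out[, r] <- rowSums(pre$B[[r]] * U)
    out
  }
  Cs <- lapply(model$groups, `[[`, "C")

  for (step in seq_along(model$program)) {
    d <- model$program[step]
    for (it in seq_len(max_state_iter)) {
      if (state_dirty || is.null(fact)) {
        K <- assembleK(s)
        Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
        fact <- if (is.null(fact)) Matrix::Cholesky(Kff, LDL = FALSE)
                else Matrix::update(fact, Kff)
        Kfc <- K[free, con_dofs, drop = FALSE]
        state_dirty <- FALSE
      }
      uc <- c(rep(0, length(fixed_dofs)), rep(-d, length(driven_z)))
      u <- numeric(ndof)
      u[con_dofs] <- uc
      rhs <- -(Kfc %*% uc)
      u[free] <- as.numeric(Matrix::solve(fact, rhs))

      eps <- elem_strain(u)
      # stresses under the current secant stiffness
      sig <- matrix(0, m, 6)
      for (g in seq_along(Cs)) {
        sel <- model$group == g
        if (any(sel))
          sig[sel, ] <- (eps[sel, , drop = FALSE] %*% t(Cs[[g]])) *
            (elem_scale0[sel] * s[sel])
      }
      ps <- principal_values(sig)
      ratio <- pmax(ifelse(model$sigma_max > 0, ps[, "max"] / model$sigma_max, 0),
                    ifelse(model$sigma_min > 0, -ps[, "min"] / model$sigma_min, 0))
      ratio[!can_fail] <- 0

      # strain measure for plastic accumulation: largest absolute principal
      # strain (tensor shear = engineering / 2)
      eps_tensor <- eps
      eps_tensor[, 4:6] <- eps_tensor[, 4:6] / 2
      pe <- principal_values(eps_tensor)
      eq_strain <- pmax(abs(pe[, "max"]), abs(pe[, "min"]))

      # converged when every element is within tol_yield of its limit; when
      # iterating, pull every violating element back to the limit surface
      over_tol <- !failed & can_fail & ratio > 1 + tol_yield
      changed <- FALSE
      if (any(over_tol)) {
        viol <- which(!failed & can_fail & ratio > 1)
        first <- viol[is.na(eps_yield[viol])]
        # elastic strain share at the moment the limit is reached
        eps_yield[first] <- eq_strain[first] / ratio[first]
        s[viol] <- pmax(s[viol] / ratio[viol], floor_scale[viol])
        changed <- TRUE
      }
      plast <- eq_strain - eps_yield
      now_fail <- which(!failed & !is.na(eps_yield) &
                          plast >= pmax(model$eps_ab, 0))
      if (length(now_fail)) {
        failed[now_fail] <- TRUE
        s[now_fail] <- floor_scale[now_fail]
        changed <- TRUE
      }
      if (changed) state_dirty <- TRUE else break
    }
    if (it == max_state_iter && state_dirty) conv <- FALSE

    f_int <- as.numeric(K %*% u)
    force[step + 1] <- -sum(f_int[driven_z])
    fixed_z <- fixed_dofs[seq(3, length(fixed_dofs), by = 3)]
    balance[step] <- abs(sum(f_int[fixed_z]) + sum(f_int[driven_z])) /
      max(abs(force[step + 1]), 1e-12)
    if (verbose)
      message(sprintf("  step %d/%d: u = %.4f mm, F = %.2f N, yielded %d, failed %d",
                      step, length(model$program), d, force[step + 1],
                      sum(!is.na(eps_yield)) , sum(failed)))
    if (stop_ratio > 0 &&
        force[step + 1] < stop_ratio * max(force[seq_len(step + 1)])) {
      disp <- disp[seq_len(step + 1)]
      force <- force[seq_len(step + 1)]
      break
    }
  }

  out <- data.frame(displacement = disp, force = force)
  class(out) <- c("load_displacement_curve", "data.frame")
  attr(out, "element_state") <- s
  attr(out, "converged") <- conv
  attr(out, "force_balance") <- max(balance[seq_len(length(disp) - 1)])
  attr(out, "label") <- model$label
  out
}

#' @export
print.load_displacement_curve <- function(x, ...) {
  cat(sprintf("<load_displacement_curve> '%s': %d points, peak %.2f N at %.3f mm\n",
              attr(x, "label") %||% "", nrow(x),
              max(x$force), x$displacement[which.max(x$force)]))
  invisible(x)
}

#' @export
plot.load_displacement_curve <- function(x, ...) {
  plot(x$displacement, x$force, type = "b", pch = 16,
       xlab = "applied displacement (mm)", ylab = "reaction force (N)",
       main = attr(x, "label") %||% "load-displacement", ...)
  fl <- extract_failure(x)
  points(fl$failure_displacement, fl$failure_load, col = 2, pch = 8, cex = 1.5)
  invisible(x)
}

#' Failure load and displacement from a load-displacement curve
#'
#' The failure load is the global maximum of the reaction force; the failure
#' displacement is the applied displacement at that maximum (the earliest
#' index on ties).  A curve that never softens (the maximum sits at the last
#' point of a strictly increasing trace) is returned with
#' `no_softening = TRUE`.
#'
#' @param curve a `load_displacement_curve` (or data.frame with
#'   `displacement` and `force`).
#' @param source_model optional label recorded in the result.
#' @return list of class `failure_result`: `failure_load` (N),
#'   `failure_displacement` (mm), `source_model`, `no_softening`.
#' @export
extract_failure <- function(curve, source_model = attr(curve, "label")) {
  if (is.null(curve$force) || nrow(curve) == 0) stop("empty curve")
  i <- which.max(curve$force)
  no_soft <- i == nrow(curve) && all(diff(curve$force) > 0)
  structure(list(failure_load = curve$force[i],
                 failure_displacement = curve$displacement[i],
                 source_model = source_model %||% "model",
                 no_softening = no_soft),
            class = "failure_result")
}

#' @export
print.failure_result <- function(x, ...) {
  cat(sprintf("<failure_result> '%s': %.2f N at %.3f mm%s\n",
              x$source_model, x$failure_load, x$failure_displacement,
              if (x$no_softening) " (no softening observed)" else ""))
  invisible(x)
}
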