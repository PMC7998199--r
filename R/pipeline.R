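# End-to-end orchestration: synthetic cohort -> densitometry -> meshing ->
# material mapping -> compression FE of single vertebrae and functional
# spinal units -> cohort table and partial-correlation panel.
#
# Each synthetic subject is a 6-vertebra stack: vertebrae 1-3 are the lumbar
# reference segment (L1-L3), vertebrae 4-6 the fracture-site segment with
# vertebra 5 the fractured level.  Three analyses use the lumbar bodies
# singly (L1, L2, L3), one functional spinal unit spans L1-L3 (discs 1-2),
# and one spans the fracture segment (discs 4-5).  Posterior elements are
# rendered in the images but excluded from the structural models: the
# compressive load path runs through body and disc.

#' Pipeline run configuration
#'
#' @param phantom a [phantom_spec()] for subject geometry.
#' @param cohort a [cohort_spec()].
#' @param calib a [calibration_phantom()].
#' @param height_fraction densitometry ROI height fraction.
#' @param floor modulus floor, MPa.
#' @param axial_strain applied compressive displacement as a fraction of
#'   model height.
#' @param n_increments displacement increments per analysis.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), cohort = cohort_spec(),
                       calib = calibration_phantom(),
                       height_fraction = 2 / 3, floor = 0.01,
                       axial_strain = 0.015, n_increments = 20,
                       out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"),
            inherits(calib, "calibration_phantom"),
            axial_strain > 0, n_increments >= 1)
  structure(list(phantom = phantom, cohort = cohort, calib = calib,
                 height_fraction = height_fraction, floor = floor,
                 axial_strain = axial_strain,
                 n_increments = as.integer(n_increments),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys (`phantom`, `cohort`, `calib`,
#' and scalar options) are passed to the corresponding constructors.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    phantom = do.call(phantom_spec, y$phantom %||% list()),
    cohort = do.call(cohort_spec, y$cohort %||% list()),
    calib = do.call(calibration_phantom, y$calib %||% list()),
    height_fraction = y$height_fraction %||% 2 / 3,
    floor = y$floor %||% 0.01,
    axial_strain = y$axial_strain %||% 0.015,
    n_increments = y$n_increments %||% 20,
    out_dir = y$out_dir
  )
}

# Mesh one vertebral body (trabecular + cortical labels) with surface sets.
vertebra_mesh <- function(labels, v) {
  labs <- phantom_labels(6)
  extract_surface_sets(
    mask_to_tet_mesh(labels, c(labs$trabecular[v], labs$cortical[v]),
                     region_tag = labs$trabecular[v]))
}

disc_meshes <- function(labels, j) {
  list(annulus = mask_to_tet_mesh(labels, 300L + j),
       nucleus = mask_to_tet_mesh(labels, 400L + j))
}

model_height <- function(meshes) {
  zr <- range(unlist(lapply(meshes, function(m) range(m$nodes[, 3]))))
  diff(zr)
}

#' Run the full analysis for one subject
#'
#' From one subject's CT and label volumes: per-vertebra densitometry for
#' all six bodies, single-vertebra compression of L1-L3, and compression of
#' the two functional spinal units (L1-L3 and the fracture-centred segment).
#'
#' @param config a [run_config()].
#' @param subject list with `ct` and `labels` (as produced by
#'   [simulate_cohort()]).
#' @return list with `bmd` (densitometry table for vertebrae 1-6),
#'   `single` (list of three [extract_failure()] results for L1-L3),
#'   `fsu_l1l3` and `fsu_f` (failure results), and `curves` (the underlying
#'   load-displacement curves).
#' @export
run_subject <- function(config, subject) {
  stopifnot(inherits(config, "run_config"))
  ct <- subject$ct; labels <- subject$labels
  labs <- phantom_labels(6)

  bmd <- measure_bmd(ct, labels,
                     stats::setNames(labs$trabecular,
                                     c("L1", "L2", "L3", "F-1", "F", "F+1")),
                     config$calib, config$height_fraction)

  solve_model <- function(model) solve_compression(model)
  curves <- list()

  single <- vector("list", 3)
  vmeshes <- lapply(1:6, function(v) vertebra_mesh(labels, v))
  vcards <- lapply(vmeshes, function(m)
    assign_element_materials(m, ct, config$floor))
  for (v in 1:3) {
    prog <- load_program(config$axial_strain * model_height(vmeshes[v]),
                         config$n_increments)
    mdl <- assemble_single_vertebra(vmeshes[[v]], vcards[[v]], prog,
                                    label = paste0("L", v))
    curves[[paste0("L", v)]] <- solve_model(mdl)
    single[[v]] <- extract_failure(curves[[paste0("L", v)]])
  }

  fsu <- function(vs, ds, label) {
    dmesh <- lapply(ds, function(j) disc_meshes(labels, j))
    prog <- load_program(config$axial_strain *
                           model_height(vmeshes[vs]),
                         config$n_increments)
    mdl <- assemble_fsu(vmeshes[vs], dmesh, vcards[vs], prog,
                        floor_mod = config$floor, label = label)
    solve_model(mdl)
  }
  curves$FSU_L1L3 <- fsu(1:3, 1:2, "FSU_L1-L3")
  curves$FSU_F <- fsu(4:6, 4:5, "FSU_F")

  list(bmd = bmd,
       single = single,
       fsu_l1l3 = extract_failure(curves$FSU_L1L3),
       fsu_f = extract_failure(curves$FSU_F),
       curves = curves)
}

#' Run the cohort analysis end-to-end
#'
#' Simulates the cohort, runs every subject through [run_subject()]
#' (subjects that error are logged and dropped), aggregates the per-subject
#' measures (vBMD, failure displacement and load averaged over L1-L3, the
#' fracture/lumbar BMD ratio, and the two unit failure loads), and computes
#' the adjusted partial-correlation panel.  When `config$out_dir` is set the
#' cohort table, panel and a run manifest are written as CSV/JSON.
#'
#' @param config a [run_config()].
#' @return list with `records` (cohort table, one row per subject),
#'   `panel` (see [run_correlation_panel()]), `truth` (generator ground
#'   truth), and `failures` (error messages of dropped subjects).
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_cohort(config$cohort, config$phantom, config$calib)
  n <- config$cohort$n_subjects

  rows <- vector("list", n)
  errs <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(run_subject(config, sim$subjects[[i]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("subject %d: %s", i, conditionMessage(res)))
      next
    }
    bmd <- res$bmd
    rows[[i]] <- data.frame(
      subject = i,
      fsu_f = res$fsu_f$failure_load,
      fsu_l1l3 = res$fsu_l1l3$failure_load,
      bmd_l1l3_mean = mean(bmd$bmd_qct[1:3]),
      displacement_l1l3_mean = mean(vapply(res$single,
                                           `[[`, 0, "failure_displacement")),
      load_l1l3_mean = mean(vapply(res$single, `[[`, 0, "failure_load")),
      bmd_ratio = bmd_ratio(bmd$bmd_qct[4:6], bmd$bmd_qct[1:3])
    )
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(records) || nrow(records) < 4)
    stop("fewer than 4 usable subjects; cannot run correlation panel")
  panel <- run_correlation_panel(records)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(panel, file.path(config$out_dir, "panel.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("osteofea")),
      seed = config$cohort$seed,
      n_subjects = n,
      n_failed = length(errs),
      timestamp = NULL  # deliberately omitted: outputs must be reproducible
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(records = records, panel = panel, truth = sim$truth, failures = errs)
}
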