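#' Calibration phantom description
#'
#' A two-compartment densitometry calibration phantom scanned together with
#' the spine: a water-equivalent compartment (0 mg/mL hydroxyapatite, HA) and
#' a bone-equivalent compartment (200 mg/mL HA).  The measured attenuations
#' of the two compartments (`hu_water`, `hu_bone`) anchor the linear HU-to-BMD
#' calibration; `ha_water` is carried for completeness but does not enter the
#' calibration formula.
#'
#' @param hu_water attenuation of the water compartment (HU).
#' @param hu_bone attenuation of the bone compartment (HU); must differ from
#'   `hu_water`.
#' @param ha_water HA density of the water compartment (mg/mL).
#' @param ha_bone HA density of the bone compartment (mg/mL).
#' @return An object of class `calibration_phantom`.
#' @export
calibration_phantom <- function(hu_water = 0, hu_bone = 400,
                                ha_water = 0, ha_bone = 200) {
  if (hu_bone == hu_water)
    stop("degenerate calibration: hu_bone must differ from hu_water")
  structure(list(hu_water = hu_water, hu_bone = hu_bone,
                 ha_water = ha_water, ha_bone = ha_bone),
            class = "calibration_phantom")
}

#' @export
print.calibration_phantom <- function(x, ...) {
  cat(sprintf("<calibration_phantom> water %g HU (%g mg/mL HA), bone %g HU (%g mg/mL HA)\n",
              x$hu_water, x$ha_water, x$hu_bone, x$ha_bone))
  invisible(x)
}

#' Phantom-calibrated BMD from attenuation
#'
#' Converts a mean ROI attenuation to volumetric bone mineral density on the
#' scanner's MDCT scale using the two-point phantom calibration
#' `BMD = HAb / (HUb - HUw) * (HU - HUw)`.
#'
#' @param hu attenuation value(s) in HU.
#' @param calib a [calibration_phantom()].
#' @return vBMD on the MDCT scale, mg/mL.
#' @seealso [to_qct()] for conversion to the standard QCT scale, [hu_from_bmd()]
#'   for the inverse map used when rendering phantoms at a target density.
#' @export
calibrate_bmd <- function(hu, calib) {
  stopifnot(inherits(calib, "calibration_phantom"))
  calib$ha_bone / (calib$hu_bone - calib$hu_water) * (hu - calib$hu_water)
}

#' MDCT-scale to QCT-scale BMD
#'
#' Scanner-specific linear conversion from contrast-enhanced MDCT densitometry
#' to standard quantitative-CT values, `BMD_QCT = 0.69 * BMD_MDCT - 11` mg/mL.
#' The affine map may produce negative values at very low attenuation; these
#' are returned as-is.
#'
#' @param bmd_mdct vBMD on the MDCT scale, mg/mL.
#' @return vBMD on the QCT scale, mg/mL.
#' @export
to_qct <- function(bmd_mdct) 0.69 * bmd_mdct - 11

#' Inverse maps used to render phantoms at a target density
#'
#' `hu_from_bmd()` inverts the phantom calibration so that a voxel rendered at
#' the returned HU reads back the requested MDCT-scale density;
#' `mdct_from_qct()` inverts the MDCT-to-QCT conversion.
#'
#' @param bmd_mdct target density on the MDCT scale (mg/mL).
#' @param calib a [calibration_phantom()].
#' @return attenuation in HU.
#' @export
hu_from_bmd <- function(bmd_mdct, calib) {
  stopifnot(inherits(calib, "calibration_phantom"))
  calib$hu_water + (calib$hu_bone - calib$hu_water) * bmd_mdct / calib$ha_bone
}

#' @rdname hu_from_bmd
#' @param bmd_qct target density on the QCT scale (mg/mL).
#' @export
mdct_from_qct <- function(bmd_qct) (bmd_qct + 11) / 0.69

#' Trabecular ROI specification
#'
#' Defines the region of interest used for vBMD extraction: on the most
#' central sagittal slice of the vertebral body, a region in the anterior half
#' of the trabecular compartment, vertically centred between the endplates and
#' spanning `height_fraction` of the body height (default two-thirds).
#'
#' @param target_label label id of the trabecular compartment to sample.
#' @param height_fraction fraction of the body height enclosed by the ROI,
#'   in (0, 1].
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(target_label, height_fraction = 2 / 3) {
  stopifnot(is.numeric(height_fraction), length(height_fraction) == 1)
  if (height_fraction <= 0 || height_fraction > 1)
    stop("height_fraction must lie in (0, 1]")
  structure(list(target_label = as.integer(target_label),
                 height_fraction = height_fraction),
            class = "roi_spec")
}

#' Mean ROI attenuation of a vertebral body
#'
#' Builds the trabecular ROI described by [roi_spec()] and returns its mean
#' attenuation.  The ROI is deterministic: the mid-sagittal slice is the
#' X-index closest to the label centroid, "anterior" is the half of the
#' anterior-posterior (Y) extent on the low-Y side of the centroid, and the
#' vertical band covers the central `height_fraction` of the labelled Z
#' extent.
#'
#' @param vol a [ct_volume()].
#' @param labels a [label_volume()] with the same geometry.
#' @param roi a [roi_spec()].
#' @return mean attenuation over the ROI (HU).
#' @export
extract_roi_hu <- function(vol, labels, roi) {
  stopifnot(inherits(vol, "ct_volume"), inherits(labels, "label_volume"),
            inherits(roi, "roi_spec"))
  if (!all(dim(vol$data) == dim(labels$data)))
    stop("volume and label geometry differ")
  mask <- labels$data == roi$target_label
  if (!any(mask)) stop("target label ", roi$target_label, " not present")
  idx <- which(mask, arr.ind = TRUE)

  x_mid <- round(mean(range(idx[, 1])))
  y_mid <- mean(range(idx[, 2]))
  z_lo <- min(idx[, 3]); z_hi <- max(idx[, 3])
  z_c <- (z_lo + z_hi) / 2
  half <- (z_hi - z_lo) * roi$height_fraction / 2

  keep <- idx[, 1] == x_mid &
    idx[, 2] <= y_mid &
    abs(idx[, 3] - z_c) <= half
  if (!any(keep)) stop("ROI construction produced an empty region")
  mean(vol$data[idx[keep, , drop = FALSE]])
}

#' Fracture-to-lumbar BMD ratio
#'
#' Ratio of the mean vBMD of the fractured vertebra and its adjacent upper and
#' lower neighbours to the mean vBMD of L1-L3.  Used as the adjustment
#' covariate in the partial-correlation analysis to account for vBMD
#' heterogeneity along the spine.
#'
#' @param fracture_segment_bmds vBMD values of the fracture-level triplet
#'   (mg/mL).
#' @param lumbar_bmds vBMD values of L1-L3 (mg/mL).
#' @return dimensionless ratio.
#' @export
bmd_ratio <- function(fracture_segment_bmds, lumbar_bmds) {
  if (length(fracture_segment_bmds) == 0 || length(lumbar_bmds) == 0)
    stop("both BMD lists must be non-empty")
  lm <- mean(lumbar_bmds)
  if (lm == 0) stop("lumbar mean vBMD is zero; ratio undefined")
  mean(fracture_segment_bmds) / lm
}

#' Per-vertebra BMD table
#'
#' Runs ROI extraction and calibration for a set of vertebral trabecular
#' labels and returns the densitometry table.
#'
#' @param vol a [ct_volume()].
#' @param labels a [label_volume()].
#' @param trabecular_labels named or unnamed integer vector of trabecular
#'   label ids, one per vertebra.
#' @param calib a [calibration_phantom()].
#' @param height_fraction ROI height fraction, see [roi_spec()].
#' @return data.frame with columns `vertebra`, `hu_mean`, `bmd_mdct`,
#'   `bmd_qct`.
#' @export
measure_bmd <- function(vol, labels, trabecular_labels, calib,
                        height_fraction = 2 / 3) {
  hu <- vapply(trabecular_labels, function(lab) {
    extract_roi_hu(vol, labels, roi_spec(lab, height_fraction))
  }, numeric(1))
  mdct <- calibrate_bmd(hu, calib)
  data.frame(
    vertebra = if (!is.null(names(trabecular_labels))) names(trabecular_labels)
               else as.character(trabecular_labels),
    label = as.integer(trabecular_labels),
    hu_mean = hu,
    bmd_mdct = mdct,
    bmd_qct = to_qct(mdct),
    row.names = NULL
  )
}
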