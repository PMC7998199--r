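#' CT image volume
#'
#' Light-weight container for a 3D CT-like image: a numeric array of
#' attenuation values in Hounsfield units (HU) plus the voxel spacing and the
#' world-coordinate origin.  Axis 3 of the array is the cranio-caudal (Z)
#' axis; axis 1 is left-right (X) and axis 2 anterior-posterior (Y).  Voxel
#' `(i, j, k)` occupies the axis-aligned box with corners
#' `origin + (c(i,j,k) - 1) * spacing` and `origin + c(i,j,k) * spacing`;
#' its center sits at `origin + (c(i,j,k) - 0.5) * spacing`.
#'
#' @param data numeric 3D array of HU values.
#' @param spacing voxel edge lengths in mm, length 3 (or a scalar, recycled).
#' @param origin world coordinate (mm) of the corner of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive and finite")
  structure(
    list(data = data, spacing = spacing, origin = rep_len(as.numeric(origin), 3)),
    class = "ct_volume"
  )
}

#' Label volume
#'
#' Integer segmentation mask sharing the geometry of a [ct_volume()]:
#' 0 is background, positive integers are region labels (vertebral bodies,
#' cortical shells, posterior elements, disc annulus/nucleus, calibration
#' phantom compartments).
#'
#' @inheritParams ct_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  v <- ct_volume(data, spacing, origin)
  class(v) <- c("label_volume", "ct_volume")
  v
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (inherits(x, "label_volume")) {
    labs <- sort(unique(as.vector(x$data)))
    labs <- labs[labs != 0]
    cat("  labels:", if (length(labs)) paste(labs, collapse = ", ") else "none", "\n")
  } else {
    cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# World coordinates (mm) of voxel centers along one axis.
voxel_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$spacing[axis]
}

voxel_volume <- function(vol) prod(vol$spacing)

#' Write a volume to a NIfTI file
#'
#' @param vol a [ct_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path a NIfTI file.
#' @param label read as integer [label_volume()]?
#' @return A [ct_volume()] or [label_volume()].
#' @export
read_volume <- function(path, label = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  if (label) label_volume(round(arr), spacing = sp) else ct_volume(arr, spacing = sp)
}
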