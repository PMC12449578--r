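#' Calibrated voxel volume
#'
#' The pipeline currency: a rectangular 3D grid of density values (mgCaHA/cc
#' once calibrated) with voxel spacing and origin metadata. Axis convention is
#' (x in-plane, y in-plane, z cranio-caudal).
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @param calibrated logical; `TRUE` once values are in mgCaHA/cc.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0),
                         calibrated = TRUE) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(values)))
    stop("voxel values must be finite")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         calibrated = isTRUE(calibrated)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    if (x$calibrated) ", calibrated (mgCaHA/cc)" else ", raw units"))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Physical voxel-centre coordinates along one axis
#' @param vol a [voxel_volume()].
#' @param axis integer 1..3.
#' @return numeric vector of coordinates in mm.
#' @export
voxel_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Total mineral mass of a volume
#'
#' Sum of voxel value times voxel volume; in mg when values are mgCaHA/cc
#' (voxel volume converted from mm^3 to cc).
#' @param vol a [voxel_volume()].
#' @return scalar mass in mg.
#' @export
total_mass <- function(vol) {
  sum(vol$values) * prod(vol$spacing) / 1000
}

#' Write a volume to NIfTI
#'
#' Spacing is stored in the NIfTI header (pixdim); the calibration flag goes
#' into the header description field.
#' @param vol a [voxel_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(img)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#' @param path NIfTI file.
#' @param calibrated logical; whether the stored values are mgCaHA/cc.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, calibrated = TRUE) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = RNifti::pixdim(img)[1:3],
               calibrated = calibrated)
}
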