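#' Trabecular bone volume fraction (BV/TV)
#'
#' Percentage of voxels in the trabecular segmentation whose BMD is strictly
#' above the mineral threshold.
#'
#' @param volume calibrated [voxel_volume()].
#' @param mask logical array (trabecular segmentation).
#' @param threshold mineral threshold, mgCaHA/cc.
#' @return BV/TV in percent.
#' @export
bvtv <- function(volume, mask, threshold = 250) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!volume$calibrated) stop("bvtv needs a calibrated volume")
  sel <- mask != 0
  if (!any(sel)) stop("empty trabecular mask")
  100 * sum(volume$values[sel] > threshold) / sum(sel)
}

#' Trabecular tissue mineral density (TMD)
#'
#' Mean density of the voxels above the mineral threshold within the
#' trabecular segmentation. Returns `NA` (with a warning) when no voxel
#' exceeds the threshold - the measure is undefined there, not an error.
#'
#' @inheritParams bvtv
#' @return TMD in mgCaHA/cc, or `NA_real_` when undefined.
#' @export
tmd <- function(volume, mask, threshold = 250) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!volume$calibrated) stop("tmd needs a calibrated volume")
  sel <- mask != 0
  if (!any(sel)) stop("empty trabecular mask")
  v <- volume$values[sel]
  v <- v[v > threshold]
  if (length(v) == 0) {
    warning("no voxel above threshold: TMD undefined")
    return(NA_real_)
  }
  mean(v)
}

#' Compartmental BMD and BMC
#'
#' Mean BMD and integrated mineral content over one labeled compartment of
#' a segmentation (e.g. `"SPONGIOSA_PEELED"`, `"SUBCORTEX"`,
#' `"VERTICAL_CORTEX"`).
#'
#' @param volume calibrated [voxel_volume()].
#' @param seg a [segment_cortex()] result on the same grid.
#' @param compartment a VOI name from [voi_codes()].
#' @param threshold mineral threshold used for the accompanying BV/TV and
#'   TMD values, mgCaHA/cc.
#' @return data.frame with compartment, n_voxels, volume_cc, bmd (mgCaHA/cc),
#'   bmc (mg), bvtv (percent), tmd (mgCaHA/cc) and threshold.
#' @export
compartment_bmd_bmc <- function(volume, seg, compartment, threshold = 250) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(seg, "cortex_segmentation"))
  codes <- voi_codes()
  if (!compartment %in% names(codes)) stop("unknown compartment label")
  mask <- seg$voi_labels == codes[[compartment]]
  if (!any(mask)) stop("compartment '", compartment, "' is empty")
  v <- volume$values[mask]
  vox_cc <- prod(volume$spacing) / 1000
  supra <- v[v > threshold]
  data.frame(
    compartment = compartment,
    n_voxels = sum(mask),
    volume_cc = sum(mask) * vox_cc,
    bmd = mean(v),
    bmc = sum(v) * vox_cc,
    bvtv = 100 * length(supra) / length(v),
    tmd = if (length(supra)) mean(supra) else NA_real_,
    threshold = threshold,
    stringsAsFactors = FALSE
  )
}
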