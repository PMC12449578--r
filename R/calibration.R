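#' Fit a density calibration from calibration-rod measurements
#'
#' Ordinary least squares of the known rod reference densities on the
#' measured raw-unit ROI means (forward regression: the reference densities
#' are exact, the measurements carry the noise, and the fitted affine map is
#' what gets applied per voxel).
#'
#' @param measured raw-unit rod ROI means.
#' @param reference known rod densities, mgCaHA/cc.
#' @return object of class `calibration_model` with `slope`, `intercept`,
#'   `r_squared`, `residuals` and the input rod values.
#' @export
fit_calibration <- function(measured, reference) {
  measured <- as.numeric(measured)
  reference <- as.numeric(reference)
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length")
  if (length(measured) < 2L || length(unique(reference)) < 2L)
    stop("need at least 2 rods with distinct reference densities")
  if (length(unique(measured)) < 2L)
    stop("all measured values identical: singular calibration fit")
  fit <- lm(reference ~ measured)
  ss_tot <- sum((reference - mean(reference))^2)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = 1 - sum(fit$residuals^2) / ss_tot,
         residuals = unname(fit$residuals),
         rod_reference_densities = reference,
         rod_measured_means = measured),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> BMD = %.6g * raw + %.6g (R^2 = %.6f, %d rods)\n",
    x$slope, x$intercept, x$r_squared, length(x$rod_measured_means)))
  invisible(x)
}

#' Apply a calibration to a raw volume
#'
#' Affine per-voxel transform into mgCaHA/cc. Refuses to calibrate a volume
#' already flagged as calibrated.
#'
#' @param volume a raw-unit [voxel_volume()].
#' @param model a [fit_calibration()] result.
#' @return calibrated [voxel_volume()].
#' @export
apply_calibration <- function(volume, model) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(model, "calibration_model"))
  if (volume$calibrated)
    stop("volume is already calibrated (double-calibration guard)")
  voxel_volume(model$slope * volume$values + model$intercept,
               spacing = volume$spacing, origin = volume$origin,
               calibrated = TRUE)
}

#' Save / load a calibration model as JSON
#' @param model a `calibration_model`.
#' @param path JSON file.
#' @return `read_calibration` returns the model; `write_calibration` returns
#'   `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "calibration_model")
}
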