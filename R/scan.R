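#' Calibrated PET activity volume
#'
#' Wraps a 3D array of decay-corrected activity concentration (kBq/mL) with
#' its voxel spacing. This is the raw quantity a calibrated scanner
#' reconstruction provides; [to_suv()] converts it to a standardized uptake
#' value image given the patient's injection data.
#'
#' @param activity 3D numeric array, activity concentration in kBq/mL.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class `pet_scan` with elements `activity` and
#'   `spacing`.
#' @seealso [to_suv()], [make_phantom_scan()], [read_scan()]
#' @export
pet_scan <- function(activity, spacing) {
  if (length(dim(activity)) != 3L) abort("`activity` must be a 3D array.")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  if (any(activity < 0, na.rm = TRUE)) {
    abort("activity concentrations must be non-negative.")
  }
  structure(
    list(activity = activity, spacing = as.numeric(spacing)),
    class = "pet_scan"
  )
}

#' @export
print.pet_scan <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf(
    "<pet_scan> %d x %d x %d voxels @ %.4g x %.4g x %.4g mm, activity %.3g-%.3g kBq/mL\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$activity), max(x$activity)
  ))
  invisible(x)
}

new_suv_image <- function(voxels, spacing, normalization) {
  structure(
    list(
      voxels = voxels,
      spacing = as.numeric(spacing),
      normalization = normalization
    ),
    class = "suv_image"
  )
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<suv_image> [%s] %d x %d x %d voxels @ %.4g x %.4g x %.4g mm, SUV %.3g-%.3g\n",
    x$normalization, d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}
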