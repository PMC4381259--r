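#' Read and write PET scans as NIfTI-1 volumes
#'
#' Scans are stored as NIfTI-1 with voxel values in kBq/mL and the voxel
#' spacing in the pixdim header fields.
#'
#' @param scan a [pet_scan()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_scan()` returns the path invisibly; `read_scan()` a
#'   [pet_scan()].
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "pet_scan"))
  img <- RNifti::asNifti(scan$activity)
  RNifti::pixdim(img) <- scan$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort("expected a 3D NIfTI volume.")
  pet_scan(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

flatten_geom <- function(df) {
  df |>
    dplyr::mutate(
      center_x_mm = purrr::map_dbl(.data$center_mm, 1),
      center_y_mm = purrr::map_dbl(.data$center_mm, 2),
      center_z_mm = purrr::map_dbl(.data$center_mm, 3),
      size_mm_csv = purrr::map_chr(
        .data$size_mm %||% .data$radii_mm,
        ~ paste(.x, collapse = ";")
      )
    ) |>
    dplyr::select(-dplyr::any_of(c("center_mm", "size_mm", "radii_mm")))
}

#' Materialise a synthetic cohort to disk
#'
#' Writes every patient's staging and interim scan as NIfTI-1 volumes
#' (kBq/mL) plus plain-text sidecars: `meta.csv` (patient metadata),
#' `outcomes.csv` (labels, therapy groups, visual scores), `truth.csv`
#' (designed per-patient decrease), `lesions.csv`/`masks.csv` (geometry),
#' and `scan_truth.csv` (per-scan noise-free lesion ground truth).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if missing).
#' @param compress write `.nii.gz` instead of `.nii`? Default `TRUE`.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$meta, file.path(dir, "meta.csv"))
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  lesions_flat <- cohort$lesions |>
    dplyr::rename(size_mm = "radii_mm") |>
    flatten_geom() |>
    dplyr::rename(radii_mm = "size_mm_csv")
  readr::write_csv(lesions_flat, file.path(dir, "lesions.csv"))
  masks_flat <- flatten_geom(cohort$masks) |>
    dplyr::rename(size_mm = "size_mm_csv")
  readr::write_csv(masks_flat, file.path(dir, "masks.csv"))
  ext <- if (compress) ".nii.gz" else ".nii"
  truth_rows <- list()
  for (pid in cohort$meta$patient_id) {
    for (tp in 1:2) {
      ph <- realize_scan(cohort, pid, tp)
      write_scan(ph$scan, file.path(dir, sprintf("%s_pet%d%s", pid, tp, ext)))
      truth_rows[[length(truth_rows) + 1L]] <- dplyr::mutate(
        ph$lesions, patient_id = pid, timepoint = tp, .before = 1
      )
    }
  }
  readr::write_csv(dplyr::bind_rows(truth_rows),
                   file.path(dir, "scan_truth.csv"))
  invisible(dir)
}

#' Build a cohort design from a JSON file
#'
#' Reads a JSON object whose fields mirror the [cohort_design()] arguments
#' (`grid` as `{"dim": [...], "spacing": [...]}`, the delta distributions
#' as `{"mean": ..., "sd": ..., "max": ...}`) and returns the design.
#' Fields left out fall back to the defaults.
#'
#' @param path JSON file path.
#' @return A `cohort_design`.
#' @export
design_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$grid)) {
    args$grid <- pet_grid(raw$grid$dim, raw$grid$spacing)
  }
  for (f in c("delta_responders", "delta_nonresponders")) {
    if (!is.null(raw[[f]])) {
      args[[f]] <- trunc_norm_spec(raw[[f]]$mean, raw[[f]]$sd,
                                   raw[[f]]$max %||% 100)
    }
  }
  do.call(cohort_design, args)
}

#' Write a pipeline run's outputs
#'
#' Emits the Table-shaped report and the per-patient record table as CSV
#' plus a small structured text log (seed, thresholds, exclusions).
#'
#' @param run a `pet_run`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pet_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$report, file.path(dir, "report.csv"))
  readr::write_csv(run$records, file.path(dir, "records.csv"))
  readr::write_csv(run$log, file.path(dir, "log.csv"))
  invisible(dir)
}
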