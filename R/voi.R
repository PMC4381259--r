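#' Lesion mask and physiological-uptake exclusion specifications
#'
#' A mask is a coarse geometric region (sphere, box or cylinder) placed over
#' a visually detected lesion; the isocontour VOI is then delineated inside
#' it by thresholding. An exclusion is the same geometry used to remove
#' areas of high but physiological uptake (brain, myocardium, urinary
#' tract, brown fat) from the segmentation.
#'
#' `size_mm` is shape-appropriate: sphere — diameter; box — the three full
#' edge lengths; cylinder (z-axis aligned) — diameter and height.
#'
#' @param shape `"sphere"`, `"box"` or `"cylinder"`.
#' @param center_mm centre in mm (physical coordinates).
#' @param size_mm shape dimensions in mm (see Details).
#' @param label mask label, used as the lesion label in results.
#' @param reason for exclusions: one of `"brain"`, `"myocardium"`,
#'   `"urinary"`, `"brown_fat"`, `"other"`.
#' @return One-row tibble with list-columns `center_mm` and `size_mm`;
#'   combine several with `dplyr::bind_rows()`.
#' @examples
#' mask_spec("sphere", c(100, 100, 100), 40, label = "L1")
#' @export
mask_spec <- function(shape = c("sphere", "box", "cylinder"),
                      center_mm, size_mm, label = "lesion") {
  shape <- match.arg(shape)
  check_mask_geometry(shape, center_mm, size_mm)
  tibble::tibble(
    label = as.character(label),
    shape = shape,
    center_mm = list(as.numeric(center_mm)),
    size_mm = list(as.numeric(size_mm))
  )
}

#' @rdname mask_spec
#' @export
exclusion_spec <- function(shape = c("sphere", "box", "cylinder"),
                           center_mm, size_mm,
                           reason = c("brain", "myocardium", "urinary",
                                      "brown_fat", "other")) {
  shape <- match.arg(shape)
  reason <- match.arg(reason)
  check_mask_geometry(shape, center_mm, size_mm)
  tibble::tibble(
    reason = reason,
    shape = shape,
    center_mm = list(as.numeric(center_mm)),
    size_mm = list(as.numeric(size_mm))
  )
}

check_mask_geometry <- function(shape, center_mm, size_mm) {
  if (length(center_mm) != 3L || any(!is.finite(center_mm))) {
    abort("`center_mm` must be a finite 3-vector.")
  }
  needed <- switch(shape, sphere = 1L, box = 3L, cylinder = 2L)
  if (length(size_mm) != needed || any(!is.finite(size_mm)) || any(size_mm <= 0)) {
    abort(sprintf("`size_mm` for a %s needs %d positive value(s).", shape, needed))
  }
  invisible(TRUE)
}

mask_voxels <- function(image, row) {
  geometry_voxels(dim(image$voxels), image$spacing, row$shape,
                  row$center_mm[[1]], row$size_mm[[1]])
}

#' Threshold-based isocontour VOI inside a mask
#'
#' The irregular isocontour volume of interest: all voxels inside the mask,
#' outside every exclusion region, whose SUV strictly exceeds the
#' threshold. No connected-component pruning is applied by default — every
#' supra-threshold voxel in the mask counts; set `connected = TRUE` to keep
#' only the 6-connected components that touch the mask's hottest voxel.
#'
#' @param image a `suv_image`.
#' @param mask one-row tibble from [mask_spec()].
#' @param threshold segmentation threshold (strict `>`), in the image's SUV
#'   units.
#' @param exclusions optional tibble of [exclusion_spec()] rows.
#' @param connected keep only components connected to the hottest voxel?
#'   Default `FALSE`.
#' @return Integer vector of linear voxel indices into `image$voxels`.
#' @export
isocontour_voi <- function(image, mask, threshold, exclusions = NULL,
                           connected = FALSE) {
  stopifnot(inherits(image, "suv_image"))
  inside <- mask_voxels(image, mask)
  if (length(inside) == 0L) {
    abort(sprintf("mask '%s' does not intersect the image.", mask$label))
  }
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    excl <- unlist(lapply(seq_len(nrow(exclusions)), function(i) {
      mask_voxels(image, exclusions[i, ])
    }))
    inside <- setdiff(inside, excl)
  }
  voi <- inside[image$voxels[inside] > threshold]
  if (connected && length(voi) > 1L) {
    voi <- connected_to_hottest(image, voi)
  }
  attr(voi, "mask_voxels") <- inside
  voi
}

# 6-connected component of the supra-threshold set containing its hottest
# voxel; flood fill over linear indices.
connected_to_hottest <- function(image, voi) {
  d <- dim(image$voxels)
  nx <- d[1]; nxy <- d[1] * d[2]
  in_set <- new.env(hash = TRUE, size = length(voi))
  for (v in voi) assign(as.character(v), TRUE, envir = in_set)
  seed <- voi[which.max(image$voxels[voi])]
  keep <- integer(0)
  frontier <- seed
  remove(list = as.character(seed), envir = in_set)
  while (length(frontier)) {
    keep <- c(keep, frontier)
    nb <- unique(c(frontier - 1L, frontier + 1L,
                   frontier - nx, frontier + nx,
                   frontier - nxy, frontier + nxy))
    nb <- nb[nb >= 1L & nb <= prod(d)]
    present <- vapply(nb, function(v) {
      exists(as.character(v), envir = in_set, inherits = FALSE)
    }, logical(1))
    frontier <- nb[present]
    if (length(frontier)) remove(list = as.character(frontier), envir = in_set)
  }
  sort(keep)
}

#' Quantitative metrics of an isocontour VOI
#'
#' Computes the per-lesion quartet: SUVmax, SUVmean, metabolic tumor volume
#' (MTV, mL) and total lesion glycolysis (TLG = SUVmean × MTV, g). When the
#' VOI is empty (nothing in the mask exceeds the threshold) MTV and TLG are
#' zero and SUVmax/SUVmean are reported over the whole mask with
#' `below_threshold = TRUE` — the lesion is still measurable, just
#' metabolically negative at this threshold.
#'
#' @param image the `suv_image` the VOI was delineated on.
#' @param voi voxel index vector from [isocontour_voi()].
#' @param scheme label of the threshold scheme (e.g. `"suv_bw_2.5"`).
#' @param label lesion label.
#' @param threshold the threshold used, echoed into the result.
#' @return One-row tibble (`lesion_label`, `scheme`, `threshold`,
#'   `suv_max`, `suv_mean`, `mtv_ml`, `tlg_g`, `n_voxels`,
#'   `below_threshold`, plus mask-level summaries used for aggregation).
#' @export
voi_metrics <- function(image, voi, scheme = "suv_bw_2.5", label = "lesion",
                        threshold = NA_real_) {
  stopifnot(inherits(image, "suv_image"))
  vol <- voxel_volume_ml(image$spacing)
  mask_idx <- attr(voi, "mask_voxels") %||% voi
  mask_vals <- image$voxels[mask_idx]
  n <- length(voi)
  if (n > 0L) {
    vals <- image$voxels[voi]
    suv_max <- max(vals)
    suv_mean <- mean(vals)
    mtv <- n * vol
    below <- FALSE
  } else {
    suv_max <- if (length(mask_vals)) max(mask_vals) else NA_real_
    suv_mean <- if (length(mask_vals)) mean(mask_vals) else NA_real_
    mtv <- 0
    below <- TRUE
  }
  tibble::tibble(
    lesion_label = label,
    scheme = scheme,
    threshold = threshold,
    suv_max = suv_max,
    suv_mean = suv_mean,
    mtv_ml = mtv,
    tlg_g = if (below) 0 else suv_mean * mtv,
    n_voxels = n,
    below_threshold = below,
    n_mask_voxels = length(mask_idx),
    mask_mean = if (length(mask_vals)) mean(mask_vals) else NA_real_
  )
}

#' Segment and measure every lesion mask on one SUV image
#'
#' Convenience wrapper: for each mask, delineate the isocontour VOI and
#' compute its metrics.
#'
#' @inheritParams isocontour_voi
#' @param masks tibble of [mask_spec()] rows.
#' @param scheme threshold scheme label carried into the results.
#' @return Tibble with one [voi_metrics()] row per mask.
#' @export
measure_lesions <- function(image, masks, threshold, exclusions = NULL,
                            scheme = "suv_bw_2.5", connected = FALSE) {
  purrr::map_dfr(seq_len(nrow(masks)), function(i) {
    m <- masks[i, ]
    voi <- isocontour_voi(image, m, threshold, exclusions, connected)
    voi_metrics(image, voi, scheme = scheme, label = m$label,
                threshold = threshold)
  })
}

#' Re-measure PET1 masks on the interim scan
#'
#' The masks defined on the staging scan are placed identically on the
#' follow-up (interim) scan — phantom pairs are co-registered by
#' construction — and the same metrics are extracted with the same
#' threshold scheme. The interim MTV may legitimately be zero.
#'
#' @param pet2_image `suv_image` of the follow-up scan.
#' @param masks the PET1 mask tibble.
#' @param threshold segmentation threshold for the scheme.
#' @param exclusions optional exclusion tibble.
#' @param scheme scheme label.
#' @param reference optional `suv_image`/`pet_scan` from PET1; if given, the
#'   follow-up geometry must match it exactly.
#' @inheritParams isocontour_voi
#' @return Tibble of per-mask [voi_metrics()] rows on the follow-up image.
#' @export
apply_masks_to_followup <- function(pet2_image, masks, threshold,
                                    exclusions = NULL, scheme = "suv_bw_2.5",
                                    reference = NULL, connected = FALSE) {
  if (!is.null(reference) && !same_geometry(pet2_image, reference)) {
    abort("PET2 geometry does not match the PET1 reference grid.")
  }
  measure_lesions(pet2_image, masks, threshold, exclusions, scheme, connected)
}

#' Aggregate per-lesion metrics to one per-patient value set
#'
#' The study reports a single value per patient and parameter; with several
#' target lesions the aggregation used here is: SUVmax — maximum over
#' lesions; MTV and TLG — sums; SUVmean — MTV-weighted mean over lesions
#' (so the patient-level TLG identity TLG = SUVmean × MTV is preserved
#' exactly). If every lesion is below threshold, SUVmean falls back to the
#' mask-voxel-count-weighted mean over whole masks and the patient is
#' flagged `below_threshold`.
#'
#' @param lesion_metrics tibble of [voi_metrics()] rows (one scheme, one
#'   timepoint, one patient).
#' @return One-row tibble: `suv_max`, `suv_mean`, `mtv_ml`, `tlg_g`,
#'   `n_lesions`, `below_threshold`.
#' @export
aggregate_lesions <- function(lesion_metrics) {
  stopifnot(nrow(lesion_metrics) > 0)
  mtv <- sum(lesion_metrics$mtv_ml)
  tlg <- sum(lesion_metrics$tlg_g)
  below <- all(lesion_metrics$below_threshold)
  suv_mean <- if (mtv > 0) {
    tlg / mtv
  } else {
    stats::weighted.mean(lesion_metrics$mask_mean,
                         lesion_metrics$n_mask_voxels)
  }
  tibble::tibble(
    suv_max = max(lesion_metrics$suv_max),
    suv_mean = suv_mean,
    mtv_ml = mtv,
    tlg_g = tlg,
    n_lesions = nrow(lesion_metrics),
    below_threshold = below
  )
}
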