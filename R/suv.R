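#' Body surface area (DuBois-DuBois)
#'
#' Classic DuBois-DuBois estimate
#' \eqn{BSA = 0.007184 \, W^{0.425} H^{0.725}} with weight in kg and height
#' in cm, the most common clinical default for body-surface-area-normalized
#' SUV.
#'
#' @param weight_kg body weight in kg (> 0), vectorised.
#' @param height_cm body height in cm (> 0), vectorised.
#' @return Body surface area in m².
#' @examples
#' body_surface_area(70, 170) # ~1.81 m2
#' @export
body_surface_area <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive and finite.")
  }
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    abort("`height_cm` must be positive and finite.")
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Lean body mass (James formula)
#'
#' Sex-specific James estimate of lean body mass, the normalizer used for
#' SUL (SUV corrected for lean body mass) in PERCIST-style analyses:
#' males \eqn{1.10 W - 128 (W/H)^2}, females \eqn{1.07 W - 148 (W/H)^2}
#' (W in kg, H in cm).
#'
#' @param weight_kg body weight in kg (> 0), vectorised.
#' @param height_cm body height in cm (> 0), vectorised.
#' @param sex `"male"` or `"female"`, recycled against weight/height.
#' @return Lean body mass in kg; errors if the formula leaves the physiologic
#'   domain (non-positive result).
#' @examples
#' lean_body_mass(70, 170, "male")   # ~55.3 kg
#' lean_body_mass(70, 170, "female") # ~49.9 kg
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive and finite.")
  }
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    abort("`height_cm` must be positive and finite.")
  }
  sex <- match_sex(sex)
  n <- max(length(weight_kg), length(height_cm), length(sex))
  w <- rep_len(weight_kg, n); h <- rep_len(height_cm, n)
  s <- rep_len(sex, n)
  ratio2 <- (w / h)^2
  lbm <- ifelse(s == "male", 1.10 * w - 128 * ratio2, 1.07 * w - 148 * ratio2)
  if (any(lbm <= 0)) {
    abort("lean body mass is non-positive for these inputs; outside the formula's physiologic domain.")
  }
  lbm
}

match_sex <- function(sex) {
  if (!all(sex %in% c("male", "female"))) {
    abort('`sex` must be "male" or "female".')
  }
  sex
}

suv_normalizer <- function(meta, normalization) {
  # SUV = C[kBq/mL] / (ID[kBq] / normalizer[g]); with dose in MBq and
  # weight in kg the unit factors cancel, so SUV_bw = C * W / ID.
  # For bsa the conventional cm^2 scale is used: SUV_bsa = C * BSA[cm^2] / ID[kBq].
  switch(normalization,
    bw = meta$weight_kg / meta$injected_dose_MBq,
    lbm = {
      if (is.null(meta$sex) || is.null(meta$height_cm) ||
          is.na(meta$sex) || is.na(meta$height_cm)) {
        abort("lbm normalization needs `sex` and `height_cm` in the metadata.")
      }
      lean_body_mass(meta$weight_kg, meta$height_cm, meta$sex) /
        meta$injected_dose_MBq
    },
    bsa = {
      if (is.null(meta$height_cm) || is.na(meta$height_cm)) {
        abort("bsa normalization needs `height_cm` in the metadata.")
      }
      body_surface_area(meta$weight_kg, meta$height_cm) * 1e4 /
        (meta$injected_dose_MBq * 1e3)
    },
    abort('`normalization` must be one of "bw", "bsa", "lbm".')
  )
}

#' Convert an activity volume to a standardized uptake value image
#'
#' Voxelwise SUV = activity concentration divided by injected dose per unit
#' normalizer. Three normalizations are supported: body weight (`"bw"`,
#' the usual dimensionless g/mL convention), body surface area (`"bsa"`,
#' reported on the conventional cm² scale, i.e. activity × BSA(cm²) /
#' dose(kBq) — numerically several-fold smaller than SUV_bw, so fixed
#' thresholds tuned for SUV_bw are far more stringent on this scale), and
#' lean body mass (`"lbm"`, the SUL of PERCIST-style analyses).
#' Activity is assumed decay-corrected to injection time by the scanner;
#' uptake time is carried as metadata only.
#'
#' @param scan a [pet_scan()] in kBq/mL.
#' @param meta one-row data frame (or list) with `weight_kg`,
#'   `injected_dose_MBq` and, for `"bsa"`/`"lbm"`, `height_cm` and `sex`.
#' @param normalization `"bw"`, `"bsa"` or `"lbm"`.
#' @return A `suv_image` (voxels, spacing, normalization).
#' @examples
#' meta <- tibble::tibble(weight_kg = 50, height_cm = 160, sex = "male",
#'                        injected_dose_MBq = 250)
#' scan <- pet_scan(array(5, c(4, 4, 4)), spacing = c(4, 4, 4))
#' to_suv(scan, meta, "bw")
#' @export
to_suv <- function(scan, meta, normalization = c("bw", "bsa", "lbm")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(scan, "pet_scan"))
  meta <- as.list(meta)
  if (is.null(meta$injected_dose_MBq) || !is.finite(meta$injected_dose_MBq) ||
      meta$injected_dose_MBq <= 0) {
    abort("`injected_dose_MBq` must be positive.")
  }
  if (is.null(meta$weight_kg) || !is.finite(meta$weight_kg) || meta$weight_kg <= 0) {
    abort("`weight_kg` must be positive.")
  }
  f <- suv_normalizer(meta, normalization)
  new_suv_image(scan$activity * f, scan$spacing, normalization)
}

#' Liver reference statistics for individualized SUL thresholding
#'
#' Mean and standard deviation of SUL over a spherical volume of interest
#' (default diameter 5.15 cm) placed in normal liver, the individual
#' background reference used to threshold lesions at mean + 2 SD.
#' Sphere membership uses the voxel-centre-inside rule.
#'
#' @param sul a `suv_image` with `normalization == "lbm"`.
#' @param center_mm sphere centre in mm (physical coordinates).
#' @param diameter_cm sphere diameter in cm; default 5.15.
#' @return One-row tibble: `mean_sul`, `sd_sul`, `n_voxels`, `diameter_cm`
#'   and the centre coordinates.
#' @seealso [sul_threshold()]
#' @export
liver_reference <- function(sul, center_mm, diameter_cm = 5.15) {
  stopifnot(inherits(sul, "suv_image"))
  if (!identical(sul$normalization, "lbm")) {
    abort("liver reference statistics are defined on the SUL (lbm) image.")
  }
  d <- dim(sul$voxels)
  r_mm <- diameter_cm * 10 / 2
  if (!sphere_inside(d, sul$spacing, center_mm, r_mm)) {
    abort("liver reference sphere extends outside the field of view.")
  }
  idx <- geometry_voxels(d, sul$spacing, "sphere", center_mm, diameter_cm * 10)
  if (length(idx) < 2L) {
    abort("liver reference sphere covers fewer than two voxel centres.")
  }
  vals <- sul$voxels[idx]
  tibble::tibble(
    mean_sul = mean(vals),
    sd_sul = sd(vals),
    n_voxels = length(idx),
    diameter_cm = diameter_cm,
    center_x_mm = center_mm[1],
    center_y_mm = center_mm[2],
    center_z_mm = center_mm[3]
  )
}

#' Individualized SUL segmentation threshold
#'
#' Threshold for lesion delineation on the SUL image: mean liver SUL plus
#' two standard deviations, excluding the patient's individual background
#' from lesion volumes.
#'
#' @param liver_stats result of [liver_reference()] (or any list with
#'   `mean_sul` and `sd_sul`).
#' @return Numeric threshold in SUL units.
#' @examples
#' sul_threshold(list(mean_sul = 2.0, sd_sul = 0.1)) # 2.2
#' @export
sul_threshold <- function(liver_stats) {
  if (is.null(liver_stats$mean_sul) || is.null(liver_stats$sd_sul)) {
    abort("`liver_stats` needs `mean_sul` and `sd_sul`.")
  }
  if (any(liver_stats$sd_sul < 0)) abort("`sd_sul` must be non-negative.")
  liver_stats$mean_sul + 2 * liver_stats$sd_sul
}
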