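#' Ellipsoidal lesion specification for phantom scans
#'
#' Lesions are ellipsoids with either a uniform SUV or a gaussian falloff
#' profile `peak * exp(-rho^2 / (2 * 0.5^2))` in the normalised ellipsoidal
#' radius `rho` (so the rim at `rho = 1` sits at ~13.5% of the peak, giving
#' sub-threshold rims that exercise threshold segmentation).
#'
#' @param center_mm lesion centre in mm.
#' @param radii_mm ellipsoid semi-axes in mm (3-vector, positive).
#' @param peak_suv peak SUV (body-weight scale) at the lesion centre, >= 0.
#' @param profile `"uniform"` or `"gaussian"`.
#' @param label lesion label.
#' @return One-row tibble; combine with `dplyr::bind_rows()`.
#' @export
lesion_spec <- function(center_mm, radii_mm, peak_suv,
                        profile = c("uniform", "gaussian"), label = "lesion") {
  profile <- match.arg(profile)
  if (length(center_mm) != 3L || any(!is.finite(center_mm))) {
    abort("`center_mm` must be a finite 3-vector.")
  }
  if (length(radii_mm) != 3L || any(radii_mm <= 0)) {
    abort("`radii_mm` must be three positive semi-axes.")
  }
  if (!is.finite(peak_suv) || peak_suv < 0) abort("`peak_suv` must be >= 0.")
  tibble::tibble(
    label = as.character(label),
    center_mm = list(as.numeric(center_mm)),
    radii_mm = list(as.numeric(radii_mm)),
    peak_suv = peak_suv,
    profile = profile
  )
}

lesion_profile_values <- function(rho2, peak, profile) {
  if (profile == "uniform") rep(peak, length(rho2))
  else peak * exp(-2 * rho2) # gaussian, sigma = 0.5 in normalised radius
}

#' Generate one synthetic PET scan with known ground truth
#'
#' Builds a noise-free SUV (body-weight) image from a uniform soft-tissue
#' background, ellipsoidal lesions, an optional heterogeneous liver region
#' and optional physiological hotspots; adds i.i.d. gaussian noise in SUV
#' units; and converts to an activity volume (kBq/mL) using the patient's
#' injection data, so that [to_suv()] round-trips the designed values.
#' Lesions replace the background (voxelwise maximum), so a lesion's
#' designed peak is the SUV actually observed at its centre.
#'
#' The ground truth is measured on the noise-free image: per lesion the
#' true SUVmax over the lesion's support voxels and the true volume (mL)
#' of support voxels whose noise-free SUV exceeds 2.5; for the liver the
#' realised per-voxel mean and SD (the liver is given per-voxel tissue
#' heterogeneity even at `noise_sd_suv = 0`, since the individualized
#' threshold consumes its SD).
#'
#' @param meta one-row patient metadata (needs `weight_kg`,
#'   `injected_dose_MBq`).
#' @param lesions tibble of [lesion_spec()] rows (may be empty).
#' @param liver_mean_suv,liver_sd_suv liver mean/SD on the SUV (bw) scale,
#'   or `NULL` for no liver region.
#' @param grid a [pet_grid()]; default 128 x 128 x 160 voxels at 4 mm.
#' @param noise_sd_suv SD of additive gaussian image noise, SUV units.
#' @param seed integer seed for liver texture and noise.
#' @param background_suv uniform soft-tissue background SUV; default 1.0.
#' @param liver_center_mm centre of the liver sphere (mm).
#' @param liver_diameter_cm liver region diameter; default 5.15 cm.
#' @param hotspots optional tibble (`center_mm` list-col, `radius_mm`,
#'   `suv`) of uniform spherical physiological hotspots.
#' @return List: `scan` (a [pet_scan()]), `lesions` (ground-truth tibble:
#'   `label`, `true_suv_max`, `true_mtv_ml`, `n_support_voxels`), `liver`
#'   (realised mean/SD tibble or `NULL`).
#' @export
make_phantom_scan <- function(meta, lesions = NULL,
                              liver_mean_suv = NULL, liver_sd_suv = 0,
                              grid = pet_grid(), noise_sd_suv = 0,
                              seed = 1L, background_suv = 1.0,
                              liver_center_mm = NULL, liver_diameter_cm = 5.15,
                              hotspots = NULL) {
  stopifnot(inherits(grid, "pet_grid"))
  meta <- as.list(meta)
  if (!is.finite(noise_sd_suv) || noise_sd_suv < 0) {
    abort("`noise_sd_suv` must be non-negative.")
  }
  d <- grid$dim; sp <- grid$spacing
  extent <- d * sp
  vol <- array(background_suv, dim = d)
  set.seed(as.integer(seed))

  liver_truth <- NULL
  liver_idx <- integer(0)
  if (!is.null(liver_mean_suv)) {
    if (is.null(liver_center_mm)) {
      abort("`liver_center_mm` is required when a liver region is requested.")
    }
    r_mm <- liver_diameter_cm * 10 / 2
    if (!sphere_inside(d, sp, liver_center_mm, r_mm)) {
      abort("liver region extends outside the field of view.")
    }
    liver_idx <- geometry_voxels(d, sp, "sphere", liver_center_mm,
                                 liver_diameter_cm * 10)
    liver_vals <- rnorm(length(liver_idx), liver_mean_suv, liver_sd_suv)
    liver_vals <- pmax(liver_vals, 0)
    vol[liver_idx] <- liver_vals
    liver_truth <- tibble::tibble(
      mean_suv = mean(liver_vals),
      sd_suv = sd(liver_vals),
      n_voxels = length(liver_idx),
      center_x_mm = liver_center_mm[1],
      center_y_mm = liver_center_mm[2],
      center_z_mm = liver_center_mm[3],
      diameter_cm = liver_diameter_cm
    )
  }

  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    for (i in seq_len(nrow(hotspots))) {
      hidx <- geometry_voxels(d, sp, "sphere", hotspots$center_mm[[i]],
                              2 * hotspots$radius_mm[i])
      vol[hidx] <- pmax(vol[hidx], hotspots$suv[i])
    }
  }

  lesion_truth <- tibble::tibble(
    label = character(0), true_suv_max = numeric(0),
    true_mtv_ml = numeric(0), n_support_voxels = integer(0)
  )
  if (!is.null(lesions) && nrow(lesions) > 0) {
    vv <- voxel_volume_ml(sp)
    rows <- vector("list", nrow(lesions))
    for (i in seq_len(nrow(lesions))) {
      le <- lesions[i, ]
      ctr <- le$center_mm[[1]]; rad <- le$radii_mm[[1]]
      if (any(ctr - rad < 0) || any(ctr + rad > extent)) {
        abort(sprintf("lesion '%s' extends outside the field of view.", le$label))
      }
      g <- geometry_voxels(d, sp, "ellipsoid", ctr, rad, with_rho2 = TRUE)
      if (length(liver_idx) && length(intersect(g$idx, liver_idx))) {
        abort(sprintf("lesion '%s' overlaps the liver reference region.", le$label))
      }
      vals <- lesion_profile_values(g$rho2, le$peak_suv, le$profile)
      vol[g$idx] <- pmax(vol[g$idx], vals)
      painted <- vol[g$idx]
      rows[[i]] <- tibble::tibble(
        label = le$label,
        true_suv_max = if (length(painted)) max(painted) else NA_real_,
        true_mtv_ml = sum(painted > 2.5) * vv,
        n_support_voxels = length(g$idx)
      )
    }
    lesion_truth <- dplyr::bind_rows(rows)
  }

  if (noise_sd_suv > 0) {
    vol <- vol + array(rnorm(length(vol), 0, noise_sd_suv), dim = d)
    vol <- pmax(vol, 0)
  }

  if (is.null(meta$weight_kg) || meta$weight_kg <= 0 ||
      is.null(meta$injected_dose_MBq) || meta$injected_dose_MBq <= 0) {
    abort("`meta` needs positive `weight_kg` and `injected_dose_MBq`.")
  }
  activity <- vol * meta$injected_dose_MBq / meta$weight_kg
  list(
    scan = pet_scan(activity, sp),
    lesions = lesion_truth,
    liver = liver_truth
  )
}

rtnorm_upper <- function(n, mean, sd, upper) {
  # draws from N(mean, sd) truncated to (-Inf, upper]
  pu <- pnorm(upper, mean, sd)
  if (pu < 1e-10) {
    abort("infeasible truncation: essentially no mass at or below the bound.")
  }
  qnorm(runif(n, 0, pu), mean, sd)
}

trunc_norm_spec <- function(mean, sd, max = 100) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    abort("distribution spec needs finite mean and positive sd.")
  }
  list(mean = mean, sd = sd, max = max)
}

#' Synthetic cohort design
#'
#' Parameters of the paired-scan phantom cohort the analysis pipeline is
#' validated on. Defaults emulate the study population: 54 patients of whom
#' 6 relapse (~11% prevalence), responders drawing a true percentage
#' SUVmax decrease from N(92, 13) truncated at 100 and non-responders from
#' N(55, 15) truncated at 100, liver SUL N(1.8, 0.15) per voxel, and 0.1
#' SUV of additive image noise.
#'
#' @param n_patients cohort size; default 54.
#' @param n_relapse number of relapse (non-responder) patients; default 6.
#' @param delta_responders,delta_nonresponders truncated-normal specs
#'   (`list(mean, sd, max)`) of the true percentage decrease in SUVmax from
#'   staging to interim scan, truncated at 100%.
#' @param liver_sul_mean,liver_sul_sd per-voxel liver uptake on the SUL
#'   scale.
#' @param noise_sd_suv additive image noise SD, SUV units.
#' @param grid a [pet_grid()] for the phantom scans; default 64 x 64 x 80
#'   voxels at 4 mm (25.6 x 25.6 x 32 cm field of view).
#' @param background_suv uniform background SUV.
#' @param mean_extra_lesions Poisson mean of lesions beyond the first
#'   (capped at 4 per patient).
#' @param hotspot simulate one high-uptake physiological region (with a
#'   matching exclusion) in every scan? Default `TRUE`.
#' @param seed integer seed; the whole cohort (metadata, geometry, labels,
#'   every voxel) is reproducible from it.
#' @return A `cohort_design` list, input to [make_cohort()].
#' @export
cohort_design <- function(n_patients = 54L, n_relapse = 6L,
                          delta_responders = trunc_norm_spec(92, 13, 100),
                          delta_nonresponders = trunc_norm_spec(55, 15, 100),
                          liver_sul_mean = 1.8, liver_sul_sd = 0.15,
                          noise_sd_suv = 0.1,
                          grid = pet_grid(c(64L, 64L, 80L), c(4, 4, 4)),
                          background_suv = 1.0,
                          mean_extra_lesions = 0.8,
                          hotspot = TRUE,
                          seed = 20150128L) {
  n_patients <- as.integer(n_patients); n_relapse <- as.integer(n_relapse)
  if (n_patients < 1L) abort("`n_patients` must be >= 1.")
  if (n_relapse < 0L || n_relapse > n_patients) {
    abort("`n_relapse` must lie in [0, n_patients].")
  }
  for (spec in list(delta_responders, delta_nonresponders)) {
    if (pnorm(spec$max, spec$mean, spec$sd) < 1e-10) {
      abort("infeasible truncation in a delta distribution spec.")
    }
  }
  if (liver_sul_mean <= 0 || liver_sul_sd < 0) {
    abort("liver SUL parameters must be positive (mean) and non-negative (sd).")
  }
  structure(
    list(
      n_patients = n_patients, n_relapse = n_relapse,
      delta_responders = delta_responders,
      delta_nonresponders = delta_nonresponders,
      liver_sul_mean = liver_sul_mean, liver_sul_sd = liver_sul_sd,
      noise_sd_suv = noise_sd_suv, grid = grid,
      background_suv = background_suv,
      mean_extra_lesions = mean_extra_lesions,
      hotspot = hotspot,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

# Fixed anatomy of the cohort phantom, derived from the field-of-view
# extent: liver reference sphere (and a myocardium-like hotspot at the same
# axial level, laterally clear of it) near the top of the volume, lesions
# confined to an axial zone below both with enough clearance that a lesion
# plus its mask can never touch the liver or hotspot.
cohort_anatomy <- function(grid) {
  extent <- grid$dim * grid$spacing
  r_liv <- 25.75           # 5.15 cm reference sphere
  lesion_margin <- 18 + 8  # max semi-axis + mask margin
  zc <- extent[3] - r_liv - 8
  anatomy <- list(
    liver_center = c(0.35 * extent[1], 0.60 * extent[2], zc),
    hotspot_center = c(0.75 * extent[1], 0.25 * extent[2], zc),
    hotspot_radius = 16, hotspot_suv = 6,
    lesion_lo = c(28, 28, 30),
    lesion_hi = c(extent[1] - 28, extent[2] - 28,
                  zc - r_liv - lesion_margin - 4)
  )
  if (any(anatomy$lesion_hi <= anatomy$lesion_lo) ||
      !sphere_inside(grid$dim, grid$spacing, anatomy$liver_center, r_liv)) {
    abort("field of view too small for the cohort phantom anatomy; use a larger grid.")
  }
  anatomy
}

sample_patient_meta <- function(n) {
  sex <- ifelse(runif(n) < 33 / 54, "male", "female")
  age <- qnorm(runif(n, pnorm(5.9, 14.6, 3), pnorm(17.8, 14.6, 3)), 14.6, 3)
  slope <- ifelse(sex == "male", 4.3, 4.0)
  height <- 100 + slope * age + rnorm(n, 0, 6)
  bmi <- qnorm(runif(n, pnorm(14, 18.5, 2.5), pnorm(28, 18.5, 2.5)), 18.5, 2.5)
  weight <- bmi * (height / 100)^2
  dose <- 4.5 * weight * exp(rnorm(n, 0, 0.08))
  uptake <- qnorm(runif(n, pnorm(40, 71.9, 20.5), 1), 71.9, 20.5)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    sex = sex,
    age_years = age,
    weight_kg = weight,
    height_cm = height,
    injected_dose_MBq = dose,
    uptake_time_min = uptake
  )
}

sample_visual_score <- function(outcome) {
  # score distribution chosen so that score >= 3 occurs in about two thirds
  # of relapsing and ~29% of remitting patients (the visual read's observed
  # sensitivity/false-positive behaviour)
  p_relapse <- c(0.10, 0.23, 0.27, 0.25, 0.15)
  p_remiss <- c(0.38, 0.33, 0.17, 0.08, 0.04)
  vapply(outcome, function(o) {
    sample(1:5, 1L, prob = if (o == "relapse") p_relapse else p_remiss)
  }, integer(1))
}

place_lesions <- function(n_lesions, anatomy, max_tries = 400L) {
  centers <- list(); mask_r <- numeric(0); radii <- list()
  for (i in seq_len(n_lesions)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      rad <- runif(3, 6, 18)
      ctr <- runif(3, anatomy$lesion_lo, anatomy$lesion_hi)
      mr <- max(rad) + 8
      clear <- TRUE
      for (j in seq_along(centers)) {
        if (sqrt(sum((ctr - centers[[j]])^2)) < mr + mask_r[j] + 4) {
          clear <- FALSE; break
        }
      }
      if (clear) {
        centers[[i]] <- ctr; radii[[i]] <- rad; mask_r[i] <- mr
        ok <- TRUE; break
      }
    }
    if (!ok) abort("could not place non-overlapping lesions; reduce lesion count or size.")
  }
  list(centers = centers, radii = radii, mask_r = mask_r)
}

#' Generate a synthetic paired-PET cohort
#'
#' Draws patient metadata, outcome labels (exactly `n_relapse` relapses),
#' therapy-group assignments, synthetic visual (Deauville-type) interim
#' scores, lesion geometry with per-lesion masks, and each patient's true
#' percentage SUVmax decrease from the group-appropriate truncated normal.
#' Interim-scan lesion intensities are the staging intensities scaled by
#' `1 - delta/100`, so the designed decrease is exact in the noise-free
#' images. Scans themselves are realised lazily and deterministically by
#' [realize_scan()] from per-scan seeds drawn here, so a 54-patient cohort
#' object stays small; [write_cohort()] materialises everything to disk.
#'
#' @param design a [cohort_design()].
#' @return A `pet_cohort` list: `design`, `meta`, `outcomes` (outcome,
#'   therapy group, visual score), `truth` (true per-patient delta),
#'   `lesions`, `masks`, `exclusions`, `liver` (per-patient liver
#'   parameters on both SUL and SUV-bw scales), `scan_seeds`.
#' @export
make_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_patients
  set.seed(design$seed)

  meta <- sample_patient_meta(n)
  outcome <- rep("remission", n)
  if (design$n_relapse > 0) {
    outcome[sample.int(n, design$n_relapse)] <- "relapse"
  }
  tg <- sample(c("TG1", "TG2", "TG3"), n, replace = TRUE,
               prob = c(17, 13, 24) / 54)
  visual <- sample_visual_score(outcome)

  dr <- design$delta_responders; dn <- design$delta_nonresponders
  true_delta <- numeric(n)
  is_rel <- outcome == "relapse"
  true_delta[!is_rel] <- rtnorm_upper(sum(!is_rel), dr$mean, dr$sd, dr$max)
  true_delta[is_rel] <- rtnorm_upper(sum(is_rel), dn$mean, dn$sd, dn$max)

  anatomy <- cohort_anatomy(design$grid)
  n_lesions <- pmin(1L + stats::rpois(n, design$mean_extra_lesions), 4L)
  lesion_rows <- list(); mask_rows <- list()
  for (i in seq_len(n)) {
    pl <- place_lesions(n_lesions[i], anatomy)
    for (k in seq_len(n_lesions[i])) {
      peak <- min(max(exp(rnorm(1, log(8), 0.3)), 4), 16)
      profile <- if (runif(1) < 0.5) "gaussian" else "uniform"
      lab <- sprintf("%s_L%d", meta$patient_id[i], k)
      lesion_rows[[length(lesion_rows) + 1L]] <- dplyr::mutate(
        lesion_spec(pl$centers[[k]], pl$radii[[k]], peak, profile, lab),
        patient_id = meta$patient_id[i], .before = 1
      )
      mask_rows[[length(mask_rows) + 1L]] <- dplyr::mutate(
        mask_spec("sphere", pl$centers[[k]], 2 * pl$mask_r[k], lab),
        patient_id = meta$patient_id[i], .before = 1
      )
    }
  }

  exclusions <- NULL
  if (isTRUE(design$hotspot)) {
    exclusions <- exclusion_spec(
      "sphere", anatomy$hotspot_center,
      2 * (anatomy$hotspot_radius + 6), reason = "myocardium"
    )
  }

  # liver parameters per patient: design is on the SUL scale; the phantom
  # paints in SUV_bw, scaled by weight / lean body mass
  w_over_lbm <- meta$weight_kg /
    lean_body_mass(meta$weight_kg, meta$height_cm, meta$sex)
  liver <- tibble::tibble(
    patient_id = meta$patient_id,
    sul_mean = design$liver_sul_mean,
    sul_sd = design$liver_sul_sd,
    suv_bw_mean = design$liver_sul_mean * w_over_lbm,
    suv_bw_sd = design$liver_sul_sd * w_over_lbm
  )

  scan_seeds <- matrix(sample.int(.Machine$integer.max, 2L * n),
                       nrow = n, ncol = 2,
                       dimnames = list(meta$patient_id, c("pet1", "pet2")))

  structure(
    list(
      design = design,
      meta = meta,
      outcomes = tibble::tibble(
        patient_id = meta$patient_id,
        outcome = outcome,
        therapy_group = tg,
        visual_score_pet2 = visual
      ),
      truth = tibble::tibble(
        patient_id = meta$patient_id,
        outcome = outcome,
        true_delta_suvmax_pct = true_delta
      ),
      lesions = dplyr::bind_rows(lesion_rows),
      masks = dplyr::bind_rows(mask_rows),
      exclusions = exclusions,
      liver = liver,
      anatomy = anatomy,
      scan_seeds = scan_seeds
    ),
    class = "pet_cohort"
  )
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf(
    "<pet_cohort> %d patients (%d relapse), %d lesions, seed %d\n",
    nrow(x$meta), sum(x$outcomes$outcome == "relapse"),
    nrow(x$lesions), x$design$seed
  ))
  invisible(x)
}

#' Realise one phantom scan of a cohort
#'
#' Deterministically materialises the staging (`timepoint = 1`) or interim
#' (`timepoint = 2`) activity volume of one cohort patient; repeated calls
#' are bit-identical. Interim lesions are the staging lesions with peak
#' intensity scaled by `1 - true_delta/100`; liver texture and image noise
#' are redrawn per scan from per-scan seeds fixed at cohort creation.
#'
#' @param cohort a [make_cohort()] result.
#' @param patient_id patient identifier (e.g. `"P001"`).
#' @param timepoint 1 (staging) or 2 (interim).
#' @return As [make_phantom_scan()]: list with `scan`, `lesions` ground
#'   truth, `liver` realised stats.
#' @export
realize_scan <- function(cohort, patient_id, timepoint = 1L) {
  stopifnot(inherits(cohort, "pet_cohort"))
  timepoint <- as.integer(timepoint)
  if (!timepoint %in% c(1L, 2L)) abort("`timepoint` must be 1 or 2.")
  i <- match(patient_id, cohort$meta$patient_id)
  if (is.na(i)) abort(sprintf("unknown patient '%s'.", patient_id))
  meta <- cohort$meta[i, ]
  lesions <- dplyr::filter(cohort$lesions, .data$patient_id == !!patient_id)
  if (timepoint == 2L) {
    scale <- 1 - cohort$truth$true_delta_suvmax_pct[i] / 100
    lesions$peak_suv <- lesions$peak_suv * scale
  }
  design <- cohort$design
  anatomy <- cohort$anatomy
  hot <- NULL
  if (isTRUE(design$hotspot)) {
    hot <- tibble::tibble(
      center_mm = list(anatomy$hotspot_center),
      radius_mm = anatomy$hotspot_radius,
      suv = anatomy$hotspot_suv
    )
  }
  make_phantom_scan(
    meta, lesions,
    liver_mean_suv = cohort$liver$suv_bw_mean[i],
    liver_sd_suv = cohort$liver$suv_bw_sd[i],
    grid = design$grid,
    noise_sd_suv = design$noise_sd_suv,
    seed = cohort$scan_seeds[i, timepoint],
    background_suv = design$background_suv,
    liver_center_mm = anatomy$liver_center,
    hotspots = hot
  )
}
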