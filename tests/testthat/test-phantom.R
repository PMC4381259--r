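test_that("a lesion-free noise-free phantom is the uniform background", {
  ph <- make_phantom_scan(tiny_meta(), lesions = NULL,
                          grid = pet_grid(c(12, 12, 12), c(4, 4, 4)),
                          noise_sd_suv = 0, seed = 1, background_suv = 1.0)
  suv <- to_suv(ph$scan, tiny_meta(), "bw")
  expect_true(all(suv$voxels == 1.0))
  expect_equal(nrow(ph$lesions), 0)
  expect_null(ph$liver)
})

test_that("spherical-lesion ground truth matches the voxel-centre oracle", {
  # radius 10 mm sphere, 2 mm isotropic grid: MTV must equal the brute-force
  # centre-in-sphere count times 0.008 mL, SUVmax exactly the designed peak
  dims <- c(24, 24, 24); sp <- c(2, 2, 2); ctr <- c(24, 24, 24)
  les <- lesion_spec(ctr, c(10, 10, 10), 8, "uniform")
  ph <- make_phantom_scan(tiny_meta(), les, grid = pet_grid(dims, sp),
                          noise_sd_suv = 0, seed = 1)
  oracle_idx <- brute_members(dims, sp, in_sphere(ctr, 10))
  expect_equal(ph$lesions$true_suv_max, 8.0)
  expect_equal(ph$lesions$true_mtv_ml, length(oracle_idx) * 0.008)
  expect_equal(ph$lesions$n_support_voxels, length(oracle_idx))
})

test_that("noise induces a small positive, bounded SUVmax bias", {
  dims <- c(24, 24, 24); sp <- c(2, 2, 2)
  les <- lesion_spec(c(24, 24, 24), c(10, 10, 10), 8, "uniform")
  meta <- tiny_meta()
  mask <- mask_spec("sphere", c(24, 24, 24), 26)
  recovered <- vapply(1:100, function(s) {
    ph <- make_phantom_scan(meta, les, grid = pet_grid(dims, sp),
                            noise_sd_suv = 0.1, seed = s)
    suv <- to_suv(ph$scan, meta, "bw")
    measure_lesions(suv, mask, 2.5)$suv_max
  }, numeric(1))
  m <- mean(recovered)
  expect_gte(m, 8.0)
  expect_lte(m, 8.0 + 4 * 0.1)
})

test_that("phantom construction rejects invalid geometry", {
  g <- pet_grid(c(16, 16, 16), c(4, 4, 4))
  outside <- lesion_spec(c(60, 60, 60), c(10, 10, 10), 8)
  expect_error(make_phantom_scan(tiny_meta(), outside, grid = g,
                                 seed = 1), "outside")
  overlapping <- lesion_spec(c(32, 32, 32), c(12, 12, 12), 8)
  expect_error(
    make_phantom_scan(tiny_meta(), overlapping, liver_mean_suv = 1.8,
                      liver_sd_suv = 0.1, grid = g, seed = 1,
                      liver_center_mm = c(32, 32, 32)),
    "overlap"
  )
  expect_error(pet_grid(c(16, 16, 16), c(4, -4, 4)), "positive")
})

test_that("cohort labels balance exactly and reproduce bit-identically", {
  d <- cohort_design(n_patients = 10, n_relapse = 3, seed = 99,
                     grid = pet_grid(c(24, 24, 32), c(4, 4, 4)),
                     mean_extra_lesions = 0)
  co1 <- make_cohort(d)
  co2 <- make_cohort(d)
  expect_equal(sum(co1$outcomes$outcome == "relapse"), 3)
  expect_identical(co1$outcomes, co2$outcomes)
  expect_identical(co1$meta, co2$meta)
  expect_identical(co1$truth, co2$truth)
  s1 <- realize_scan(co1, "P004", 2)
  s2 <- realize_scan(co2, "P004", 2)
  expect_identical(s1$scan$activity, s2$scan$activity)

  # all-remission design still generates
  co0 <- make_cohort(cohort_design(n_patients = 5, n_relapse = 0, seed = 1,
                                   grid = pet_grid(c(24, 24, 32), c(4, 4, 4)),
                                   mean_extra_lesions = 0))
  expect_true(all(co0$outcomes$outcome == "remission"))
})

test_that("the default design carries the study prevalence of 6 in 54", {
  co <- make_cohort(cohort_design(seed = 2))
  expect_equal(nrow(co$meta), 54)
  expect_equal(sum(co$outcomes$outcome == "relapse"), 6)
  expect_equal(sum(co$outcomes$outcome == "remission"), 48)
  expect_true(all(co$meta$age_years >= 1 & co$meta$age_years <= 18))
  expect_true(all(co$meta$weight_kg > 0 & co$meta$height_cm > 0 &
                    co$meta$injected_dose_MBq > 0))
})

test_that("designed delta distributions are recovered in large cohorts", {
  d <- cohort_design(
    n_patients = 1000, n_relapse = 500,
    delta_responders = petresponse:::trunc_norm_spec(92, 5, 100),
    delta_nonresponders = petresponse:::trunc_norm_spec(55, 15, 100),
    grid = pet_grid(c(24, 24, 32), c(4, 4, 4)),
    mean_extra_lesions = 0, seed = 31
  )
  co <- make_cohort(d)
  resp <- co$truth$true_delta_suvmax_pct[co$truth$outcome == "remission"]
  nonr <- co$truth$true_delta_suvmax_pct[co$truth$outcome == "relapse"]
  expect_true(all(co$truth$true_delta_suvmax_pct <= 100))
  m_resp <- trunc_norm_mean(92, 5, 100)
  m_nonr <- trunc_norm_mean(55, 15, 100)
  expect_lt(abs(mean(resp) - m_resp), 3 * sd(resp) / sqrt(length(resp)))
  expect_lt(abs(mean(nonr) - m_nonr), 3 * sd(nonr) / sqrt(length(nonr)))
})

test_that("infeasible truncation is rejected", {
  expect_error(
    cohort_design(delta_responders = petresponse:::trunc_norm_spec(200, 1, 100)),
    "truncation"
  )
  expect_error(petresponse:::rtnorm_upper(5, 200, 1, 100), "truncation")
})

test_that("noise-free phantom measurements equal the ground-truth table", {
  d <- cohort_design(n_patients = 4, n_relapse = 2, noise_sd_suv = 0,
                     grid = pet_grid(c(40, 40, 48), c(4, 4, 4)), seed = 17)
  co <- make_cohort(d)
  for (pid in co$meta$patient_id) {
    ph <- realize_scan(co, pid, 1)
    suv <- to_suv(ph$scan, co$meta[co$meta$patient_id == pid, ], "bw")
    masks <- dplyr::filter(co$masks, patient_id == pid)
    got <- measure_lesions(suv, masks, 2.5, co$exclusions)
    truth <- ph$lesions[match(got$lesion_label, ph$lesions$label), ]
    expect_equal(got$suv_max, truth$true_suv_max, tolerance = 1e-12)
    expect_equal(got$mtv_ml, truth$true_mtv_ml, tolerance = 1e-12)
  }
})
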