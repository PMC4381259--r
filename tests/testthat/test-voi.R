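test_that("segmentation of a sub-threshold image is empty, outside masks error", {
  img <- uniform_suv(1.0)
  m <- mask_spec("sphere", c(32, 32, 32), 40)
  voi <- isocontour_voi(img, m, 2.5)
  expect_length(voi, 0)
  res <- voi_metrics(img, voi, threshold = 2.5)
  expect_equal(res$mtv_ml, 0)
  expect_equal(res$tlg_g, 0)
  expect_true(res$below_threshold)
  expect_equal(res$suv_max, 1.0) # reported over the mask, flagged
  expect_error(isocontour_voi(img, mask_spec("sphere", c(500, 500, 500), 20),
                              2.5), "intersect")
})

test_that("a uniform lesion segments to exactly its voxel set, minus exclusions", {
  dims <- c(24, 24, 24); sp <- c(2, 2, 2); ctr <- c(24, 24, 24)
  ph <- make_phantom_scan(tiny_meta(),
                          lesion_spec(ctr, c(10, 10, 10), 8, "uniform"),
                          grid = pet_grid(dims, sp), noise_sd_suv = 0,
                          seed = 1)
  suv <- to_suv(ph$scan, tiny_meta(), "bw")
  m <- mask_spec("sphere", ctr, 30)
  voi <- isocontour_voi(suv, m, 2.5)
  oracle <- brute_members(dims, sp, in_sphere(ctr, 10))
  expect_setequal(as.integer(voi), oracle)

  excl <- exclusion_spec("box", ctr + c(6, 0, 0), c(12, 40, 40), reason = "other")
  voi_ex <- isocontour_voi(suv, m, 2.5, exclusions = excl)
  excluded_oracle <- brute_members(dims, sp, function(p) {
    in_sphere(ctr, 10)(p) && in_box(ctr + c(6, 0, 0), c(12, 40, 40))(p)
  })
  expect_length(voi_ex, length(oracle) - length(excluded_oracle))
})

test_that("VOI metric arithmetic: volumes, TLG product, falloff means", {
  # 100 voxels at 4 mm -> 6.4 mL; uniform SUV 8 -> TLG 51.2 g
  img <- uniform_suv(8, dim = c(10, 10, 1), spacing = c(4, 4, 4))
  voi <- seq_len(100)
  res <- voi_metrics(img, voi, threshold = 2.5)
  expect_equal(res$mtv_ml, 6.4)
  expect_equal(res$tlg_g, 51.2)
  expect_equal(res$suv_mean, res$suv_max)

  ph <- make_phantom_scan(tiny_meta(),
                          lesion_spec(c(24, 24, 24), c(12, 12, 12), 10,
                                      "gaussian"),
                          grid = pet_grid(c(24, 24, 24), c(2, 2, 2)),
                          noise_sd_suv = 0, seed = 1)
  suv <- to_suv(ph$scan, tiny_meta(), "bw")
  res2 <- measure_lesions(suv, mask_spec("sphere", c(24, 24, 24), 32), 2.5)
  expect_lt(res2$suv_mean, res2$suv_max)
  expect_equal(res2$tlg_g, res2$suv_mean * res2$mtv_ml)
})

test_that("raising the threshold never grows the VOI, MTV or TLG", {
  set.seed(11)
  img <- uniform_suv(0, dim = c(16, 16, 16))
  img$voxels[] <- runif(length(img$voxels), 0, 6)
  m <- mask_spec("box", c(32, 32, 32), c(48, 48, 48))
  prev <- NULL
  for (thr in c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5)) {
    voi <- isocontour_voi(img, m, thr)
    res <- voi_metrics(img, voi, threshold = thr)
    if (!is.null(prev)) {
      expect_lte(length(voi), prev$n)
      expect_lte(res$mtv_ml, prev$mtv)
      expect_lte(res$tlg_g, prev$tlg)
    }
    prev <- list(n = length(voi), mtv = res$mtv_ml, tlg = res$tlg_g)
  }
})

test_that("vectorised segmentation equals the exhaustive membership oracle", {
  set.seed(23)
  for (rep in 1:6) {
    dims <- sample(10:20, 3, replace = TRUE)
    sp <- runif(3, 1.5, 4.5)
    img <- petresponse:::new_suv_image(
      array(runif(prod(dims), 0, 5), dims), sp, "bw"
    )
    extent <- dims * sp
    ctr <- runif(3, 0.25, 0.75) * extent
    shape <- sample(c("sphere", "box", "cylinder"), 1)
    size <- switch(shape,
      sphere = runif(1, 10, min(extent) * 0.8),
      box = runif(3, 8, extent * 0.6),
      cylinder = c(runif(1, 10, min(extent[1:2]) * 0.7),
                   runif(1, 8, extent[3] * 0.6))
    )
    thr <- runif(1, 1, 4)
    m <- mask_spec(shape, ctr, size)
    voi <- isocontour_voi(img, m, thr)
    member <- switch(shape,
      sphere = in_sphere(ctr, size / 2),
      box = in_box(ctr, size),
      cylinder = in_cylinder(ctr, size[1], size[2])
    )
    oracle <- brute_members(dims, sp, member)
    oracle <- oracle[img$voxels[oracle] > thr]
    expect_setequal(as.integer(voi), oracle)
  }
})

test_that("follow-up masks measure identically placed VOIs", {
  ctr <- c(24, 24, 24)
  ph1 <- make_phantom_scan(tiny_meta(),
                           lesion_spec(ctr, c(10, 10, 10), 8, "uniform"),
                           grid = pet_grid(c(24, 24, 24), c(2, 2, 2)),
                           noise_sd_suv = 0, seed = 1)
  suv1 <- to_suv(ph1$scan, tiny_meta(), "bw")
  masks <- mask_spec("sphere", ctr, 30)
  r1 <- measure_lesions(suv1, masks, 2.5)

  # identical follow-up reproduces the staging result
  same <- apply_masks_to_followup(suv1, masks, 2.5, reference = suv1)
  expect_equal(same, r1)

  # halved uptake: SUVmax 4, identical voxel set for a uniform lesion
  suv_half <- petresponse:::new_suv_image(suv1$voxels * 0.5, suv1$spacing, "bw")
  r2 <- apply_masks_to_followup(suv_half, masks, 2.5, reference = suv1)
  expect_equal(r2$suv_max, 4.0)
  expect_equal(r2$mtv_ml, r1$mtv_ml)

  # scaled below threshold everywhere: zero MTV and TLG
  suv_low <- petresponse:::new_suv_image(suv1$voxels * 0.2, suv1$spacing, "bw")
  r3 <- apply_masks_to_followup(suv_low, masks, 2.5, reference = suv1)
  expect_equal(r3$mtv_ml, 0)
  expect_equal(r3$tlg_g, 0)
  expect_true(r3$below_threshold)

  # geometry mismatch is refused
  other <- uniform_suv(1, dim = c(10, 10, 10))
  expect_error(apply_masks_to_followup(other, masks, 2.5, reference = suv1),
               "geometry")
})

test_that("patient aggregation preserves the TLG identity and maxima", {
  img <- uniform_suv(0, dim = c(20, 20, 20))
  set.seed(3)
  img$voxels[] <- runif(length(img$voxels), 0, 1)
  img$voxels[1:50] <- 6; img$voxels[2001:2030] <- 9
  m1 <- mask_spec("box", c(10, 6, 4), c(40, 40, 20), label = "L1")
  res <- measure_lesions(img, dplyr::bind_rows(
    m1, mask_spec("box", c(40, 60, 24), c(78, 78, 40), label = "L2")
  ), 2.5)
  agg <- aggregate_lesions(res)
  expect_equal(agg$suv_max, max(res$suv_max))
  expect_equal(agg$mtv_ml, sum(res$mtv_ml))
  expect_equal(agg$tlg_g, sum(res$tlg_g))
  expect_equal(agg$tlg_g, agg$suv_mean * agg$mtv_ml)
})
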