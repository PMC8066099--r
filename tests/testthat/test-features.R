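test_that("first-order statistics follow population conventions", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)      # denominator n
  expect_equal(f[["sd"]], sqrt(1.25))
  expect_equal(f[["median"]], 2.5)
  expect_equal(f[["range"]], 3)
  expect_equal(f[["rms"]], sqrt(mean(c(1, 4, 9, 16))))

  # degenerate constant distribution
  fc <- first_order_features(rep(3, 10))
  expect_equal(fc[["mean"]], 3)
  expect_equal(fc[["sd"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["uniformity"]], 1)
  expect_equal(fc[["energy"]], 10 * 9)

  # symmetric sample -> zero skewness; Pearson kurtosis near 3 for a normal
  sym <- c(-3, -1, -1, 0, 0, 1, 1, 3)
  expect_lt(abs(first_order_features(sym)[["skewness"]]), 1e-12)
  z <- withr::with_seed(5, rnorm(2e4))
  expect_equal(first_order_features(z)[["kurtosis"]], 3, tolerance = 0.15)

  # permutation invariance over the ROI multiset
  x <- withr::with_seed(9, rnorm(500))
  expect_equal(first_order_features(x),
               first_order_features(withr::with_seed(1, sample(x))))

  expect_true(all(is.na(first_order_features(numeric(0)))))
})

test_that("GLCM is a symmetric probability matrix with hand-checkable entries", {
  # hand-enumerated 2x2 example, horizontal direction only, 2 grey levels
  m <- rbind(c(1, 1), c(2, 2))
  p <- glcm_matrix(array(m, c(2, 2, 1)), array(TRUE, c(2, 2, 1)),
                   n_bins = 2, directions = "horizontal")
  expect_equal(p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(glcm_stats(p)[["contrast"]], 0)

  # symmetry and unit mass on random volumes
  for (seed in 1:4) {
    v <- tiny_volume(seed = seed)
    p <- glcm_matrix(v$intensities, v$mask, n_bins = 16)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p), tolerance = 1e-12)
  }

  # constant region: single diagonal cell, no texture
  vc <- slice_volume(matrix(4, 6, 6))
  g <- glcm_features(vc$intensities, vc$mask, n_bins = 8)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["cluster_shade"]], 0)
  expect_equal(g[["energy"]], 1)

  # fewer than 2 voxels -> missing sentinel
  lone <- array(c(TRUE, rep(FALSE, 35)), c(6, 6, 1))
  expect_true(all(is.na(glcm_features(vc$intensities, lone, n_bins = 8))))
})

test_that("cluster shade vanishes for symmetric co-occurrence structure and flips sign under negation", {
  # brute force over random matrices: mirroring grey levels negates the shade,
  # and the symmetrised matrix has shade 0
  for (seed in 1:20) {
    q <- withr::with_seed(seed, matrix(runif(16), 4, 4))
    q <- (q + t(q)) / 2; q <- q / sum(q)            # valid symmetric GLCM
    qr <- q[4:1, 4:1]                               # grey-level negation
    expect_equal(glcm_stats(qr)[["cluster_shade"]],
                 -glcm_stats(q)[["cluster_shade"]], tolerance = 1e-12)
    sym <- (q + qr) / 2                             # symmetric about the mean level
    expect_lt(abs(glcm_stats(sym)[["cluster_shade"]]), 1e-12)
  }

  # at the image level: negating intensities flips the shade sign
  v <- tiny_volume(seed = 21)
  g1 <- glcm_features(v$intensities, v$mask, n_bins = 16)
  g2 <- glcm_features(-v$intensities, v$mask, n_bins = 16)
  expect_equal(g2[["cluster_shade"]], -g1[["cluster_shade"]], tolerance = 1e-8)
})

test_that("box-counting dimension recovers plane, line and point geometry", {
  filled <- matrix(TRUE, 64, 64)
  expect_equal(box_count_dimension(filled), 2, tolerance = 0.1)

  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  expect_equal(box_count_dimension(line), 1, tolerance = 0.1)

  point <- matrix(FALSE, 16, 16); point[5, 7] <- TRUE
  expect_identical(box_count_dimension(point), 0)

  # dimension bounded by the planar embedding for arbitrary masks
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(runif(32 * 32) < 0.3, 32, 32))
    d <- box_count_dimension(m)
    expect_gte(d, 0); expect_lte(d, 2)
  }

  expect_true(is.na(box_count_dimension(matrix(FALSE, 8, 8))))

  msk <- array(FALSE, c(70, 70, 3))
  msk[3:66, 3:66, 1] <- TRUE   # near-filled slice
  msk[10, 10:40, 2] <- TRUE    # line slice
  fr <- fractal_features(msk)
  expect_equal(fr[["fd_max"]], 2, tolerance = 0.1)
  expect_true(fr[["fd_mean"]] < fr[["fd_max"]])
})

test_that("morphology features: volume, diameter and component count", {
  single <- array(FALSE, c(5, 5, 1)); single[3, 3, 1] <- TRUE
  m <- morphology_features(single, c(1, 1, 1))
  expect_equal(m[["volume_mm3"]], 1)
  expect_equal(m[["n_components"]], 1)

  block <- array(FALSE, c(14, 14, 1)); block[3:12, 3:12, 1] <- TRUE
  mb <- morphology_features(block, c(1, 1, 1))
  expect_equal(mb[["volume_mm3"]], 100)
  expect_equal(mb[["max_planar_diameter_mm"]], sqrt(162))  # corner to corner

  blobs <- array(FALSE, c(12, 12, 1))
  blobs[2:3, 2:3, 1] <- TRUE; blobs[8:10, 8:10, 1] <- TRUE
  expect_equal(morphology_features(blobs, c(1, 1, 1))[["n_components"]], 2)

  # diagonal touching counts as one 8-connected component
  diag2 <- array(FALSE, c(6, 6, 1)); diag2[2, 2, 1] <- TRUE; diag2[3, 3, 1] <- TRUE
  expect_equal(morphology_features(diag2, c(1, 1, 1))[["n_components"]], 1)
})

test_that("the assembled bank matches its configured census and is deterministic", {
  cfg <- bank_config(ib_step_pct = 20)
  expect_identical(bank_census(cfg), 13L * 18L + 15L * 15L)
  expect_identical(bank_census(bank_config()), 13L * 18L + 55L * 15L)

  v <- tiny_volume(n = 24, slices = 3, seed = 8)
  fb <- extract_bank(v, cfg)
  expect_length(fb, bank_census(cfg))
  expect_false(anyDuplicated(names(fb)) > 0)
  expect_identical(fb, extract_bank(v, cfg))

  info <- parse_feature_ids(names(fb))
  expect_setequal(unique(info$filter), c("log", "ib"))
  expect_identical(sum(info$filter == "log"), 13L * 18L)
  # family assignment: first-order only behind LoG; texture families behind IB
  expect_true(all(info$family[info$filter == "log"] == "first_order"))
  expect_setequal(unique(info$family[info$filter == "ib"]),
                  c("glcm", "fractal", "morphology"))
})

test_that("texture differences move GLCM/fractal features but not mask morphology", {
  base <- list(n_cases = 2, grid_shape = c(28L, 28L, 8L),
               voxel_spacing_mm = c(1, 1, 3), lesion_radius_mm = 8,
               noise_sd = 5, seed = 13L)
  sp_smooth <- do.call(phantom_spec, c(base, list(
    texture_correlation_length_mm = c(neg = 4, pos = 4),
    intensity_shape = c(neg = 0, pos = 0))))
  sp_rough <- do.call(phantom_spec, c(base, list(
    texture_correlation_length_mm = c(neg = 1, pos = 1),
    intensity_shape = c(neg = 0, pos = 0))))
  v_smooth <- generate_cohort(sp_smooth)$cases[[1]]
  v_rough <- generate_cohort(sp_rough)$cases[[1]]

  cfg <- bank_config(ib_step_pct = 50)  # pairs (0,50),(0,100),(50,100)
  f_smooth <- extract_bank(v_smooth, cfg)
  f_rough <- extract_bank(v_rough, cfg)
  # same lesion geometry: morphology under the full-ROI pair is identical
  expect_equal(f_smooth[grep("^ib:0:100:morphology", names(f_smooth))],
               f_rough[grep("^ib:0:100:morphology", names(f_rough))])
  # texture features differ well beyond numerical noise
  expect_gt(abs(f_smooth[["ib:0:100:glcm:contrast"]] -
                f_rough[["ib:0:100:glcm:contrast"]]), 0.5)
})
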