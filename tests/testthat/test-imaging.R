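test_that("LoG scale grid spans 0 to 4.2 mm in 0.35 mm steps", {
  g <- sigma_grid()
  expect_length(g, 13)
  expect_identical(g[1], 0)
  expect_equal(g[length(g)], 4.2)
  expect_equal(unique(round(diff(g), 10)), 0.35)
})

test_that("planar resampling maps sizes by physical extent and preserves constants", {
  v <- tiny_volume(n = 20, spacing = c(0.548, 0.548, 3))
  expect_identical(resample_planar(v, 0.548), v)   # no-op at target spacing

  v2 <- tiny_volume(n = 50, spacing = c(1.096, 1.096, 3))
  r <- resample_planar(v2, 0.548)
  # independent coordinate check: new size = round(n * old / new)
  expect_identical(dim(r$intensities)[1:2], c(100L, 100L))
  expect_equal(r$spacing_mm, c(0.548, 0.548, 3))
  expect_identical(dim(r$mask), dim(r$intensities))

  # constant volume -> constant output with the same value, exactly
  vc <- volume_with_mask(array(7, c(12, 12, 2)), c(1.3, 1.3, 3),
                         array(TRUE, c(12, 12, 2)))
  rc <- resample_planar(vc, 0.5)
  expect_true(all(rc$intensities == 7))
  # and the round trip back to the original spacing stays constant
  back <- resample_planar(rc, 1.3)
  expect_true(all(back$intensities == 7))

  degenerate <- volume_with_mask(array(1, c(1, 1, 2)), c(1, 1, 1),
                                 array(TRUE, c(1, 1, 2)))
  expect_error(resample_planar(degenerate, 0.5), "degenerate")
})

test_that("LoG filter: sigma 0 is the identity, constants vanish, impulse equals the kernel", {
  v <- tiny_volume()
  expect_identical(log_filter(v, 0), v)
  expect_error(log_filter(v, -1), "nonnegative")

  vc <- volume_with_mask(array(50, c(30, 30, 1)), c(0.548, 0.548, 3),
                         array(TRUE, c(30, 30, 1)))
  fc <- log_filter(vc, 1.05)
  expect_lt(max(abs(fc$intensities)), 1e-6 * 50)

  # single bright pixel: response must equal the discrete LoG kernel,
  # verified against a direct double-loop convolution oracle
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  vi <- slice_volume(imp, spacing = c(0.548, 0.548, 3))
  out <- log_filter(vi, 0.7)$intensities[, , 1]
  k <- log_kernel(0.7, c(0.548, 0.548))
  expect_equal(out, direct_conv2d(imp, k), tolerance = 1e-10)
  r <- (nrow(k) - 1) / 2
  expect_equal(out[(11 - r):(11 + r), (11 - r):(11 + r)], unname(k),
               tolerance = 1e-10)

  # homogeneity: response is linear in the input intensities
  f1 <- log_filter(v, 1.4)$intensities
  v2 <- v; v2$intensities <- 2 * v$intensities
  f2 <- log_filter(v2, 1.4)$intensities
  expect_equal(f2, 2 * f1, tolerance = 1e-9)
})

test_that("IB normalisation maps the 1st/99th ROI percentiles onto [0, 1]", {
  n <- 40
  vals <- seq(10, 20, length.out = n * n)
  v <- slice_volume(matrix(vals, n, n))
  nv <- ib_normalize(v)
  mid <- nv$intensities[which.min(abs(v$intensities - 15))]
  expect_equal(mid, 0.5, tolerance = 0.02)
  expect_equal(min(roi_values(nv)), 0)      # below the 1st percentile clips to 0
  expect_equal(max(roi_values(nv)), 1)

  two <- slice_volume(matrix(c(0, 100), 2, 2))
  expect_setequal(unique(roi_values(ib_normalize(two))), c(0, 1))

  const <- slice_volume(matrix(5, 4, 4))
  expect_error(ib_normalize(const), "degenerate")
})

test_that("IB threshold pairs enumerate all ordered level combinations", {
  p <- ib_threshold_pairs()
  expect_identical(nrow(p), 55L)
  # independent enumeration oracle over the 11 levels
  count <- 0L
  for (l in seq(0, 100, 10)) for (u in seq(0, 100, 10)) if (l < u) count <- count + 1L
  expect_identical(nrow(p), count)
  expect_identical(count, choose(11, 2) |> as.integer())
  expect_true(all(p$lower_pct < p$upper_pct))
  expect_false(any(p$lower_pct == p$upper_pct))
  expect_identical(nrow(ib_threshold_pairs(20)), 15L)
})

test_that("subpopulation masks select the normalised intensity interval", {
  v <- tiny_volume(n = 30, seed = 11)
  nv <- ib_normalize(v)
  expect_identical(subpopulation_mask(nv, 0, 100), nv$mask)

  # constant 0.5 inside the interval or outside it entirely
  half <- nv; half$intensities[half$mask] <- 0.5
  expect_identical(subpopulation_mask(half, 20, 60), half$mask)
  expect_false(any(subpopulation_mask(half, 60, 100)))

  # uniformly distributed normalised values: interval mass ~ width
  nvox <- 10000
  u <- withr::with_seed(3, runif(nvox))
  vu <- slice_volume(matrix(u, 100, 100))
  vu$intensities <- vu$intensities   # already in [0,1]; treat as normalised
  frac <- sum(subpopulation_mask(vu, 20, 60)) / nvox
  expect_equal(frac, 0.4, tolerance = 0.03)

  # adjacent 10%-wide pairs cover the whole ROI
  covered <- array(FALSE, dim(nv$mask))
  for (l in seq(0, 90, 10))
    covered <- covered | subpopulation_mask(nv, l, l + 10)
  expect_identical(covered, nv$mask)
})
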