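test_that("denoising preserves constants and the zero-kernel is identity", {
  vol <- ct_volume(array(-800, c(16, 16, 16)), spacing = 0.6)
  sm <- denoise_volume(vol, 1.0)
  expect_equal(sm$voxels, vol$voxels, tolerance = 1e-10)
  noisy <- ct_volume(array(rnorm(16^3, -800, 50), c(16, 16, 16)), spacing = 0.6)
  expect_identical(denoise_volume(noisy, 0)$voxels, noisy$voxels)
  expect_error(denoise_volume(noisy, -0.5), class = "copdct_parameter_error")
})

test_that("denoising reduces masked variance without shifting the mean", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 48), spacing = 0.5,
                                      noise_sd = 60), seed = 9)
  sm <- denoise_volume(ph$insp, 1.0, mask = ph$mask)
  before <- ph$insp$voxels[ph$mask]
  after <- sm$voxels[ph$mask]
  expect_lt(var(after), var(before))
  expect_lt(abs(mean(after) - mean(before)), 1)
})

test_that("density metrics count voxels below the threshold", {
  arr <- array(-800, c(10, 10, 10))
  arr[1:50] <- -1000
  insp <- ct_volume(arr, spacing = 1, phase = "inspiratory")
  expv <- ct_volume(arr * 0.875, spacing = 1, phase = "expiratory")
  mask <- array(TRUE, c(10, 10, 10))
  m <- compute_density_metrics(insp, expv, mask, mask)
  expect_equal(m$in950, 5.0)
  expect_equal(m$ei_ratio, 0.875, tolerance = 1e-12)
  expect_equal(m$volume_insp_l, 1000 / 1e6)
})

test_that("the -950 threshold is strict and monotone", {
  arr <- array(-800, c(8, 8, 8))
  arr[1:64] <- -950       # exactly at the threshold: not counted
  arr[65:128] <- -950.01  # just below: counted
  vol <- ct_volume(arr, spacing = 1)
  mask <- array(TRUE, dim(arr))
  m <- compute_density_metrics(vol, vol, mask, mask)
  expect_equal(m$in950, 100 * 64 / 512)
  # monotone non-decreasing in the threshold
  thresholds <- c(-1000, -951, -950, -949, -900, -800)
  vals <- vapply(thresholds, function(t)
    compute_density_metrics(vol, vol, mask, mask, threshold_hu = t)$in950,
    numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("metrics are invariant to voxel enumeration order", {
  set.seed(4)
  arr <- array(rnorm(512, -850, 80), c(8, 8, 8))
  mask <- array(runif(512) < 0.7, c(8, 8, 8))
  vol <- ct_volume(arr, spacing = 1)
  perm <- sample(512)
  vol2 <- ct_volume(array(arr[perm], c(8, 8, 8)), spacing = 1)
  mask2 <- array(mask[perm], c(8, 8, 8))
  m1 <- compute_density_metrics(vol, vol, mask, mask)
  m2 <- compute_density_metrics(vol2, vol2, mask2, mask2)
  expect_equal(m1$in950, m2$in950)
  expect_equal(m1$mld_insp, m2$mld_insp)
})

test_that("degenerate masks are rejected", {
  vol <- ct_volume(array(-800, c(8, 8, 8)), spacing = 1)
  empty <- array(FALSE, c(8, 8, 8))
  full <- array(TRUE, c(8, 8, 8))
  expect_error(compute_density_metrics(vol, vol, empty, full),
               class = "copdct_degenerate_input_error")
  expect_error(compute_density_metrics(vol, vol, full, array(TRUE, c(4, 4, 4))),
               class = "copdct_input_error")
})
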