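test_that("phantom generation is deterministic and conserves the lung mask", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), spacing = 0.5,
                       emphysema_fraction = 0.08, noise_sd = 20)
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  expect_identical(a$insp$voxels, b$insp$voxels)
  expect_identical(a$exp$voxels, b$exp$voxels)
  expect_identical(a$mask, b$mask)
  expect_equal(sum(a$mask), a$truth$n_lung)
  # realized emphysema fraction exact to one voxel
  n_emph <- round(0.08 * a$truth$n_lung)
  expect_equal(a$truth$true_emphysema_fraction * a$truth$n_lung, n_emph)
})

test_that("zero emphysema fraction gives a zero emphysema index", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                      lung_hu_insp = -850, lung_hu_exp = -700,
                                      emphysema_fraction = 0, noise_sd = 0),
                         seed = 1)
  m <- compute_density_metrics(ph$insp, ph$exp, ph$mask, ph$mask)
  expect_identical(m$in950, 0)
})

test_that("emphysema fraction and E/I ratio are hit by construction", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64), spacing = 0.5,
                                      lung_hu_insp = -875, lung_hu_exp = -700,
                                      emphysema_fraction = 0.10, noise_sd = 0),
                         seed = 3)
  m <- compute_density_metrics(ph$insp, ph$exp, ph$mask, ph$mask)
  expect_lt(abs(m$in950 - 10), 0.5)
  expect_lt(abs(m$ei_ratio - 0.80), 0.005)
  expect_equal(ph$truth$ei_ratio, 0.80, tolerance = 1e-12)
  expect_equal(m$mld_insp, ph$truth$mld_insp, tolerance = 1e-9)
})

test_that("tube ground truth matches closed forms and rasterized volume", {
  ph <- long_tube_phantom()
  tb <- ph$truth$tubes[[1]]
  expect_equal(tb$lumen_perimeter_mm, 2 * pi * 2, tolerance = 1e-12)
  expect_equal(tb$wall_area_mm2, pi * (3^2 - 2^2), tolerance = 1e-12)
  # rasterized lumen voxel count close to the analytic capsule volume
  # (distance to the axis segment rounds the tube ends)
  analytic <- (pi * 2^2 * 50 + 4 / 3 * pi * 2^3) / (0.4^3)
  expect_lt(abs(tb$lumen_voxel_count - analytic) / analytic, 0.05)
})

test_that("invalid phantom geometry and parameters are rejected", {
  too_big <- tube_spec(start = c(2, 2, 2), end = c(30, 30, 30),
                       lumen_radius = 3, wall_thickness = 1)
  expect_error(generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                             spacing = 0.5,
                                             tubes = list(too_big)), seed = 1),
               class = "copdct_geometry_error")
  expect_error(phantom_spec(emphysema_fraction = 1.2),
               class = "copdct_config_error")
  expect_error(phantom_spec(noise_sd = -1), class = "copdct_config_error")
  expect_error(phantom_spec(lung_hu_insp = -700, lung_hu_exp = -875),
               class = "copdct_config_error")
  expect_error(tube_spec(c(0, 0, 0), c(1, 1, 1), lumen_radius = 1,
                         wall_thickness = 1, lumen_hu = 0, wall_hu = -100),
               class = "copdct_config_error")
})
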