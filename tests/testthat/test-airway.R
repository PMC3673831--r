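test_that("region growing recovers a straight tube lumen without leaking", {
  ph <- long_tube_phantom()
  lum <- segment_lumen(ph$insp, c(12.8, 12.8, 4))
  truth <- ph$truth$tubes[[1]]$lumen_voxel_count
  expect_lt(abs(sum(lum) - truth) / truth, 0.05)
  expect_false(attr(lum, "failed"))
  expect_error(segment_lumen(ph$insp, c(12.8, 12.8 + 2.5, 25)),  # wall material
               class = "copdct_seed_error")
})

test_that("region growing reaches both children of a bifurcating tree", {
  ph <- y_phantom()
  lum <- segment_lumen(ph$insp, c(12.8, 12.8, 4))
  sp <- ph$insp$spacing
  at <- function(p) {
    ci <- pmax(1L, pmin(dim(lum), ceiling(p / sp)))
    lum[ci[1], ci[2], ci[3]]
  }
  expect_true(at(c(7.8, 12.8, 20.3)))   # end of child 1
  expect_true(at(c(17.8, 12.8, 20.3)))  # end of child 2
})

test_that("centerline of a 50-mm tube is one branch of about 50 mm", {
  ph <- long_tube_phantom()
  lum <- segment_lumen(ph$insp, c(12.8, 12.8, 4))
  tree <- extract_centerline(lum, ph$insp$spacing,
                             seed_point = c(12.8, 12.8, 4))
  expect_equal(nrow(tree$branches), 1L)
  expect_lt(abs(tree$branches$length_mm - 50) / 50, 0.10)
  # deterministic re-extraction
  tree2 <- extract_centerline(lum, ph$insp$spacing,
                              seed_point = c(12.8, 12.8, 4))
  expect_identical(tree$nodes, tree2$nodes)
})

test_that("a Y phantom yields three branches, one bifurcation, labels 0/1/1", {
  ph <- y_phantom()
  lum <- segment_lumen(ph$insp, c(12.8, 12.8, 4))
  tree <- extract_centerline(lum, ph$insp$spacing,
                             seed_point = c(12.8, 12.8, 4))
  expect_equal(nrow(tree$branches), 3L)
  expect_equal(nrow(tree$bifurcations), 1L)
  expect_equal(sort(tree$branches$generation_label), c(0L, 1L, 1L))
})

test_that("masks without interior are rejected", {
  thin <- array(FALSE, c(16, 16, 16))
  thin[, , 8] <- TRUE  # one-voxel-thick plane
  expect_error(extract_centerline(thin, 0.5, seed_point = c(4, 4, 4)),
               class = "copdct_degenerate_mask_error")
  expect_error(extract_centerline(array(FALSE, c(8, 8, 8)), 0.5,
                                  seed_point = c(1, 1, 1)),
               class = "copdct_degenerate_input_error")
})

test_that("cross-section sampling respects spacing and the local axis", {
  axis_pts <- cbind(12.8, 12.8, seq(0, 50, by = 0.5))
  tree <- airway_tree_from_polylines(list(axis_pts))
  s1 <- sample_cross_sections(tree, 1.0)
  expect_gte(nrow(s1), 49)
  expect_lte(nrow(s1), 51)
  expect_true(all(abs(s1$nz) > 0.99))
  s2 <- sample_cross_sections(tree, 2.0)
  expect_lte(abs(nrow(s2) - nrow(s1) / 2), 1.5)
  short <- airway_tree_from_polylines(list(cbind(c(0, 0.3), c(0, 0), c(0, 0.1))))
  expect_equal(nrow(sample_cross_sections(short, 1.0)), 0L)
})

test_that("ray-cast wall measurement recovers tube geometry", {
  ph <- wall_phantom()
  tb <- ph$truth$tubes[[2]]  # lumen radius 2.5 mm, wall 1.0 mm
  mid <- tb$centerline[nrow(tb$centerline) %/% 2, ]
  u <- tb$centerline[nrow(tb$centerline), ] - tb$centerline[1, ]
  u <- u / sqrt(sum(u^2))
  w <- measure_wall(ph$insp, mid, u)
  expect_equal(w$status, "valid")
  expect_lt(abs(w$pi_mm - tb$lumen_perimeter_mm) / tb$lumen_perimeter_mm, 0.05)
  expect_lt(abs(w$wa_mm2 - tb$wall_area_mm2) / tb$wall_area_mm2, 0.07)
  expect_true(all(w$outer_radius_mm >= w$inner_radius_mm, na.rm = TRUE))
})

test_that("a tilted section plane inflates the perimeter at most elliptically", {
  ph <- wall_phantom()
  tb <- ph$truth$tubes[[2]]
  mid <- tb$centerline[nrow(tb$centerline) %/% 2, ]
  u <- tb$centerline[nrow(tb$centerline), ] - tb$centerline[1, ]
  u <- u / sqrt(sum(u^2))
  w0 <- measure_wall(ph$insp, mid, u)
  # rotate the normal by 5 degrees within the x-z plane of the axis
  ang <- 5 * pi / 180
  perp <- c(u[3], 0, -u[1]) / sqrt(u[1]^2 + u[3]^2)
  w5 <- measure_wall(ph$insp, mid, cos(ang) * u + sin(ang) * perp)
  expect_lte(w5$pi_mm, w0$pi_mm / cos(ang) * 1.01)
})

test_that("sections without a detectable wall are excluded", {
  ph <- wall_phantom()
  w <- measure_wall(ph$insp, c(16, 7.3, 13), c(0, 0, 1))  # parenchyma
  expect_equal(w$status, "excluded")
  expect_gt(w$n_missing, 0.25 * 72)
  expect_error(measure_wall(ph$insp, c(-5, 0, 0), c(0, 0, 1)),
               class = "copdct_geometry_error")
})

test_that("anatomical exclusion rules remove trachea, main bronchi and branch regions", {
  secs <- data.frame(
    generation_label = c(0L, 0L, 1L, 2L, 2L, 2L, 3L),
    dist_bifurcation_mm = c(10, 10, 10, 1.5, 10, 10, 0.5),
    status = c("valid", "valid", "valid", "valid", "excluded", "valid", "valid")
  )
  f <- filter_cross_sections(secs, bifurcation_margin_mm = 2)
  expect_equal(unname(f$tally),
               c(2L, 1L, 2L, 1L))  # trachea, main bronchus, branch region, wall failed
  expect_equal(nrow(f$valid), 1L)
  expect_equal(f$valid$generation_label, 2L)

  # all-trachea input: nothing survives
  tr <- data.frame(generation_label = rep(0L, 5),
                   dist_bifurcation_mm = rep(10, 5))
  ftr <- filter_cross_sections(tr)
  expect_equal(nrow(ftr$valid), 0L)
  expect_equal(unname(ftr$tally[["trachea"]]), 5L)

  # Y tree with generations {0,1,1}: no measurable generation exists
  ph <- y_phantom()
  lum <- segment_lumen(ph$insp, c(12.8, 12.8, 4))
  tree <- extract_centerline(lum, ph$insp$spacing, seed_point = c(12.8, 12.8, 4))
  sy <- sample_cross_sections(tree)
  fy <- filter_cross_sections(sy)
  expect_equal(nrow(fy$valid), 0L)
})

test_that("the Pi10 regression is exact on forced two-point input", {
  secs <- data.frame(pi_mm = c(8, 12), sqrt_wa_mm = c(3, 4))
  p <- compute_pi10(secs)
  expect_equal(p$slope, 0.25)
  expect_equal(p$intercept, 1.0)
  expect_equal(p$pi10_mm, 3.5)
  expect_error(compute_pi10(data.frame(pi_mm = c(8, 8, 8),
                                       sqrt_wa_mm = c(3, 3.1, 2.9))),
               class = "copdct_degenerate_regression_error")
})

test_that("Pi10 is invariant to section order and duplication", {
  set.seed(2)
  secs <- data.frame(pi_mm = runif(40, 8, 25))
  secs$sqrt_wa_mm <- 1.2 + 0.18 * secs$pi_mm + rnorm(40, 0, 0.05)
  p0 <- compute_pi10(secs)
  p_shuf <- compute_pi10(secs[sample(40), ])
  p_dup <- compute_pi10(rbind(secs, secs))
  expect_equal(p_shuf$pi10_mm, p0$pi10_mm, tolerance = 1e-12)
  expect_equal(p_dup$pi10_mm, p0$pi10_mm, tolerance = 1e-12)
})
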