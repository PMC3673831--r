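# Synthetic CT phantoms: paired inspiratory/expiratory volumes containing
# airway tubes and emphysema clusters with exact geometric ground truth.

#' Specify an airway tube for a phantom
#'
#' A straight cylindrical airway segment: an air-filled lumen surrounded by a
#' soft-tissue wall, rasterized into the phantom grid. The closed-form lumen
#' perimeter (2*pi*r) and wall area (pi*((r+t)^2 - r^2)) are recorded as
#' ground truth.
#'
#' @param start,end world coordinates (mm), length-3 numeric.
#' @param lumen_radius lumen radius in mm (> 0).
#' @param wall_thickness wall thickness in mm (> 0).
#' @param lumen_hu,wall_hu attenuation of lumen air and wall tissue in HU.
#' @param generation_label airway generation: 0 = trachea, 1 = main
#'   bronchus, >= 2 = measurable bronchus.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(start, end, lumen_radius, wall_thickness,
                      lumen_hu = -1000, wall_hu = 0, generation_label = 2L) {
  check_number(lumen_radius, "lumen_radius", lower = 1e-9)
  check_number(wall_thickness, "wall_thickness", lower = 1e-9)
  if (wall_hu <= lumen_hu)
    stop_copdct("'wall_hu' must exceed 'lumen_hu'", "copdct_config_error")
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L ||
      sqrt(sum((end - start)^2)) <= 0)
    stop_copdct("tube endpoints must be distinct length-3 mm coordinates",
                "copdct_config_error")
  structure(list(start = start, end = end, lumen_radius = lumen_radius,
                 wall_thickness = wall_thickness, lumen_hu = lumen_hu,
                 wall_hu = wall_hu,
                 generation_label = as.integer(generation_label)),
            class = "tube_spec")
}

#' Specify a CT phantom
#'
#' Parameters of a paired-phase CT phantom. The lung parenchyma fills the
#' grid interior (a 2-voxel body border of soft tissue is kept around it);
#' airway tubes and spherical emphysema clusters are carved into it. The
#' expiratory phase is the inspiratory phase densified by the factor
#' `lung_hu_exp / lung_hu_insp` over the lung, so the expiratory/inspiratory
#' mean-lung-density ratio equals that factor by construction.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing voxel spacing in mm (isotropic scalar or length 3).
#' @param lung_hu_insp,lung_hu_exp mean parenchymal attenuation per phase
#'   (HU); expiration densifies the lung so `lung_hu_exp >= lung_hu_insp`.
#' @param emphysema_fraction target fraction of lung voxels set below
#'   -950 HU in the inspiratory phase, in `[0, 1]`.
#' @param emphysema_hu attenuation assigned to emphysema voxels (< -950 HU).
#' @param emphysema_radius_mm radius of the spherical clusters (mm).
#' @param noise_sd additive Gaussian noise standard deviation (HU, >= 0).
#' @param tubes list of [tube_spec()] objects.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = 0.5,
                         lung_hu_insp = -875, lung_hu_exp = -700,
                         emphysema_fraction = 0, emphysema_hu = -1000,
                         emphysema_radius_mm = 2, noise_sd = 0,
                         tubes = list()) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(grid_shape < 8L))
    stop_copdct("'grid_shape' must be at least 8 voxels per axis",
                "copdct_config_error")
  if (any(spacing <= 0))
    stop_copdct("'spacing' must be positive", "copdct_config_error")
  check_number(emphysema_fraction, "emphysema_fraction", 0, 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(emphysema_hu, "emphysema_hu", upper = -950.000001)
  check_number(emphysema_radius_mm, "emphysema_radius_mm", lower = 1e-9)
  if (lung_hu_exp < lung_hu_insp)
    stop_copdct("'lung_hu_exp' must be >= 'lung_hu_insp' (expiration densifies)",
                "copdct_config_error")
  if (lung_hu_insp >= 0 || lung_hu_exp >= 0)
    stop_copdct("lung attenuation must be negative HU", "copdct_config_error")
  if (!all(vapply(tubes, inherits, logical(1), "tube_spec")))
    stop_copdct("'tubes' must be a list of tube_spec objects",
                "copdct_config_error")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 lung_hu_insp = lung_hu_insp, lung_hu_exp = lung_hu_exp,
                 emphysema_fraction = emphysema_fraction,
                 emphysema_hu = emphysema_hu,
                 emphysema_radius_mm = emphysema_radius_mm,
                 noise_sd = noise_sd, tubes = tubes),
            class = "phantom_spec")
}

#' Standard three-tube wall phantom
#'
#' A ready-made [phantom_spec()] with three measurable airway tubes of
#' distinct caliber -- (lumen radius, wall thickness) = (1.5, 0.8),
#' (2.5, 1.0) and (4.0, 1.2) mm -- laid out in parallel lanes with slight
#' axis tilts so the tubes are not lattice-aligned. The spread of lumen
#' perimeters makes the Pi10 regression well conditioned, and the
#' closed-form (2*pi*r, sqrt(pi*((r+t)^2 - r^2))) pairs give an analytic
#' oracle for it.
#'
#' @param spacing voxel spacing in mm.
#' @param ... further arguments passed to [phantom_spec()]
#'   (e.g. `noise_sd`, `emphysema_fraction`).
#' @return A `phantom_spec`.
#' @export
standard_wall_phantom <- function(spacing = 0.3, ...) {
  geom <- list(c(1.5, 0.8), c(2.5, 1.0), c(4.0, 1.2))
  xs <- c(9.5, 23, 37)
  tilt <- list(c(sin(0.10), 0), c(0, sin(0.12)), c(sin(0.08), sin(0.05)))
  tubes <- lapply(1:3, function(i) {
    d <- c(tilt[[i]], 0)
    d[3] <- sqrt(1 - sum(d^2))
    tube_spec(start = c(xs[i], 7.3, 3), end = c(xs[i], 7.3, 3) + 20 * d,
              lumen_radius = geom[[i]][1], wall_thickness = geom[[i]][2],
              generation_label = 2L)
  })
  grid <- ceiling(c(46.5, 15, 26.1) / spacing)
  phantom_spec(grid_shape = grid, spacing = spacing, tubes = tubes, ...)
}

# Distance from each of n points to the segment a--b (rows of `pts`).
dist_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2L, a)
  tt <- pmin(1, pmax(0, (ap %*% ab) / len2))
  dx <- ap - tt %*% t(ab)
  sqrt(rowSums(dx^2))
}

#' Generate a paired-phase CT phantom
#'
#' Rasterizes the phantom described by a [phantom_spec()] into paired
#' inspiratory and expiratory [ct_volume()]s plus its exact ground truth:
#' the lung mask, the realized emphysema fraction, the noiseless mean lung
#' density per phase, and per-tube closed-form geometry.
#'
#' Emphysema is rendered as spheres placed by seeded rejection sampling
#' inside the lung mask; the final sphere is trimmed so the number of
#' emphysema voxels matches `round(fraction * n_lung)` exactly.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed (used for cluster placement and noise).
#' @return A list with elements `insp`, `exp` (both `ct_volume`), `mask`
#'   (logical array, lung parenchyma) and `truth` (list: `n_lung`,
#'   `true_emphysema_fraction`, `mld_insp`, `mld_exp`, `ei_ratio`, and
#'   `tubes` -- per-tube `lumen_perimeter_mm`, `wall_area_mm2`, `sqrt_wa_mm`,
#'   `centerline` polyline, `generation_label`).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape; sp <- spec$spacing
  margin_mm <- 2 * sp  # 2-voxel body border
  extent <- dm * sp

  # tubes must fit inside the lung with the body border plus 2 voxels slack
  for (tb in spec$tubes) {
    rr <- tb$lumen_radius + tb$wall_thickness
    u <- (tb$end - tb$start) / sqrt(sum((tb$end - tb$start)^2))
    foot <- rr * sqrt(pmax(0, 1 - u^2))  # radial footprint per axis
    for (p in list(tb$start, tb$end)) {
      if (any(p - foot < margin_mm + 2 * sp) ||
          any(p + foot > extent - margin_mm - 2 * sp))
        stop_copdct("tube extends outside the phantom lung region",
                    "copdct_geometry_error")
    }
  }

  xs <- axis_centers(dm[1], sp[1])
  ys <- axis_centers(dm[2], sp[2])
  zs <- axis_centers(dm[3], sp[3])
  pts <- cbind(rep(xs, times = dm[2] * dm[3]),
               rep(rep(ys, each = dm[1]), times = dm[3]),
               rep(zs, each = dm[1] * dm[2]))

  body <- pts[, 1] < margin_mm[1] | pts[, 1] > extent[1] - margin_mm[1] |
          pts[, 2] < margin_mm[2] | pts[, 2] > extent[2] - margin_mm[2] |
          pts[, 3] < margin_mm[3] | pts[, 3] > extent[3] - margin_mm[3]

  vox <- rep(spec$lung_hu_insp, nrow(pts))
  vox[body] <- 0
  lumen_any <- rep(FALSE, nrow(pts))
  wall_any <- rep(FALSE, nrow(pts))
  tube_truth <- list()
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    d <- dist_to_segment(pts, tb$start, tb$end)
    lum <- d < tb$lumen_radius
    wal <- !lum & d < tb$lumen_radius + tb$wall_thickness
    # walls never overwrite an existing lumen (merging branches stay open)
    wal <- wal & !lumen_any
    vox[wal] <- tb$wall_hu
    vox[lum] <- tb$lumen_hu
    lumen_any <- lumen_any | lum
    wall_any <- (wall_any | wal) & !lumen_any
    axis_len <- sqrt(sum((tb$end - tb$start)^2))
    n_cl <- max(2L, ceiling(axis_len))  # ~1-mm polyline sampling
    tt <- seq(0, 1, length.out = n_cl)
    r <- tb$lumen_radius; t <- tb$wall_thickness
    tube_truth[[ti]] <- list(
      lumen_perimeter_mm = 2 * pi * r,
      wall_area_mm2 = pi * ((r + t)^2 - r^2),
      sqrt_wa_mm = sqrt(pi * ((r + t)^2 - r^2)),
      lumen_voxel_count = sum(lum),
      generation_label = tb$generation_label,
      centerline = cbind(
        x = tb$start[1] + tt * (tb$end[1] - tb$start[1]),
        y = tb$start[2] + tt * (tb$end[2] - tb$start[2]),
        z = tb$start[3] + tt * (tb$end[3] - tb$start[3])
      )
    )
  }

  mask <- !body & !lumen_any & !wall_any
  n_lung <- sum(mask)
  n_emph <- round(spec$emphysema_fraction * n_lung)

  emph <- rep(FALSE, nrow(pts))
  if (n_emph > 0) {
    lung_idx <- which(mask)
    lo <- apply(pts[lung_idx, , drop = FALSE], 2L, min)
    hi <- apply(pts[lung_idx, , drop = FALSE], 2L, max)
    rad <- spec$emphysema_radius_mm
    with_seed(seed, {
      guard <- 0L
      while (sum(emph) < n_emph && guard < 10000L) {
        guard <- guard + 1L
        ctr <- lo + runif(3) * (hi - lo)
        ci <- pmin(dm, pmax(1L, ceiling(ctr / sp)))
        flat <- ci[1] + (ci[2] - 1L) * dm[1] + (ci[3] - 1L) * dm[1] * dm[2]
        if (!mask[flat] || emph[flat]) next
        d2 <- (pts[lung_idx, 1] - ctr[1])^2 + (pts[lung_idx, 2] - ctr[2])^2 +
              (pts[lung_idx, 3] - ctr[3])^2
        add <- lung_idx[d2 < rad^2 & !emph[lung_idx]]
        if (!length(add)) next
        need <- n_emph - sum(emph)
        if (length(add) > need) {
          # trim the final cluster from the outside in, keeping it compact
          add <- add[order(d2[match(add, lung_idx)])][seq_len(need)]
        }
        emph[add] <- TRUE
      }
    })
    if (sum(emph) < n_emph)
      stop_copdct("could not place enough emphysema voxels; lower the fraction or enlarge the grid",
                  "copdct_geometry_error")
    vox[emph] <- spec$emphysema_hu
  }

  scale_exp <- spec$lung_hu_exp / spec$lung_hu_insp
  vox_exp <- vox
  vox_exp[mask] <- vox[mask] * scale_exp

  mld_insp <- mean(vox[mask])
  mld_exp <- mean(vox_exp[mask])

  if (spec$noise_sd > 0) {
    with_seed(seed + 1L, {
      vox <- vox + rnorm(length(vox), sd = spec$noise_sd)
      vox_exp <- vox_exp + rnorm(length(vox_exp), sd = spec$noise_sd)
    })
  }

  truth <- list(
    n_lung = n_lung,
    true_emphysema_fraction = if (n_lung > 0) sum(emph) / n_lung else 0,
    mld_insp = mld_insp, mld_exp = mld_exp,
    ei_ratio = mld_exp / mld_insp,
    tubes = tube_truth
  )
  list(
    insp = ct_volume(array(vox, dim = dm), spacing = sp, phase = "inspiratory"),
    exp = ct_volume(array(vox_exp, dim = dm), spacing = sp, phase = "expiratory"),
    mask = array(mask, dim = dm),
    truth = truth
  )
}
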