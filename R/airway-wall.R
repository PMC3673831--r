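# Ray-cast bronchial wall measurement on perpendicular cross-sections and
# the Pi10 summary regression (sqrt wall area vs lumen perimeter).

#' Sample cross-sections along an airway tree
#'
#' Places cross-section centers along each branch at a fixed arc-length
#' spacing; the section normal is the local centerline tangent (central
#' differences along the branch polyline, one-sided at the ends). Each
#' section carries its branch's generation label and the straight-line
#' distance to the nearest bifurcation.
#'
#' @param tree an `airway_tree`.
#' @param spacing_mm arc-length spacing between sections (mm).
#' @return data.frame with columns `x,y,z` (center), `nx,ny,nz` (unit
#'   normal), `branch_id`, `generation_label`, `dist_bifurcation_mm`.
#' @export
sample_cross_sections <- function(tree, spacing_mm = 1.0) {
  stopifnot(inherits(tree, "airway_tree"))
  check_number(spacing_mm, "spacing_mm", lower = 1e-9)
  out <- list()
  for (b in tree$branches$branch_id) {
    nd <- tree$nodes[tree$nodes$branch_id == b, , drop = FALSE]
    p <- as.matrix(nd[, c("x", "y", "z")])
    tg <- as.matrix(nd[, c("tx", "ty", "tz")])
    if (nrow(p) < 2L) next
    seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    keep <- c(TRUE, seg > 1e-9)  # drop duplicate centerline points
    p <- p[keep, , drop = FALSE]; tg <- tg[keep, , drop = FALSE]
    if (nrow(p) < 2L) next
    seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    L <- s[length(s)]
    if (L < spacing_mm) next
    targets <- seq(0, L, by = spacing_mm)
    ip <- function(col) stats::approx(s, col, xout = targets, rule = 2)$y
    ctr <- cbind(ip(p[, 1]), ip(p[, 2]), ip(p[, 3]))
    # local direction from the resampled polyline (central differences);
    # fall back to interpolated node tangents where a difference vanishes
    nrm <- if (nrow(ctr) >= 2L) polyline_tangents(ctr) else
      cbind(ip(tg[, 1]), ip(tg[, 2]), ip(tg[, 3]))
    bad <- rowSums(nrm^2) < 1e-12
    if (any(bad)) {
      fb <- cbind(ip(tg[, 1]), ip(tg[, 2]), ip(tg[, 3]))
      nrm[bad, ] <- fb[bad, , drop = FALSE]
    }
    nn <- sqrt(rowSums(nrm^2)); nn[nn < 1e-12] <- 1
    nrm <- nrm / nn
    if (nrow(tree$bifurcations)) {
      db <- apply(ctr, 1L, function(q)
        sqrt(min(colSums((t(tree$bifurcations) - q)^2))))
    } else db <- rep(Inf, nrow(ctr))
    out[[length(out) + 1L]] <- data.frame(
      x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
      nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
      branch_id = b,
      generation_label = tree$branches$generation_label[
        tree$branches$branch_id == b],
      dist_bifurcation_mm = db
    )
  }
  if (!length(out)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      branch_id = integer(), generation_label = integer(),
                      dist_bifurcation_mm = numeric()))
  }
  do.call(rbind, out)
}

# Orthonormal in-plane basis perpendicular to a unit normal.
plane_basis <- function(normal) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-12)
    stop_copdct("section normal must be a nonzero vector",
                "copdct_geometry_error")
  n <- normal / nn
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

# First sub-step crossing of `level` in profile y over radii r, going up
# (dir = 1) before index `at`, or down (dir = -1) after it.
half_crossing <- function(r, y, level, peak_idx, dir) {
  if (dir > 0) {
    for (m in seq_len(peak_idx - 1L)) {
      if (y[m] < level && y[m + 1L] >= level) {
        f <- (level - y[m]) / (y[m + 1L] - y[m])
        return(r[m] + f * (r[m + 1L] - r[m]))
      }
    }
  } else {
    for (m in peak_idx:(length(y) - 1L)) {
      if (y[m] > level && y[m + 1L] <= level) {
        f <- (y[m] - level) / (y[m] - y[m + 1L])
        return(r[m] + f * (r[m + 1L] - r[m]))
      }
    }
  }
  NA_real_
}

#' Measure a bronchial wall cross-section by radial ray casting
#'
#' Casts `n_rays` equally spaced rays in the plane perpendicular to
#' `normal`, sampling attenuation by trilinear interpolation at `step_mm`
#' sub-voxel steps. On each ray the inner wall boundary is the half-rise
#' point between the lumen plateau and the wall peak, and the outer
#' boundary the half-fall point between the peak and the parenchymal
#' plateau (a full-width-at-half-maximum edge rule). Rays without a clear
#' wall peak (contrast below `min_contrast_hu`) are marked missing; when at
#' most `max_missing_frac` of rays are missing their boundary radii are
#' interpolated angularly, otherwise the section is excluded.
#'
#' The lumen perimeter Pi is the perimeter of the polygon through the inner
#' boundary points; the wall area WA is the area of the outer polygon minus
#' the inner polygon.
#'
#' @param vol a [ct_volume()].
#' @param center section center, world mm (must lie inside the lumen).
#' @param normal section normal (local airway direction).
#' @param n_rays number of rays (default 72).
#' @param step_mm radial sampling step (mm).
#' @param max_radius_mm maximum ray length (mm).
#' @param lumen_window_mm radial window used to estimate the lumen plateau.
#' @param tail_frac trailing fraction of the ray used for the parenchymal
#'   plateau.
#' @param min_contrast_hu minimum peak-over-plateau contrast for a ray to
#'   count as observed.
#' @param max_missing_frac maximum tolerated fraction of missing rays.
#' @param smooth_window width (rays) of the circular moving average applied
#'   to the boundary radii before polygon construction; suppresses lattice
#'   jitter that would otherwise inflate the polygon perimeter.
#' @return A list of class `wall_cross_section`: `pi_mm`, `wa_mm2`,
#'   `sqrt_wa_mm`, per-ray `inner_radius_mm` / `outer_radius_mm`,
#'   `n_missing`, and `status` (`"valid"` or `"excluded"` with reason
#'   attribute `"wall_failed"`).
#' @export
measure_wall <- function(vol, center, normal, n_rays = 72L, step_mm = 0.1,
                         max_radius_mm = 8, lumen_window_mm = 0.4,
                         tail_frac = 0.15, min_contrast_hu = 150,
                         max_missing_frac = 0.25, smooth_window = 5L) {
  stopifnot(inherits(vol, "ct_volume"))
  center <- as.numeric(center)
  dm <- dim(vol$voxels); sp <- vol$spacing
  if (any(center < 0) || any(center > dm * sp))
    stop_copdct("cross-section center lies outside the volume",
                "copdct_geometry_error")
  basis <- plane_basis(as.numeric(normal))
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  radii <- seq(step_mm, max_radius_mm, by = step_mm)
  nr <- length(radii)
  dirs <- cbind(cos(theta), sin(theta)) %*% rbind(basis$u, basis$v)
  pts <- matrix(rep(center, each = n_rays * nr), ncol = 3L) +
    dirs[rep(seq_len(n_rays), each = nr), ] * radii[rep(seq_len(nr), n_rays)]
  hu <- interp_trilinear(vol, pts)
  hu0 <- interp_trilinear(vol, matrix(center, 1L))

  inner <- rep(NA_real_, n_rays)
  outer <- rep(NA_real_, n_rays)
  for (ray in seq_len(n_rays)) {
    y <- hu[((ray - 1L) * nr + 1L):(ray * nr)]
    nok <- which(is.na(y))
    len <- if (length(nok)) nok[1L] - 1L else nr
    if (len < 10L) next
    y <- y[seq_len(len)]; r <- radii[seq_len(len)]
    lumen_plat <- mean(c(hu0, y[r <= lumen_window_mm]))
    peak_idx <- which.max(y)
    peak <- y[peak_idx]
    tail_n <- max(3L, ceiling(tail_frac * len))
    parench_plat <- mean(y[(len - tail_n + 1L):len])
    if (peak - max(lumen_plat, parench_plat) < min_contrast_hu) next
    if (peak_idx < 2L || peak_idx > len - 2L) next
    ri <- half_crossing(r, y, (lumen_plat + peak) / 2, peak_idx, dir = 1)
    ro <- half_crossing(r, y, (peak + parench_plat) / 2, peak_idx, dir = -1)
    if (is.na(ri) || is.na(ro) || ri <= 0 || ro < ri) next
    inner[ray] <- ri
    outer[ray] <- ro
  }

  n_missing <- sum(is.na(inner))
  status <- "valid"
  reason <- NA_character_
  if (n_missing > max_missing_frac * n_rays) {
    status <- "excluded"; reason <- "wall_failed"
    pi_mm <- NA_real_; wa <- NA_real_
  } else {
    if (n_missing > 0L) {
      inner <- interp_circular(inner)
      outer <- interp_circular(outer)
    }
    # regularize the contour: lattice quantization puts zero-mean jitter on
    # per-ray radii, which inflates a raw polygon perimeter; a short
    # circular moving average removes it without flattening real shape
    inner_s <- smooth_circular(inner, smooth_window)
    outer_s <- smooth_circular(outer, smooth_window)
    pin <- cbind(inner_s * cos(theta), inner_s * sin(theta))
    pout <- cbind(outer_s * cos(theta), outer_s * sin(theta))
    pi_mm <- polygon_perimeter(pin)
    wa <- polygon_area(pout) - polygon_area(pin)
  }
  structure(list(
    center = center, normal = as.numeric(normal),
    inner_radius_mm = inner, outer_radius_mm = outer,
    n_missing = n_missing, n_rays = n_rays,
    pi_mm = pi_mm, wa_mm2 = wa,
    sqrt_wa_mm = if (is.na(wa) || wa < 0) NA_real_ else sqrt(wa),
    status = status, reason = reason
  ), class = "wall_cross_section")
}

# Circular moving average of width `w` (odd).
smooth_circular <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xs <- x[c((n - half + 1L):n, 1:n, 1:half)]
  out <- stats::filter(xs, rep(1 / w, w), sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Fill NA entries of a circular series by linear angular interpolation
# between the nearest observed neighbours.
interp_circular <- function(x) {
  n <- length(x)
  obs <- which(!is.na(x))
  if (!length(obs)) return(x)
  for (i in which(is.na(x))) {
    dl <- (i - obs) %% n; dr <- (obs - i) %% n
    l <- obs[which.min(ifelse(dl == 0, n, dl))]
    r <- obs[which.min(ifelse(dr == 0, n, dr))]
    wl <- min((i - l) %% n, n); wr <- min((r - i) %% n, n)
    x[i] <- if (wl + wr == 0) x[l] else (wr * x[l] + wl * x[r]) / (wl + wr)
  }
  x
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums((q[-1L, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2)))
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Measure all cross-sections of a section table
#'
#' Convenience wrapper running [measure_wall()] for every row of a
#' [sample_cross_sections()] table and binding the results on.
#'
#' @param vol a [ct_volume()].
#' @param sections data.frame from [sample_cross_sections()].
#' @param ... passed to [measure_wall()].
#' @return `sections` with added columns `pi_mm`, `wa_mm2`, `sqrt_wa_mm`,
#'   `n_missing`, `status`.
#' @export
measure_sections <- function(vol, sections, ...) {
  res <- lapply(seq_len(nrow(sections)), function(i) {
    w <- measure_wall(vol, c(sections$x[i], sections$y[i], sections$z[i]),
                      c(sections$nx[i], sections$ny[i], sections$nz[i]), ...)
    data.frame(pi_mm = w$pi_mm, wa_mm2 = w$wa_mm2, sqrt_wa_mm = w$sqrt_wa_mm,
               n_missing = w$n_missing, status = w$status)
  })
  cbind(sections, do.call(rbind, res))
}

#' Filter cross-sections by anatomical and quality rules
#'
#' Excludes sections from the trachea (generation 0) and main bronchi
#' (generation 1), sections within `bifurcation_margin_mm` of a bifurcation
#' (branching regions), and sections whose wall measurement failed. The
#' first matching rule, in that order, is tallied as the exclusion reason.
#'
#' @param sections data.frame with `generation_label`,
#'   `dist_bifurcation_mm`, and optionally `status`.
#' @param bifurcation_margin_mm exclusion margin around bifurcations (mm).
#' @return list with `valid` (surviving rows) and `tally` (named integer
#'   vector of exclusion counts: trachea, main_bronchus, branch_region,
#'   wall_failed).
#' @export
filter_cross_sections <- function(sections, bifurcation_margin_mm = 2.0) {
  status <- if ("status" %in% names(sections)) sections$status
            else rep("valid", nrow(sections))
  reason <- rep(NA_character_, nrow(sections))
  reason[status != "valid"] <- "wall_failed"
  reason[sections$dist_bifurcation_mm < bifurcation_margin_mm] <- "branch_region"
  reason[sections$generation_label == 1L] <- "main_bronchus"
  reason[sections$generation_label == 0L] <- "trachea"
  tally <- c(trachea = sum(reason == "trachea", na.rm = TRUE),
             main_bronchus = sum(reason == "main_bronchus", na.rm = TRUE),
             branch_region = sum(reason == "branch_region", na.rm = TRUE),
             wall_failed = sum(reason == "wall_failed", na.rm = TRUE))
  list(valid = sections[is.na(reason), , drop = FALSE], tally = tally)
}

#' Pi10: regression summary of bronchial wall thickness
#'
#' Ordinary least squares of the square root of wall area on the lumen
#' perimeter over all valid cross-sections; Pi10 is the fitted square root
#' of wall area at a lumen perimeter of 10 mm, a standardized per-subject
#' bronchial wall thickness.
#'
#' @param sections data.frame with columns `pi_mm` and `sqrt_wa_mm`
#'   (e.g. the `valid` element of [filter_cross_sections()]).
#' @param exclusion_tally optional named vector recorded in the result.
#' @return list of class `pi10_result`: `slope`, `intercept`, `pi10_mm`,
#'   `n_sections_used`, `n_sections_excluded`.
#' @export
compute_pi10 <- function(sections, exclusion_tally = NULL) {
  ok <- is.finite(sections$pi_mm) & is.finite(sections$sqrt_wa_mm)
  x <- sections$pi_mm[ok]; y <- sections$sqrt_wa_mm[ok]
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop_copdct("need at least 2 sections with distinct lumen perimeters",
                "copdct_degenerate_regression_error")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  structure(list(
    slope = slope, intercept = intercept,
    pi10_mm = intercept + 10 * slope,
    n_sections_used = length(x),
    n_sections_excluded = exclusion_tally %||% c()
  ), class = "pi10_result")
}

#' @export
print.pi10_result <- function(x, ...) {
  cat(sprintf("Pi10 = %.3f mm  (sqrtWA = %.3f + %.4f * Pi; %d sections)\n",
              x$pi10_mm, x$intercept, x$slope, x$n_sections_used))
  invisible(x)
}
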