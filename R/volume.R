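# CT volume container and world<->voxel geometry.
#
# Convention: voxel indices are 0-based in world-coordinate formulas;
# world position of voxel (i,j,k) is ((i,j,k) + 0.5) * spacing, i.e. voxel
# centers, with the volume corner at the world origin. R arrays are indexed
# 1-based as usual.

#' Construct a CT volume
#'
#' A minimal in-memory container for a 3-D CT image: a numeric array of
#' Hounsfield Units plus the voxel spacing in millimetres and the
#' respiratory phase it was acquired in.
#'
#' @param voxels 3-D numeric array of attenuation values in HU.
#' @param spacing voxel spacing in mm, length 1 (isotropic) or 3.
#' @param phase `"inspiratory"` or `"expiratory"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = 1, phase = c("inspiratory", "expiratory")) {
  phase <- match.arg(phase)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_copdct("'voxels' must be a 3-D array", "copdct_config_error")
  if (any(!is.finite(voxels)))
    stop_copdct("voxel values must be finite HU", "copdct_config_error")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0))
    stop_copdct("'spacing' must be positive on every axis", "copdct_config_error")
  structure(list(voxels = voxels, spacing = spacing, phase = phase),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s, %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              x$phase, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel volume in litres
#' @param vol a `ct_volume` or spacing vector (mm).
#' @return volume of one voxel in litres.
#' @keywords internal
voxel_volume_l <- function(vol) {
  sp <- if (inherits(vol, "ct_volume")) vol$spacing else rep_len(vol, 3L)
  prod(sp) / 1e6  # mm^3 -> litres
}

# World (mm) coordinates of all voxel centers along one axis.
axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Trilinear interpolation of a volume at world points
#'
#' Samples attenuation at arbitrary world-space positions (mm) by trilinear
#' interpolation between the eight surrounding voxel centers. Points outside
#' the voxel-center bounding box return `NA`.
#'
#' @param vol a `ct_volume`.
#' @param pts numeric matrix, one row per point, columns x/y/z in mm.
#' @return numeric vector of interpolated HU values (NA outside the grid).
#' @export
interp_trilinear <- function(vol, pts) {
  stopifnot(inherits(vol, "ct_volume"))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  dm <- dim(vol$voxels)
  sp <- vol$spacing
  # continuous voxel coordinate: voxel center i (1-based) at (i - 0.5) * sp
  u <- sweep(pts, 2L, sp, "/") + 0.5  # 1-based fractional index
  i0 <- floor(u)
  f <- u - i0
  out <- rep(NA_real_, nrow(pts))
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] < dm[1] & i0[, 2] < dm[2] & i0[, 3] < dm[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  v <- vol$voxels
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  c000 <- idx(0, 0, 0); c100 <- idx(1, 0, 0)
  c010 <- idx(0, 1, 0); c110 <- idx(1, 1, 0)
  c001 <- idx(0, 0, 1); c101 <- idx(1, 0, 1)
  c011 <- idx(0, 1, 1); c111 <- idx(1, 1, 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Read / write CT volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel spacing and
#' respiratory phase of a [ct_volume()].
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param phase respiratory phase to tag the loaded volume with.
#' @return `read_volume` returns a `ct_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, phase = c("inspiratory", "expiratory")) {
  phase <- match.arg(phase)
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3], phase = phase)
}

#' @rdname read_volume
#' @param vol a `ct_volume` (or a plain array for masks).
#' @param spacing spacing in mm when `vol` is a plain array.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$voxels; sp <- vol$spacing
  } else {
    arr <- vol; sp <- rep_len(spacing %||% 1, 3L)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}
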