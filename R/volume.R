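#' Scalar image volume with slice geometry
#'
#' A `volume3d` wraps a numeric array indexed `(slice, row, col)` together
#' with voxel spacing, per-slice longitudinal (z) positions, an orientation
#' quaternion, and an intensity-unit annotation. Slice positions must be
#' strictly monotonic; on file read they are sorted ascending.
#'
#' @param data Numeric array indexed `(slice, row, col)`; a matrix is
#'   treated as a single slice.
#' @param spacing_mm Voxel spacing `(dz, dy, dx)` in mm; all components
#'   must be positive and finite.
#' @param slice_z_mm Per-slice longitudinal positions in mm; defaults to
#'   `(0, dz, 2*dz, ...)`. Must be strictly monotonic.
#' @param orientation Unit quaternion `(w, x, y, z)` giving the rotation
#'   from voxel axes `(x, y, z)` to world axes.
#' @param intensity_units Free-text unit annotation.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_mm, slice_z_mm = NULL,
                     orientation = c(1, 0, 0, 0),
                     intensity_units = "arbitrary") {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  if (any(dim(data) == 0L)) stop("volume has empty dimensions")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing must be three positive finite values (dz, dy, dx)")
  n <- dim(data)[1L]
  if (is.null(slice_z_mm)) slice_z_mm <- (seq_len(n) - 1) * spacing_mm[1L]
  slice_z_mm <- as.numeric(slice_z_mm)
  if (length(slice_z_mm) != n) stop("slice_z_mm length must match slice count")
  if (n > 1L) {
    dz <- diff(slice_z_mm)
    if (!(all(dz > 0) || all(dz < 0))) stop("slice_z_mm must be strictly monotonic")
  }
  orientation <- quat_normalize(as.numeric(orientation))
  structure(list(data = data, spacing_mm = spacing_mm,
                 slice_z_mm = slice_z_mm, orientation = orientation,
                 intensity_units = intensity_units),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d slices x %d x %d, spacing (dz,dy,dx) = %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x ")))
  cat(sprintf("  z: %s mm; units: %s\n",
              paste(signif(x$slice_z_mm, 5), collapse = ", "),
              x$intensity_units))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

# New volume on the same grid as `vol` with replaced voxel data.
vol_like <- function(vol, data, intensity_units = vol$intensity_units) {
  volume3d(array(data, dim = dim(vol$data)), vol$spacing_mm, vol$slice_z_mm,
           vol$orientation, intensity_units)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing_mm - b$spacing_mm)) < tol &&
    max(abs(a$slice_z_mm - b$slice_z_mm)) < tol
}

#' Label map over a volume grid
#'
#' Integer volume coding `0` background, `1` remote, `2` border, `3` infarct
#' myocardium, sharing the grid of its source volume.
#'
#' @param labels Integer array (slice, row, col) with values in `{0,1,2,3}`.
#' @param reference A `volume3d` supplying the grid, or `NULL` to pass
#'   `spacing_mm`/`slice_z_mm` directly via `...`.
#' @param ... Grid arguments forwarded to [volume3d()] when `reference` is
#'   `NULL`.
#' @return Object of classes `label_map` and `volume3d`.
#' @export
label_map <- function(labels, reference = NULL, ...) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(1L, dim(labels)))
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3))
    stop("label values must lie in {0, 1, 2, 3}")
  v <- if (is.null(reference)) {
    volume3d(labels, ..., intensity_units = "label")
  } else {
    volume3d(labels, reference$spacing_mm, reference$slice_z_mm,
             reference$orientation, "label")
  }
  v$coding <- c(`0` = "background", `1` = "remote", `2` = "border",
                `3` = "infarct")
  class(v) <- c("label_map", "volume3d")
  v
}

region_names <- c("remote", "border", "infarct")

vol_affine <- function(vol) {
  R <- quat_to_rotmat(vol$orientation)
  sp <- vol$spacing_mm  # (dz, dy, dx)
  A <- diag(4)
  A[1:3, 1] <- R[, 1] * sp[3L]
  A[1:3, 2] <- R[, 2] * sp[2L]
  A[1:3, 3] <- R[, 3] * sp[1L]
  A[1:3, 4] <- R[, 3] * vol$slice_z_mm[1L]
  A
}

uniform_dz <- function(vol, tol = 1e-6) {
  n <- length(vol$slice_z_mm)
  if (n == 1L) return(vol$spacing_mm[1L])
  dz <- diff(vol$slice_z_mm)
  if (max(abs(dz - dz[1L])) > tol)
    stop("non-uniform slice spacing cannot be stored as NIfTI")
  dz[1L]
}

#' Write a volume to a NIfTI-1 file
#'
#' Integer volumes (including label maps) are stored as 32-bit integers so
#' that labels round-trip without value change; floating-point volumes are
#' stored as doubles. The voxel grid, slice positions, and orientation are
#' encoded in the qform/sform affine.
#'
#' @param vol A [volume3d()] (slice spacing must be uniform).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (any(dim(vol$data) == 0L)) stop("volume has empty dimensions")
  dz <- uniform_dz(vol)
  sp <- c(vol$spacing_mm[3L], vol$spacing_mm[2L], dz)  # (dx, dy, dz)
  arr <- aperm(vol$data, c(3L, 2L, 1L))
  dtype <- if (is.integer(vol$data)) "int32" else "double"
  img <- RNifti::asNifti(arr,
                         reference = list(pixdim = c(-1, sp, 0, 0, 0, 0)),
                         datatype = dtype)
  A <- vol_affine(vol)
  RNifti::qform(img) <- structure(A, code = 2L)
  RNifti::sform(img) <- structure(A, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a volume
#'
#' Populates voxel data, spacing, per-slice z positions, and the
#' orientation quaternion from the header. Slices are reordered so z is
#' ascending.
#'
#' @param path Path to a 3D NIfTI-1 file.
#' @param intensity_units Unit annotation to attach (NIfTI does not store
#'   one).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, intensity_units = "arbitrary") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  A <- unclass(RNifti::xform(img))
  M <- A[1:3, 1:3]
  sp_xyz <- sqrt(colSums(M^2))
  if (any(!is.finite(sp_xyz)) || any(sp_xyz <= 0))
    stop("non-finite or non-positive voxel spacing in header")
  R <- sweep(M, 2L, sp_xyz, "/")
  if (det(R) <= 0) stop("left-handed orientation matrices are not supported")
  q <- rotmat_to_quat(R)
  normal <- R[, 3]
  z0 <- sum(normal * A[1:3, 4])
  zk <- z0 + (seq_len(d[3L]) - 1) * sp_xyz[3L] * sum(normal * R[, 3])
  arr <- aperm(as.array(img), c(3L, 2L, 1L))
  attributes(arr) <- list(dim = dim(arr))
  if (d[3L] > 1L && zk[2L] < zk[1L]) {
    arr <- arr[rev(seq_len(d[3L])), , , drop = FALSE]
    zk <- rev(zk)
  }
  volume3d(arr, spacing_mm = c(sp_xyz[3L], sp_xyz[2L], sp_xyz[1L]),
           slice_z_mm = zk, orientation = q,
           intensity_units = intensity_units)
}

#' Read a label map from a NIfTI-1 file
#'
#' @inheritParams read_volume
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  v <- read_volume(path, intensity_units = "label")
  lab <- v$data
  storage.mode(lab) <- "integer"
  label_map(lab, reference = v)
}

# In-plane voxel-centre coordinate matrices (mm) for a grid of
# `dim_yx = (nrow, ncol)` pixels with spacing `(dy, dx)`; origin at pixel
# (1,1) centre, x along columns, y along rows.
inplane_coords <- function(dim_yx, spacing_yx) {
  y <- (seq_len(dim_yx[1L]) - 1) * spacing_yx[1L]
  x <- (seq_len(dim_yx[2L]) - 1) * spacing_yx[2L]
  list(y = matrix(y, dim_yx[1L], dim_yx[2L]),
       x = matrix(x, dim_yx[1L], dim_yx[2L], byrow = TRUE))
}
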