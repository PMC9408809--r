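#' Rigid transform between two volume spaces
#'
#' Composed from the orientation quaternions stored in the two volume
#' headers (`q_fixed * q_moving^-1`) plus the translation aligning the
#' world centroids of the two foreground masks. An optional mask-moment
#' refinement is not applied here; the metadata reading is the default.
#'
#' @param moving,fixed [volume3d()] objects carrying orientation
#'   quaternions.
#' @param moving_mask,fixed_mask Optional logical foreground arrays; by
#'   default voxels above the Otsu level of each volume (or simply nonzero
#'   voxels for label maps / binary data).
#' @return An object of class `rigid_transform` with elements `q`
#'   (quaternion), `R` (rotation matrix), and `t` (translation, mm).
#' @export
rigid_align <- function(moving, fixed, moving_mask = NULL, fixed_mask = NULL) {
  stopifnot(inherits(moving, "volume3d"), inherits(fixed, "volume3d"))
  if (is.null(moving$orientation) || is.null(fixed$orientation))
    stop("missing orientation metadata")
  q_rel <- quat_multiply(fixed$orientation, quat_conjugate(moving$orientation))
  R <- quat_to_rotmat(q_rel)
  cm <- mask_world_centroid(moving, moving_mask)
  cf <- mask_world_centroid(fixed, fixed_mask)
  tr <- cf - as.vector(R %*% cm)
  structure(list(q = q_rel, R = R, t = tr), class = "rigid_transform")
}

default_fg_mask <- function(vol) {
  x <- vol$data
  u <- unique(as.vector(x))
  if (length(u) <= 3L) return(x != 0)
  x > otsu_threshold(as.vector(x))
}

mask_world_centroid <- function(vol, mask = NULL) {
  if (is.null(mask)) mask <- default_fg_mask(vol)
  if (inherits(mask, "volume3d")) mask <- mask$data != 0
  if (!any(mask)) stop("empty foreground mask")
  d3 <- dim(vol$data)
  idx <- which(mask, arr.ind = TRUE)  # (slice, row, col)
  loc <- cbind((idx[, 3L] - 1) * vol$spacing_mm[3L],
               (idx[, 2L] - 1) * vol$spacing_mm[2L],
               vol$slice_z_mm[idx[, 1L]])
  Rv <- quat_to_rotmat(vol$orientation)
  colMeans(loc %*% t(Rv))
}

#' Apply or invert a rigid transform
#'
#' @param tf A `rigid_transform`.
#' @param pts `n x 3` matrix of points (mm).
#' @return Transformed points / the inverse transform.
#' @export
apply_rigid <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3L)
  sweep(pts %*% t(tf$R), 2L, tf$t, "+")
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(tf) {
  Rt <- t(tf$R)
  structure(list(q = quat_conjugate(tf$q), R = Rt,
                 t = -as.vector(Rt %*% tf$t)),
            class = "rigid_transform")
}

#' Uniform longitudinal rescaling of slice positions
#'
#' Affine map of z sending the most basal and most apical label-map
#' slices onto the corresponding cDTI slice positions; interior spacing is
#' scaled uniformly.
#'
#' @param label_slice_z Slice z positions (mm), at least two.
#' @param cdti_basal_z,cdti_apical_z Target basal and apical positions.
#' @return Rescaled z positions with the endpoints matching exactly.
#' @export
longitudinal_rescale <- function(label_slice_z, cdti_basal_z, cdti_apical_z) {
  z <- as.numeric(label_slice_z)
  n <- length(z)
  if (n < 2L) stop("degenerate input: at least two slices required")
  span <- z[n] - z[1L]
  if (span == 0) stop("degenerate input: zero slice span")
  if (cdti_apical_z == cdti_basal_z) stop("cdti span is zero")
  cdti_basal_z + (z - z[1L]) * (cdti_apical_z - cdti_basal_z) / span
}

#' Detect endo- and epicardial contours on a cDTI slice
#'
#' Canny edge detection followed by 8-connected grouping of edge pixels;
#' the two largest closed groups are taken as the myocardial borders, the
#' inner one (smaller mean radius) as the endocardium.
#'
#' @param slice_img Numeric matrix (one short-axis slice).
#' @param spacing_yx In-plane spacing `(dy, dx)`, mm.
#' @param sigma Gaussian smoothing SD (voxels) for the edge detector.
#' @param low_frac,high_frac Hysteresis thresholds as fractions of the
#'   Otsu level of the gradient magnitude.
#' @param min_pixels Minimum pixels for an edge group to count as a
#'   contour.
#' @return List with closed polygonal contours `endo` and `epi` (n x 2
#'   matrices of (x, y) mm, first point repeated last) and `center`
#'   (x, y) mm.
#' @export
detect_myocardial_edges <- function(slice_img, spacing_yx = c(1, 1),
                                    sigma = 1.4, low_frac = 0.5,
                                    high_frac = 1.0, min_pixels = 8L) {
  edges <- canny_edges(slice_img, sigma, low_frac, high_frac)
  comp <- connected_components(edges)
  sizes <- tabulate(comp[comp > 0L])
  keep <- which(sizes >= min_pixels)
  if (length(keep) < 2L) stop("no myocardial contours")
  keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  pix <- lapply(keep, function(k) which(comp == k, arr.ind = TRUE))
  all_pix <- do.call(rbind, pix)
  cx <- mean((all_pix[, 2L] - 1) * spacing_yx[2L])
  cy <- mean((all_pix[, 1L] - 1) * spacing_yx[1L])
  ## gradient magnitude of a lightly smoothed image for sub-pixel radial
  ## refinement of the contour points (parabolic peak along the ray)
  gref <- sobel_gradients(smooth2d(slice_img, min(sigma, 0.8)))
  magref <- sqrt(gref$gx^2 + gref$gy^2)
  polys <- lapply(pix, function(p) {
    x <- (p[, 2L] - 1) * spacing_yx[2L]
    y <- (p[, 1L] - 1) * spacing_yx[1L]
    ux <- x - cx; uy <- y - cy
    un <- sqrt(ux^2 + uy^2); un[un == 0] <- 1
    ux <- ux / un; uy <- uy / un
    h <- 0.75  # probe offset, voxels
    samp <- function(t) {
      rr <- matrix((y + t * h * uy * spacing_yx[1L]) / spacing_yx[1L] + 1, ncol = 1)
      cc <- matrix((x + t * h * ux * spacing_yx[2L]) / spacing_yx[2L] + 1, ncol = 1)
      as.vector(bilinear_sample(magref, rr, cc))
    }
    m0 <- samp(0); mm <- samp(-1); mp <- samp(1)
    den <- mm - 2 * m0 + mp
    tstar <- ifelse(abs(den) > 1e-12, 0.5 * (mm - mp) / den, 0)
    tstar <- pmin(pmax(tstar, -1), 1) * h
    x <- x + tstar * ux * spacing_yx[2L]
    y <- y + tstar * uy * spacing_yx[1L]
    th <- atan2(y - cy, x - cx)
    o <- order(th)
    m <- cbind(x = x[o], y = y[o])
    rbind(m, m[1L, , drop = FALSE])  # close the contour
  })
  mean_r <- vapply(polys, function(m)
    mean(sqrt((m[, 1L] - cx)^2 + (m[, 2L] - cy)^2)), numeric(1L))
  endo <- polys[[which.min(mean_r)]]
  epi <- polys[[which.max(mean_r)]]
  if (min(mean_r) >= max(mean_r))
    stop("no myocardial contours")
  list(endo = endo, epi = epi, center = c(x = cx, y = cy))
}

# Interpolated radius-vs-angle function for a star-shaped contour.
contour_radius_fn <- function(contour, center) {
  x <- contour[-nrow(contour), 1L]; y <- contour[-nrow(contour), 2L]
  th <- atan2(y - center[2L], x - center[1L])
  r <- sqrt((x - center[1L])^2 + (y - center[2L])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  th_ext <- c(th - 2 * pi, th, th + 2 * pi)
  r_ext <- rep(r, 3L)
  function(q) approx(th_ext, r_ext, xout = q, rule = 2)$y
}

# Binary myocardium mask between the endo and epi contours.
contours_to_mask <- function(contours, dim_yx, spacing_yx) {
  co <- inplane_coords(dim_yx, spacing_yx)
  cx <- contours$center[1L]; cy <- contours$center[2L]
  r <- sqrt((co$x - cx)^2 + (co$y - cy)^2)
  th <- atan2(co$y - cy, co$x - cx)
  fe <- contour_radius_fn(contours$endo, contours$center)
  fp <- contour_radius_fn(contours$epi, contours$center)
  re <- matrix(fe(as.vector(th)), dim_yx[1L], dim_yx[2L])
  rp <- matrix(fp(as.vector(th)), dim_yx[1L], dim_yx[2L])
  r >= re & r <= rp
}

#' Distance-weighted average of two binary slices
#'
#' Weighted sum of the masks immediately above and below a target z
#' position, with weights proportional to the opposite z distances,
#' thresholded at 0.5 to a binary slice.
#'
#' @param mask_above,mask_below Logical matrices on a common grid.
#' @param z_above,z_below,z_target z positions (mm) with
#'   `z_below <= z_target <= z_above`.
#' @return Logical matrix.
#' @export
weighted_average_masks <- function(mask_above, mask_below, z_above, z_below,
                                   z_target) {
  if (z_target < z_below || z_target > z_above)
    stop("z_target outside [z_below, z_above]")
  if (z_above == z_below) return(mask_below != 0)
  w_below <- (z_above - z_target) / (z_above - z_below)
  avg <- w_below * (mask_below != 0) + (1 - w_below) * (mask_above != 0)
  avg >= 0.5
}

# Symmetric demons iteration between two smoothed binary images.
# Returns per-pixel displacement (row, col) in voxels; sampling is
# pull-back: warped(x) = img(x + u(x)).
demons_field <- function(moving, fixed, n_iter = 200L, smooth_sigma = 1.0,
                         field_sigma = 1.5, step = 1.0, cap = 1.0) {
  m <- smooth2d(moving * 1, smooth_sigma)
  f <- smooth2d(fixed * 1, smooth_sigma)
  nr <- nrow(m); nc <- ncol(m)
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  gm <- sobel_gradients(m); gf <- sobel_gradients(f)
  ur <- matrix(0, nr, nc); uc <- matrix(0, nr, nc)
  eps <- 1e-9
  for (it in seq_len(n_iter)) {
    wr <- ri + ur; wc <- ci + uc
    mw <- bilinear_sample(m, wr, wc)
    diff <- f - mw
    gr <- 0.5 * (gf$gy + bilinear_sample(gm$gy, wr, wc))
    gc <- 0.5 * (gf$gx + bilinear_sample(gm$gx, wr, wc))
    den <- gr^2 + gc^2 + diff^2 + eps
    vr <- diff * gr / den
    vc <- diff * gc / den
    vn <- sqrt(vr^2 + vc^2)
    scale <- ifelse(vn > cap, cap / vn, 1)
    # gradient ascent on the warped moving image toward the fixed image
    ur <- smooth2d(ur + step * vr * scale, field_sigma)
    uc <- smooth2d(uc + step * vc * scale, field_sigma)
  }
  list(u_row = ur, u_col = uc)
}

#' Non-rigid (demons) registration of a label slice onto a binary mask
#'
#' Symmetric-demons registration driven by the smoothed binary myocardium
#' supports (the moving support is `labels > 0`); the recovered in-plane
#' field then warps the labels with nearest-neighbor sampling so the label
#' alphabet is preserved. A warning is issued when the warped support's
#' Dice overlap with the fixed mask falls below `dice_floor`.
#'
#' @param moving_labels Integer label matrix (values 0-3).
#' @param fixed_mask Logical matrix (target myocardium support).
#' @param spacing_yx In-plane spacing `(dy, dx)` mm, used to report the
#'   field in mm.
#' @param n_iter,smooth_sigma,field_sigma,step Demons parameters (voxel
#'   units).
#' @param dice_floor Warn when the post-registration support Dice is below
#'   this value.
#' @return List with `field` (per-pixel `(dy, dx)` displacements, mm),
#'   `labels` (warped label matrix), and `dice`.
#' @export
nonrigid_register <- function(moving_labels, fixed_mask, spacing_yx = c(1, 1),
                              n_iter = 200L, smooth_sigma = 1.0,
                              field_sigma = 1.5, step = 1.0,
                              dice_floor = 0.8) {
  mov_sup <- moving_labels > 0
  if (!any(mov_sup) || !any(fixed_mask)) stop("empty masks")
  fld <- demons_field(mov_sup, fixed_mask, n_iter, smooth_sigma,
                      field_sigma, step)
  nr <- nrow(moving_labels); nc <- ncol(moving_labels)
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sr <- pmin(pmax(round(ri + fld$u_row), 1L), nr)
  sc <- pmin(pmax(round(ci + fld$u_col), 1L), nc)
  warped <- matrix(moving_labels[cbind(as.vector(sr), as.vector(sc))], nr, nc)
  d <- dice_coefficient(warped > 0, fixed_mask)
  if (d < dice_floor)
    warning(sprintf("warped-support Dice %.3f below floor %.3f", d, dice_floor))
  list(field = list(dy = fld$u_row * spacing_yx[1L],
                    dx = fld$u_col * spacing_yx[2L]),
       labels = warped, dice = d)
}

#' Interpolate a label stack onto new slice positions
#'
#' One-hot indicators of each label are interpolated linearly in z and the
#' arg-max label is taken, ties resolved toward the more severe label
#' (infarct > border > remote > background). Positions outside the stack's
#' span use the nearest slice.
#'
#' @param warped 3D integer label array `(slice, row, col)`.
#' @param z_src Source slice positions (mm), ascending.
#' @param target_z Target slice positions (mm).
#' @return 3D integer label array with `length(target_z)` slices.
#' @export
interpolate_labels_to_slices <- function(warped, z_src, target_z) {
  if (length(dim(warped)) != 3L || dim(warped)[1L] == 0L) stop("empty stack")
  if (length(z_src) != dim(warped)[1L]) stop("z_src length mismatch")
  d <- dim(warped)
  out <- array(0L, dim = c(length(target_z), d[2L], d[3L]))
  for (i in seq_along(target_z)) {
    zt <- target_z[i]
    if (zt <= z_src[1L]) { out[i, , ] <- warped[1L, , ]; next }
    if (zt >= z_src[length(z_src)]) {
      out[i, , ] <- warped[length(z_src), , ]; next
    }
    j <- findInterval(zt, z_src)
    if (z_src[j] == zt) { out[i, , ] <- warped[j, , ]; next }
    w_lo <- (z_src[j + 1L] - zt) / (z_src[j + 1L] - z_src[j])
    lo <- warped[j, , ]; hi <- warped[j + 1L, , ]
    best <- matrix(-1, d[2L], d[3L]); lab <- matrix(0L, d[2L], d[3L])
    for (k in 0:3) {
      sc <- w_lo * (lo == k) + (1 - w_lo) * (hi == k)
      take <- sc >= best  # >= so ties go to the higher (more severe) label
      lab[take] <- k
      best[take] <- sc[take]
    }
    out[i, , ] <- lab
  }
  out
}

# Average of the b = 0 volumes of a DWI series (arithmetic mean of
# magnitudes).
b0_volume <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (length(dwi$s0_index) == 0L) stop("no b = 0 volume in series")
  acc <- Reduce(`+`, lapply(dwi$volumes[dwi$s0_index], function(v) v$data))
  vol_like(dwi$volumes[[1L]], acc / length(dwi$s0_index))
}

#' Register diastolic LGE-based label maps onto the systolic cDTI grid
#'
#' Executes the full registration chain: (a) metadata-quaternion rigid
#' alignment with foreground-centroid translation, (b) uniform
#' longitudinal rescaling matching the basal and apical slices, (c) Canny
#' detection of the cDTI endo/epicardial borders and distance-weighted
#' mask averaging at each label-map z position, (d) slicewise demons
#' registration of the label support onto the averaged cDTI mask, and
#' (e) one-hot 3D interpolation of the warped labels onto the original
#' cDTI slice positions. The result partitions the detected cDTI
#' myocardium into remote/border/infarct.
#'
#' @param labels Diastolic [label_map()] on the LGE grid.
#' @param lge LGE [volume3d()] (supplies the moving-space geometry).
#' @param cdti_b0 b = 0 cDTI [volume3d()] (fixed space).
#' @param options List of tuning parameters: `skip_rescale` (ablation
#'   flag), `canny_sigma`, `canny_low_frac`, `canny_high_frac`,
#'   `demons_iter`, `smooth_sigma`, `field_sigma`, `step`, `dice_floor`,
#'   `fill` (fill unlabeled myocardial voxels from neighbors).
#' @return List with `labels` (a [label_map()] on the cDTI grid) and
#'   `diagnostics` (rigid transform, z mappings, per-slice demons Dice).
#' @export
register_labels <- function(labels, lge, cdti_b0, options = list()) {
  stopifnot(inherits(labels, "label_map"), inherits(lge, "volume3d"),
            inherits(cdti_b0, "volume3d"))
  opt <- utils::modifyList(list(skip_rescale = FALSE, canny_sigma = 1.4,
                                canny_low_frac = 0.5, canny_high_frac = 1.0,
                                demons_iter = 200L, smooth_sigma = 1.0,
                                field_sigma = 1.5, step = 1.0,
                                dice_floor = 0.8, fill = TRUE), options)
  ## (a) rigid alignment: LGE/labels -> cDTI space
  tf <- rigid_align(lge, cdti_b0, moving_mask = labels$data > 0L)
  inv <- invert_rigid(tf)
  Rm <- quat_to_rotmat(lge$orientation)
  Rf <- quat_to_rotmat(cdti_b0$orientation)
  df <- dim(cdti_b0$data); dm <- dim(labels$data)
  spf <- cdti_b0$spacing_mm; spm <- lge$spacing_mm
  ## transformed z of each LGE slice (evaluated at the in-plane centre)
  xc <- (dm[3L] - 1) * spm[3L] / 2; yc <- (dm[2L] - 1) * spm[2L] / 2
  nfix <- Rf[, 3L]
  z_moved <- vapply(labels$slice_z_mm, function(zs) {
    w <- apply_rigid(tf, as.vector(Rm %*% c(xc, yc, zs)))
    sum(nfix * w)
  }, numeric(1L))
  ## resample each label slice onto the cDTI in-plane grid
  co <- inplane_coords(df[2:3], spf[2:3])
  res <- array(0L, dim = c(dm[1L], df[2L], df[3L]))
  for (s in seq_len(dm[1L])) {
    wx <- cbind(as.vector(co$x), as.vector(co$y), z_moved[s]) %*% t(Rf)
    pm <- apply_rigid(inv, wx) %*% Rm  # local moving coords (x, y, z)
    ri <- matrix(pm[, 2L] / spm[2L] + 1, df[2L], df[3L])
    ci <- matrix(pm[, 1L] / spm[3L] + 1, df[2L], df[3L])
    ## one-hot bilinear sampling with severity tie-break keeps sub-voxel
    ## boundary placement while preserving the label alphabet
    lab2 <- labels$data[s, , ]
    best <- matrix(-1, df[2L], df[3L]); pick <- matrix(0L, df[2L], df[3L])
    for (k in 0:3) {
      sc <- bilinear_sample((lab2 == k) * 1, ri, ci)
      take <- sc >= best
      pick[take] <- k
      best[take] <- sc[take]
    }
    out_of_grid <- ri < 1 | ri > dm[2L] | ci < 1 | ci > dm[3L]
    pick[out_of_grid] <- 0L
    res[s, , ] <- pick
  }
  ## (b) longitudinal rescale to the cDTI span
  zf <- cdti_b0$slice_z_mm
  z_scaled <- if (isTRUE(opt$skip_rescale)) z_moved else
    longitudinal_rescale(z_moved, zf[1L], zf[length(zf)])
  ## (c) cDTI myocardium masks per slice, then weighted average at each
  ## label z position
  cdti_masks <- lapply(seq_len(df[1L]), function(s) {
    ct <- detect_myocardial_edges(cdti_b0$data[s, , ], spf[2:3],
                                  sigma = opt$canny_sigma,
                                  low_frac = opt$canny_low_frac,
                                  high_frac = opt$canny_high_frac)
    contours_to_mask(ct, df[2:3], spf[2:3])
  })
  ## (d) demons per label slice
  warped <- array(0L, dim = dim(res))
  slice_dice <- numeric(dm[1L])
  for (s in seq_len(dm[1L])) {
    zt <- min(max(z_scaled[s], zf[1L]), zf[length(zf)])
    j <- findInterval(zt, zf)
    j2 <- min(j + 1L, length(zf))
    if (zf[j] == zt) j2 <- j
    fixed <- weighted_average_masks(cdti_masks[[j2]], cdti_masks[[j]],
                                    zf[j2], zf[j], zt)
    nr <- nonrigid_register(res[s, , ], fixed, spf[2:3],
                            n_iter = opt$demons_iter,
                            smooth_sigma = opt$smooth_sigma,
                            field_sigma = opt$field_sigma, step = opt$step,
                            dice_floor = opt$dice_floor)
    warped[s, , ] <- nr$labels
    slice_dice[s] <- nr$dice
  }
  ## (e) 3D interpolation onto the cDTI slice positions
  final <- interpolate_labels_to_slices(warped, z_scaled, zf)
  ## restrict to the detected myocardium and fill unlabeled voxels
  for (s in seq_len(df[1L])) {
    lab <- final[s, , ]
    myo <- cdti_masks[[s]]
    lab[!myo] <- 0L
    if (isTRUE(opt$fill)) lab <- fill_unlabeled(lab, myo)
    final[s, , ] <- lab
  }
  out <- label_map(final, reference = cdti_b0)
  list(labels = out,
       diagnostics = list(rigid = tf, z_original = labels$slice_z_mm,
                          z_moved = z_moved, z_scaled = z_scaled,
                          slice_dice = slice_dice, options = opt))
}

# Fill unlabeled myocardial pixels from the modal neighbor label; ties go
# to the more severe label. Iterates until stable.
fill_unlabeled <- function(lab, myo) {
  for (it in 1:25) {
    todo <- myo & lab == 0L
    if (!any(todo)) break
    cnt <- lapply(1:3, function(k) {
      m <- (lab == k) * 1
      acc <- matrix(0, nrow(lab), ncol(lab))
      for (di in -1:1) for (dj in -1:1)
        if (di != 0L || dj != 0L) acc <- acc + shift2(m, di, dj)
      acc
    })
    best <- matrix(0, nrow(lab), ncol(lab))
    pick <- matrix(0L, nrow(lab), ncol(lab))
    for (k in 1:3) {
      take <- cnt[[k]] >= best & cnt[[k]] > 0
      pick[take] <- k
      best[take] <- cnt[[k]][take]
    }
    newly <- todo & pick > 0L
    if (!any(newly)) break
    lab[newly] <- pick[newly]
  }
  lab
}
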