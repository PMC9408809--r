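#' Per-voxel diffusion tensor field
#'
#' Symmetric 3x3 tensors in mm^2/s stored as six unique components per
#' voxel, ordered `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`, with a validity mask.
#'
#' @param tensor6 Numeric array `(slice, row, col, 6)`.
#' @param valid Logical array `(slice, row, col)`.
#' @param reference A [volume3d()] supplying the grid.
#' @param s0 Optional fitted b = 0 signal array.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(tensor6, valid, reference, s0 = NULL) {
  stopifnot(length(dim(tensor6)) == 4L, dim(tensor6)[4L] == 6L,
            identical(dim(valid), dim(tensor6)[1:3]))
  structure(list(tensor6 = tensor6, valid = valid,
                 spacing_mm = reference$spacing_mm,
                 slice_z_mm = reference$slice_z_mm,
                 orientation = reference$orientation, s0 = s0),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> grid %s; %d valid voxels\n",
              paste(dim(x$valid), collapse = " x "), sum(x$valid)))
  invisible(x)
}

tensor_ref_volume <- function(field) {
  volume3d(array(0, dim(field$valid)), field$spacing_mm, field$slice_z_mm,
           field$orientation)
}

#' Log-linear least-squares diffusion tensor reconstruction
#'
#' Solves, per voxel, `ln S(b, g) = ln S0 - b g' D g` by ordinary least
#' squares for the six unique tensor components and `ln S0`. The fit is
#' unweighted and unconstrained: negative eigenvalues are reported as-is
#' (see `clip_negative`). Voxels with any nonpositive signal are marked
#' invalid and skipped.
#'
#' @param dwi A [dwi_series()].
#' @param mask Optional logical array restricting the fit.
#' @param clip_negative If `TRUE`, clip negative tensor eigenvalues to zero
#'   after fitting (off by default).
#' @return A [tensor_field()].
#' @export
fit_tensor_loglinear <- function(dwi, mask = NULL, clip_negative = FALSE) {
  stopifnot(inherits(dwi, "dwi_series"))
  scheme <- dwi$scheme
  if (!isTRUE(scheme$fit_ready))
    stop("scheme has fewer than 6 nonzero-b directions")
  if (length(dwi$s0_index) == 0L) stop("no b = 0 volume in series")
  X <- cbind(1, -scheme$bvals * quadratic_design(scheme$bvecs))
  if (qr(X)$rank < 7L) stop("rank-deficient design matrix")
  P <- solve(crossprod(X), t(X))  # 7 x ngrad projector
  S <- dwi_signal_matrix(dwi)     # nvox x ngrad
  d3 <- dim(dwi$volumes[[1L]]$data)
  ok <- rowSums(S <= 0) == 0L
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  beta <- matrix(NA_real_, nrow = nrow(S), ncol = 7L)
  if (any(ok)) beta[ok, ] <- log(S[ok, , drop = FALSE]) %*% t(P)
  tensor6 <- array(beta[, 2:7], dim = c(d3, 6L))
  if (clip_negative && any(ok)) {
    idx <- which(ok)
    t6 <- beta[idx, 2:7, drop = FALSE]
    for (i in seq_along(idx)) {
      e <- eigen(tensor6_to_mat(t6[i, ]), symmetric = TRUE)
      if (any(e$values < 0)) {
        lam <- pmax(e$values, 0)
        t6[i, ] <- mat_to_tensor6(e$vectors %*% diag(lam) %*% t(e$vectors))
      }
    }
    for (k in 1:6) {
      comp <- tensor6[, , , k]
      comp[idx] <- t6[, k]
      tensor6[, , , k] <- comp
    }
  }
  s0 <- array(exp(beta[, 1]), dim = d3)
  tensor_field(tensor6, array(ok, dim = d3), dwi$volumes[[1L]], s0 = s0)
}

#' Diffusion tensor invariants
#'
#' Eigenvalues sorted descending (`e1 >= e2 >= e3`), mean diffusivity
#' `MD = (e1 + e2 + e3)/3`, radial diffusivity `RD = (e2 + e3)/2` (the
#' average of the secondary and tertiary eigenvalues, i.e. diffusivity
#' transverse to the myocyte long axis), and fractional anisotropy
#' `FA = sqrt(3/2) ||e - MD|| / ||e||` (defined as 0 for a zero tensor).
#'
#' @param D Symmetric 3x3 matrix, or the six unique components ordered
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @return A list with `e1, e2, e3, MD, RD, FA` and the eigenvector matrix
#'   `vectors` (columns matching e1..e3).
#' @export
compute_invariants <- function(D) {
  if (is.matrix(D)) {
    if (!all(dim(D) == c(3L, 3L))) stop("tensor must be 3x3")
    tol <- 1e-8 * max(abs(D), 1e-300)
    if (max(abs(D - t(D))) > tol) stop("tensor is not symmetric")
  } else {
    D <- tensor6_to_mat(as.numeric(D))
  }
  e <- eigen(D, symmetric = TRUE)
  lam <- e$values  # descending
  md <- mean(lam)
  rd <- (lam[2L] + lam[3L]) / 2
  nrm <- sqrt(sum(lam^2))
  fa <- if (nrm == 0) 0 else sqrt(1.5) * sqrt(sum((lam - md)^2)) / nrm
  list(e1 = lam[1L], e2 = lam[2L], e3 = lam[3L],
       MD = md, RD = rd, FA = fa, vectors = e$vectors)
}

#' Biomarker maps from a tensor field
#'
#' Computes per-voxel eigenvalues and derived invariants wherever the
#' field is valid; other voxels are `NA`.
#'
#' @param field A [tensor_field()].
#' @return Named list of [volume3d()] maps: `MD`, `FA`, `e1`, `e2`, `e3`,
#'   `RD`.
#' @export
invariant_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d3 <- dim(field$valid)
  nvox <- prod(d3)
  t6 <- matrix(field$tensor6, nrow = nvox, ncol = 6L)
  out <- matrix(NA_real_, nrow = nvox, ncol = 6L,
                dimnames = list(NULL, c("MD", "FA", "e1", "e2", "e3", "RD")))
  for (i in which(as.vector(field$valid))) {
    inv <- compute_invariants(t6[i, ])
    out[i, ] <- c(inv$MD, inv$FA, inv$e1, inv$e2, inv$e3, inv$RD)
  }
  ref <- tensor_ref_volume(field)
  lapply(setNames(colnames(out), colnames(out)), function(nm)
    vol_like(ref, out[, nm],
             intensity_units = if (nm == "FA") "dimensionless" else "mm^2/s"))
}

#' Reject voxels with non-physiological mean diffusivity
#'
#' Voxels with MD strictly above the free-diffusion coefficient of water
#' (default 3e-3 mm^2/s) are removed from the validity mask; the rejected
#' fraction is reported over the previously valid voxels.
#'
#' @param field A [tensor_field()].
#' @param threshold Rejection threshold in mm^2/s; must be positive.
#' @return List with the updated `field`, the retained-voxel `mask`, and
#'   `rejected_fraction`.
#' @export
reject_voxels_md <- function(field, threshold = 3e-3) {
  stopifnot(inherits(field, "tensor_field"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  d3 <- dim(field$valid)
  t6 <- matrix(field$tensor6, prod(d3), 6L)
  md <- array((t6[, 1L] + t6[, 2L] + t6[, 3L]) / 3, d3)  # trace/3
  # strict "above" with a relative guard so round-off at the boundary
  # (e.g. a trace summing to 3x the threshold) does not reject equality
  over <- !is.na(md) & md > threshold * (1 + 1e-9)
  nvalid <- sum(field$valid)
  frac <- if (nvalid == 0L) 0 else sum(over & field$valid) / nvalid
  field$valid <- field$valid & !over
  list(field = field, mask = field$valid, rejected_fraction = frac)
}
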