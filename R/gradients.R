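#' Diffusion gradient scheme
#'
#' Bundle of b-values (s/mm^2) and unit gradient directions. Directions
#' with nonzero b are renormalized to unit length; zero vectors are only
#' accepted where b = 0. The scheme must contain at least one b = 0 entry,
#' its nonzero-b directions must span rank 3, and the outer-product design
#' matrix used by the tensor fit must have rank 6.
#'
#' @param bvals Numeric vector of b-values in s/mm^2.
#' @param bvecs Matrix of direction vectors, one row per entry.
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns")
  if (nrow(bvecs) != length(bvals))
    stop("length mismatch between bval and bvec")
  nrm <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  if (any(nz & nrm < 1e-12))
    stop("nonzero b-value with zero gradient vector")
  bvecs[nrm > 1e-12, ] <- bvecs[nrm > 1e-12, , drop = FALSE] / nrm[nrm > 1e-12]
  if (!any(!nz)) stop("scheme must contain at least one b = 0 entry")
  dirs <- bvecs[nz, , drop = FALSE]
  fit_ready <- nrow(dirs) >= 6L
  if (fit_ready) {
    if (qr(dirs)$rank < 3L)
      stop("nonzero-b directions do not span rank 3 (coplanar scheme)")
    if (qr(quadratic_design(dirs))$rank < 6L)
      stop("direction set has rank-deficient (rank < 6) tensor design matrix")
  }
  structure(list(bvals = bvals, bvecs = bvecs, fit_ready = fit_ready),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d entries; b = {%s} s/mm^2 (%d at b = 0)\n",
              length(x$bvals), paste(unique(x$bvals), collapse = ", "),
              sum(x$bvals == 0)))
  invisible(x)
}

# Rows (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz); with tensor components
# ordered (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) this gives g' D g per row.
quadratic_design <- function(dirs) {
  dirs <- as.matrix(dirs)
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2],
        2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

mat_to_tensor6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])

#' Default icosahedral direction set
#'
#' The 12 vertices of a regular icosahedron, normalized to unit length.
#' This set spans rank 3 and yields a rank-6 tensor design matrix, which is
#' verified when a [gradient_scheme()] is built from it.
#'
#' @param n Number of directions (only 12 is provided).
#' @return A `n x 3` matrix of unit directions.
#' @export
default_directions <- function(n = 12L) {
  if (n != 12L) stop("only the 12-direction icosahedral set is provided")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
             c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

parse_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(vapply(rows, anyNA, logical(1L))))
    stop("non-numeric entries in ", path)
  rows
}

#' Read an FSL-dialect gradient table
#'
#' `bval` holds whitespace-separated b-values; `bvec` holds three rows
#' (x, y, z components). A transposed variant with one row per direction
#' is auto-detected by shape. Directions are renormalized to unit length.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- unlist(parse_numeric_table(bval_path))
  rows <- parse_numeric_table(bvec_path)
  nr <- length(rows)
  lens <- vapply(rows, length, integer(1L))
  if (nr == 3L && length(unique(lens)) == 1L && lens[1L] != 3L) {
    bvecs <- t(do.call(rbind, rows))
  } else if (nr == 3L && all(lens == 3L)) {
    # ambiguous 3x3: FSL convention, rows are components
    bvecs <- t(do.call(rbind, rows))
  } else if (all(lens == 3L)) {
    bvecs <- do.call(rbind, rows)
  } else {
    stop("bvec file must have 3 rows (FSL) or 3 columns")
  }
  if (nrow(bvecs) != length(bvals))
    stop("length mismatch between bval and bvec")
  gradient_scheme(bvals, bvecs)
}

#' Write a gradient scheme as FSL bval/bvec text files
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, `scheme`.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(scheme)
}

#' Diffusion-weighted image series
#'
#' One [volume3d()] per gradient entry, all on a common grid, together
#' with the gradient scheme and the indices of the b = 0 volumes.
#'
#' @param volumes List of [volume3d()] objects, one per scheme entry.
#' @param scheme A [gradient_scheme()].
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(volumes) != length(scheme$bvals))
    stop("number of volumes must equal number of scheme entries")
  ref <- volumes[[1L]]
  ok <- vapply(volumes, function(v) inherits(v, "volume3d") && same_grid(v, ref),
               logical(1L))
  if (!all(ok)) stop("all DWI volumes must share one grid and spacing")
  structure(list(volumes = volumes, scheme = scheme,
                 s0_index = which(scheme$bvals == 0)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> %d volumes (%d at b = 0), grid %s\n",
              length(x$volumes), length(x$s0_index),
              paste(dim(x$volumes[[1L]]$data), collapse = " x ")))
  invisible(x)
}

# Signal matrix (voxels x gradients) from a dwi_series.
dwi_signal_matrix <- function(dwi) {
  matrix(unlist(lapply(dwi$volumes, function(v) as.vector(v$data)),
                use.names = FALSE),
         nrow = length(dwi$volumes[[1L]]$data),
         ncol = length(dwi$volumes))
}
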