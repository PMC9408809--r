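# Small 2D image operations (Gaussian smoothing, Sobel gradients, Otsu
# threshold, Canny edges, connected components, bilinear sampling) used by
# the registration chain. Implemented here because no pre-installed package
# provides them for plain matrices.

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along rows (along = 1) or columns (along = 2) with
# replicate padding.
conv1d_replicate <- function(M, k, along = 1L) {
  if (along == 2L) return(t(conv1d_replicate(t(M), k, 1L)))
  r <- (length(k) - 1L) / 2L
  nr <- nrow(M)
  pad <- rbind(M[rep(1L, r), , drop = FALSE], M,
               M[rep(nr, r), , drop = FALSE])
  out <- matrix(0, nr, ncol(M))
  for (i in seq_along(k))
    out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  out
}

smooth2d <- function(M, sigma) {
  if (sigma <= 0) return(M)
  k <- gauss_kernel(sigma)
  conv1d_replicate(conv1d_replicate(M, k, 1L), k, 2L)
}

# Shift with replicate border: positive di moves content down (value at
# [i, j] comes from [i - di, j - dj]).
shift2 <- function(M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  M[ri, ci, drop = FALSE]
}

sobel_gradients <- function(M) {
  gx <- (shift2(M, 0, -1) - shift2(M, 0, 1)) * 2 +
    (shift2(M, -1, -1) - shift2(M, -1, 1)) +
    (shift2(M, 1, -1) - shift2(M, 1, 1))
  gy <- (shift2(M, -1, 0) - shift2(M, 1, 0)) * 2 +
    (shift2(M, -1, -1) - shift2(M, 1, -1)) +
    (shift2(M, -1, 1) - shift2(M, 1, 1))
  list(gx = gx / 8, gy = gy / 8)
}

# Otsu's threshold maximizing between-class variance on a 256-bin
# histogram.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w <- cumsum(h); mu <- cumsum(h * mids)
  wtot <- w[nbins]; mtot <- mu[nbins]
  w0 <- w[-nbins]; w1 <- wtot - w0
  m0 <- mu[-nbins] / pmax(w0, 1e-12)
  m1 <- (mtot - mu[-nbins]) / pmax(w1, 1e-12)
  bc <- w0 * w1 * (m0 - m1)^2
  bc[w0 == 0 | w1 == 0] <- -Inf
  mids[which.max(bc)]
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, and hysteresis with
# thresholds tied to the Otsu level of the gradient magnitude
# (high = high_frac * otsu, low = low_frac * otsu).
canny_edges <- function(img, sigma = 1.4, low_frac = 0.5, high_frac = 1.0) {
  sm <- smooth2d(img, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(g$gy, g$gx)                # radians
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: E-W, 1: NE-SW, 2: N-S, 3: NW-SE
  n1 <- matrix(0, nrow(img), ncol(img)); n2 <- n1
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L), "1" = c(1L, 1L),
                "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == s
    n1[sel] <- shift2(mag, d[1L], d[2L])[sel]
    n2[sel] <- shift2(mag, -d[1L], -d[2L])[sel]
  }
  nms <- mag >= n1 & mag >= n2 & mag > 0
  lev <- otsu_threshold(mag[mag > 0])
  strong <- nms & mag >= high_frac * lev
  weak <- nms & mag >= low_frac * lev
  repeat {
    grown <- strong
    for (di in -1:1) for (dj in -1:1)
      grown <- grown | shift2(strong, di, dj)
    grown <- grown & weak
    if (all(grown == strong)) break
    strong <- grown
  }
  strong
}

# 8-connected component labels of a logical matrix via iterative
# min-label propagation; returns an integer matrix (0 = background).
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  repeat {
    cur <- lab
    cur[!mask] <- big
    mn <- cur
    for (di in -1:1) for (dj in -1:1) {
      sh <- shift2(cur, di, dj)
      mn <- pmin(mn, sh)
    }
    mn[!mask] <- 0L
    mn[mask & mn == big] <- lab[mask & mn == big]
    if (all(mn == lab)) break
    lab <- mn
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

# Bilinear sampling of matrix M at (fractional) row/col coordinate
# matrices; coordinates are clamped to the image domain.
bilinear_sample <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  rv <- as.vector(r0); cv <- as.vector(c0)
  out <- M[cbind(rv, cv)] * (1 - fr) * (1 - fc) +
    M[cbind(rv + 1L, cv)] * fr * (1 - fc) +
    M[cbind(rv, cv + 1L)] * (1 - fr) * fc +
    M[cbind(rv + 1L, cv + 1L)] * fr * fc
  matrix(out, nrow(r), ncol(r))
}

#' Dice overlap coefficient
#'
#' @param a,b Logical arrays of equal shape.
#' @return `2 |a & b| / (|a| + |b|)`; 1 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Per-class Dice between two label maps
#'
#' @param labels,truth Label arrays or [label_map()]s on a common grid.
#' @param classes Label values to score.
#' @return Named numeric vector of Dice coefficients.
#' @export
dice_per_class <- function(labels, truth, classes = 1:3) {
  la <- if (inherits(labels, "volume3d")) labels$data else labels
  tr <- if (inherits(truth, "volume3d")) truth$data else truth
  out <- vapply(classes, function(k) dice_coefficient(la == k, tr == k),
                numeric(1L))
  names(out) <- region_names[classes]
  out
}
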