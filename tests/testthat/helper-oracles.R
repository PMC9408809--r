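# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive rank-based Kruskal-Wallis H for two groups (tie-corrected).
brute_force_kw_h <- function(a, b) {
  x <- c(a, b)
  g <- c(rep(1L, length(a)), rep(2L, length(b)))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    (sum(r[g == 1L])^2 / length(a) + sum(r[g == 2L])^2 / length(b)) -
    3 * (n + 1)
  ties <- table(x)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / cf
}

# Mean of a Rician-distributed magnitude (numeric integration with scaled
# Bessel to stay finite at high SNR).
rician_mean_oracle <- function(A, sigma) {
  f <- function(r) {
    z <- r * A / sigma^2
    (r^2 / sigma^2) * exp(-(r - A)^2 / (2 * sigma^2)) *
      besselI(z, 0, expon.scaled = TRUE)
  }
  integrate(f, 0, A + 12 * sigma, rel.tol = 1e-10)$value
}

# Plain point-in-cylinder test for a cylinder matrix (no grid, no
# periodic images beyond the naive 27 shifts).
r_point_in_cylinders <- function(p, cyl, edge) {
  w <- p %% edge
  shifts <- as.matrix(expand.grid(sx = c(-edge, 0, edge),
                                  sy = c(-edge, 0, edge),
                                  sz = c(-edge, 0, edge)))
  for (i in seq_len(nrow(cyl))) {
    for (s in seq_len(nrow(shifts))) {
      p1 <- cyl[i, 1:3] + shifts[s, ]
      p2 <- cyl[i, 4:6] + shifts[s, ]
      d <- p2 - p1
      len2 <- sum(d^2)
      t <- if (len2 > 0) sum((w - p1) * d) / len2 else 0
      t <- min(max(t, 0), 1)
      if (sum((w - p1 - t * d)^2) <= cyl[i, 7]^2) return(TRUE)
    }
  }
  FALSE
}

# Small-grid phantom configuration used where full default size is not
# needed; keeps unit tests fast while exercising the same code paths.
small_phantom_config <- function(...) {
  phantom_config(lge_dim_inplane = c(64L, 64L),
                 cdti_dim_inplane = c(44L, 44L),
                 endo_radius_mm = 11, epi_radius_mm = 19, ...)
}
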