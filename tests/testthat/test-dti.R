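make_single_voxel_field <- function(t6vec) {
  t6 <- array(0, c(1, 1, 1, 6)); t6[1, 1, 1, ] <- t6vec
  ref <- volume3d(array(0, c(1, 1, 1)), c(8, 2, 2))
  tensor_field(t6, array(TRUE, c(1, 1, 1)), ref)
}

default_scheme <- function(b = 350) {
  gradient_scheme(c(0, rep(b, 12)), rbind(c(0, 0, 0), default_directions()))
}

test_that("forward synthesis then log-linear fit is the identity", {
  sch <- default_scheme()
  # diagonal example plus randomly rotated positive-definite tensors
  set.seed(42)
  cases <- list(c(2e-3, 1e-3, 0.5e-3, 0, 0, 0))
  for (i in 1:4) {
    A <- matrix(rnorm(9), 3)
    Q <- qr.Q(qr(A))
    lam <- sort(runif(3, 0.3e-3, 2.8e-3), decreasing = TRUE)
    D <- Q %*% diag(lam) %*% t(Q)
    cases[[i + 1]] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  for (t6vec in cases) {
    tf <- make_single_voxel_field(t6vec)
    dwi <- synthesize_dwi(tf, sch, s0 = 100, snr = Inf)
    fit <- fit_tensor_loglinear(dwi)
    expect_lt(max(abs(fit$tensor6[1, 1, 1, ] - t6vec)) / max(abs(t6vec)),
              1e-12)
  }
})

test_that("isotropic signal recovers an isotropic tensor", {
  sch <- default_scheme()
  d <- 1.5e-3
  tf <- make_single_voxel_field(c(d, d, d, 0, 0, 0))
  dwi <- synthesize_dwi(tf, sch, s0 = 1, snr = Inf)
  # direct scalar check of the forward model
  expect_equal(dwi$volumes[[2]]$data[1, 1, 1], exp(-350 * d),
               tolerance = 1e-12)
  fit <- fit_tensor_loglinear(dwi)
  expect_equal(fit$tensor6[1, 1, 1, 1:3], rep(d, 3), tolerance = 1e-12)
  expect_equal(fit$tensor6[1, 1, 1, 4:6], rep(0, 3), tolerance = 1e-15)
})

test_that("voxels with nonpositive signal are masked, others unaffected", {
  sch <- default_scheme()
  d <- 1.5e-3
  t6 <- array(0, c(1, 1, 2, 6))
  t6[1, 1, 1, 1:3] <- d; t6[1, 1, 2, 1:3] <- d
  ref <- volume3d(array(0, c(1, 1, 2)), c(8, 2, 2))
  tf <- tensor_field(t6, array(TRUE, c(1, 1, 2)), ref)
  dwi <- synthesize_dwi(tf, sch, s0 = 100, snr = Inf)
  dwi$volumes[[3]]$data[1, 1, 2] <- 0  # kill one direction of voxel 2
  fit <- fit_tensor_loglinear(dwi)
  expect_true(fit$valid[1, 1, 1])
  expect_false(fit$valid[1, 1, 2])
  expect_equal(fit$tensor6[1, 1, 1, 1], d, tolerance = 1e-12)
})

test_that("fit refuses schemes without enough directions or b = 0", {
  sch2 <- gradient_scheme(c(0, 350), rbind(c(0, 0, 0), c(1, 0, 0)))
  v <- lapply(1:2, function(i) volume3d(array(1, c(1, 2, 2)), c(8, 2, 2)))
  expect_error(fit_tensor_loglinear(dwi_series(v, sch2)),
               "fewer than 6")
})

test_that("tensor invariants match their defining formulas", {
  # isotropic: MD = RD = d, FA = 0
  inv <- compute_invariants(diag(rep(2e-3, 3)))
  expect_equal(inv$MD, 2e-3); expect_equal(inv$RD, 2e-3)
  expect_equal(inv$FA, 0)
  # rank-1 limit: FA = 1, RD = 0
  inv <- compute_invariants(diag(c(1, 0, 0)))
  expect_equal(inv$FA, 1); expect_equal(inv$RD, 0)
  # infarct-region median eigenvalues: MD and RD from the definitions
  inv <- compute_invariants(diag(c(2.28, 1.83, 1.42) * 1e-3))
  expect_equal(inv$MD, 1.843333333e-3, tolerance = 1e-9)
  expect_equal(inv$RD, 1.625e-3, tolerance = 1e-12)
  # exact identities
  expect_equal(inv$MD, (inv$e1 + inv$e2 + inv$e3) / 3)
  expect_equal(inv$RD, (inv$e2 + inv$e3) / 2)
  # zero tensor: FA defined 0
  expect_equal(compute_invariants(matrix(0, 3, 3))$FA, 0)
  # symmetric-input guard
  M <- diag(3); M[1, 2] <- 1e-3
  expect_error(compute_invariants(M), "symmetric")
})

test_that("FA is scale-invariant and MD >= RD iff e1 >= (e2+e3)/2", {
  set.seed(7)
  for (i in 1:25) {
    A <- matrix(rnorm(9), 3)
    D <- (A + t(A)) / 2
    inv <- compute_invariants(D)
    inv2 <- compute_invariants(3.7 * D)
    expect_equal(inv$FA, inv2$FA, tolerance = 1e-10)
    expect_true(inv$e1 >= inv$e2 && inv$e2 >= inv$e3)
    expect_equal(inv$MD >= inv$RD, inv$e1 >= (inv$e2 + inv$e3) / 2)
  }
})

test_that("MD rejection is strictly above threshold and reports the fraction", {
  d3 <- c(1, 10, 10)
  t6 <- array(0, c(d3, 6))
  t6[, , , 1:3] <- 1.5e-3
  # voxel at exactly 3e-3 is kept, one strictly above is rejected
  t6[1, 1, 1, 1:3] <- 3e-3
  t6[1, 1, 2, 1:3] <- 3.1e-3
  ref <- volume3d(array(0, d3), c(8, 2, 2))
  tf <- tensor_field(t6, array(TRUE, d3), ref)
  rej <- reject_voxels_md(tf)
  expect_true(rej$mask[1, 1, 1])
  expect_false(rej$mask[1, 1, 2])
  expect_equal(rej$rejected_fraction, 1 / 100)
  # 2% injected outliers -> fraction 0.02
  t6[, , , 1:3] <- 1.5e-3
  t6[1, 1, 1:2, 1] <- 9e-3; t6[1, 1, 1:2, 2] <- 9e-3; t6[1, 1, 1:2, 3] <- 9e-3
  rej <- reject_voxels_md(tensor_field(t6, array(TRUE, d3), ref))
  expect_equal(rej$rejected_fraction, 0.02)
  # all below -> zero
  t6[, , , 1:3] <- 1.5e-3
  rej <- reject_voxels_md(tensor_field(t6, array(TRUE, d3), ref))
  expect_equal(rej$rejected_fraction, 0)
  expect_error(reject_voxels_md(tf, threshold = 0), "positive")
})
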