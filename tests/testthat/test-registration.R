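annulus_slice <- function(n, spacing, r_in, r_out, value = 100) {
  cx <- (n - 1) * spacing / 2
  x <- matrix((seq_len(n) - 1) * spacing, n, n, byrow = TRUE)
  y <- matrix((seq_len(n) - 1) * spacing, n, n)
  r <- sqrt((x - cx)^2 + (y - cx)^2)
  (r >= r_in & r <= r_out) * value
}

test_that("rigid alignment from header quaternions recovers known transforms", {
  arr <- array(0, c(3, 20, 20)); arr[, 8:12, 8:12] <- 1
  v1 <- volume3d(arr, c(8, 2, 2))
  # identity case
  tf <- rigid_align(v1, v1)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, rep(0, 3), tolerance = 1e-9)
  # apply-then-invert is the identity on a point cloud
  set.seed(8)
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  expect_equal(apply_rigid(invert_rigid(tf), apply_rigid(tf, pts)), pts,
               tolerance = 1e-9)
  # a known 10-degree rotation about z is recovered from the metadata
  th <- 10 * pi / 180
  q10 <- c(cos(th / 2), 0, 0, sin(th / 2))
  v2 <- volume3d(arr, c(8, 2, 2), orientation = q10)
  tf2 <- rigid_align(v1, v2)
  ang <- 2 * acos(min(1, abs(tf2$q[1])))
  expect_equal(ang, th, tolerance = 1e-6)
  expect_equal(apply_rigid(invert_rigid(tf2), apply_rigid(tf2, pts)), pts,
               tolerance = 1e-9)
  # degenerate orientation is rejected at construction
  expect_error(volume3d(arr, c(8, 2, 2), orientation = c(0, 0, 0, 0)),
               "zero norm")
})

test_that("longitudinal rescaling maps basal and apical slices exactly", {
  z <- c(0, 8, 16, 24, 32)
  out <- longitudinal_rescale(z, 0, 24)
  expect_equal(out, c(0, 6, 12, 18, 24))
  expect_equal(diff(out), rep(6, 4))  # uniform interior scaling (0.75)
  # identity when the spans match
  expect_equal(longitudinal_rescale(z, 0, 32), z)
  # endpoints map exactly by construction
  out2 <- longitudinal_rescale(c(3, 9, 21), -5, 7)
  expect_equal(out2[1], -5); expect_equal(out2[3], 7)
  expect_error(longitudinal_rescale(5, 0, 24), "two slices")
  expect_error(longitudinal_rescale(c(3, 3), 0, 24), "zero slice span")
})

test_that("Canny contour detection finds the annulus borders", {
  img <- annulus_slice(80, 1, 20, 30)
  ct <- detect_myocardial_edges(img, c(1, 1))
  r_endo <- sqrt((ct$endo[, 1] - ct$center[1])^2 +
                   (ct$endo[, 2] - ct$center[2])^2)
  r_epi <- sqrt((ct$epi[, 1] - ct$center[1])^2 +
                  (ct$epi[, 2] - ct$center[2])^2)
  expect_lt(abs(mean(r_endo) - 20), 1)
  expect_lt(abs(mean(r_epi) - 30), 1)
  # epi encloses endo: strictly larger mean radius, larger polygon area
  shoelace <- function(p) abs(sum(p[-nrow(p), 1] * p[-1, 2] -
                                    p[-1, 1] * p[-nrow(p), 2])) / 2
  expect_gt(shoelace(ct$epi), shoelace(ct$endo))
  expect_error(detect_myocardial_edges(matrix(0, 40, 40), c(1, 1)),
               "no myocardial contours")
})

test_that("weighted mask averaging honors its weight formula", {
  a <- annulus_slice(60, 1, 20, 30) > 0
  b <- annulus_slice(60, 1, 22, 32) > 0
  # z_target at an endpoint returns that mask exactly
  expect_identical(weighted_average_masks(a, b, 8, 0, 0), b)
  # identical masks at the midpoint return the mask
  expect_identical(weighted_average_masks(a, a, 8, 0, 4), a)
  # midpoint of two concentric annuli: mean radii within one voxel of 21/31
  m <- weighted_average_masks(b, a, 8, 0, 4)
  cx <- 59 / 2
  idx <- which(m, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 1 - cx)^2 + (idx[, 2] - 1 - cx)^2)
  expect_lt(abs(min(r) - 21), 1)
  expect_lt(abs(max(r) - 31), 1)
  expect_error(weighted_average_masks(a, b, 8, 0, 9), "outside")
})

test_that("demons registration is stable on the identity and recovers a dilation", {
  lab <- annulus_slice(60, 1, 15, 24, 1)
  storage.mode(lab) <- "integer"
  lab[annulus_slice(60, 1, 15, 24) > 0 &
        annulus_slice(60, 1, 14, 19.5) > 0] <- 2L
  # identity: near-zero field, unchanged labels
  res <- nonrigid_register(lab, lab > 0)
  expect_lt(max(abs(c(res$field$dy, res$field$dx))), 0.1)
  expect_identical(res$labels, lab)
  # fixed = moving dilated radially by ~2 voxels
  fixed <- annulus_slice(60, 1, 13, 26) > 0
  res2 <- nonrigid_register(lab, fixed, n_iter = 300)
  expect_gte(res2$dice, 0.95)
  expect_true(all(res2$labels %in% 0:3))
  expect_error(nonrigid_register(lab * 0L, fixed), "empty masks")
})

test_that("one-hot z interpolation keeps labels and breaks ties severely", {
  st <- array(0L, c(2, 2, 2))
  st[1, , ] <- 1L; st[2, , ] <- 1L
  # constant column stays constant
  out <- interpolate_labels_to_slices(st, c(0, 8), 4)
  expect_true(all(out == 1L))
  # target at an existing slice returns that slice unchanged
  st[2, , ] <- 3L
  expect_identical(interpolate_labels_to_slices(st, c(0, 8), 8)[1, , ],
                   st[2, , ])
  # 50/50 tie between border and infarct goes to infarct
  st[1, , ] <- 2L
  expect_true(all(interpolate_labels_to_slices(st, c(0, 8), 4) == 3L))
  # nearest-slice extrapolation outside the span
  expect_identical(interpolate_labels_to_slices(st, c(0, 8), -4)[1, , ],
                   st[1, , ])
  expect_error(interpolate_labels_to_slices(array(0L, c(0, 2, 2)),
                                            numeric(0), 1), "empty")
})

test_that("the full chain maps the label alphabet onto the cDTI myocardium", {
  ph <- make_lv_phantom(small_phantom_config(seed = 4L))
  rois <- phantom_rois(ph$truth_labels_diastole)
  thr <- estimate_region_stats(ph$lge, rois$remote, rois$infarct)
  lab_d <- classify_voxels(ph$lge, thr, ph$truth_labels_diastole$data > 0)
  b0 <- cardti:::b0_volume(ph$dwi)
  reg <- register_labels(lab_d, ph$lge, b0)
  expect_true(all(reg$labels$data %in% 0:3))
  # output grid matches the cDTI grid
  expect_identical(dim(reg$labels$data), dim(b0$data))
  # the labeled set agrees well with the systolic myocardium
  d <- dice_coefficient(reg$labels$data > 0, ph$truth_labels_systole$data > 0)
  expect_gte(d, 0.9)
  # per-stage diagnostics are reported
  expect_length(reg$diagnostics$slice_dice, dim(ph$lge$data)[1])
  expect_true(all(reg$diagnostics$slice_dice > 0.8))
})
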