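test_that("phantom generation is deterministic for a fixed seed", {
  cfg <- small_phantom_config(seed = 9L)
  a <- make_lv_phantom(cfg)
  b <- make_lv_phantom(cfg)
  expect_identical(a$lge$data, b$lge$data)
  expect_identical(a$truth_labels_diastole$data, b$truth_labels_diastole$data)
  expect_identical(lapply(a$dwi$volumes, `[[`, "data"),
                   lapply(b$dwi$volumes, `[[`, "data"))
})

test_that("a zero-degree infarct sector leaves only remote myocardium", {
  ph <- make_lv_phantom(small_phantom_config(infarct_sector_deg = 0))
  expect_setequal(unique(as.vector(ph$truth_labels_diastole$data)), c(0L, 1L))
  expect_setequal(unique(as.vector(ph$truth_labels_systole$data)), c(0L, 1L))
})

test_that("config validation rejects impossible geometry", {
  expect_error(phantom_config(infarct_sector_deg = 320, border_rim_deg = 30),
               "360")
  expect_error(phantom_config(endo_radius_mm = 50, epi_radius_mm = 62),
               "field of view")
  expect_error(phantom_config(transmural_extent = 0), "transmural")
  expect_error(phantom_config(systolic_z_scale = 1.2), "z_scale")
})

test_that("fitting tensors on the noise-free phantom recovers the configured eigenvalues", {
  cfg <- small_phantom_config(snr = Inf)
  ph <- make_lv_phantom(cfg)
  fit <- fit_tensor_loglinear(ph$dwi, mask = ph$truth_labels_systole$data > 0)
  lam_cfg <- cfg$region_eigenvalues
  idx <- which(ph$truth_labels_systole$data > 0)
  # sample a subset of voxels from each region and compare eigenvalues
  set.seed(3)
  for (k in 1:3) {
    vox <- which(ph$truth_labels_systole$data == k)
    vox <- sample(vox, 25)
    d3 <- dim(ph$truth_labels_systole$data)
    t6 <- matrix(fit$tensor6, prod(d3), 6)
    for (v in vox) {
      inv <- compute_invariants(t6[v, ])
      rel <- abs(c(inv$e1, inv$e2, inv$e3) - lam_cfg[k, ]) / lam_cfg[k, ]
      expect_lt(max(rel), 1e-9)
    }
  }
})

test_that("synthesize_dwi follows the monoexponential forward model", {
  d <- 1.5e-3
  t6 <- array(0, c(1, 2, 2, 6)); t6[, , , 1] <- d; t6[, , , 2] <- d
  t6[, , , 3] <- d
  ref <- volume3d(array(0, c(1, 2, 2)), c(8, 2, 2))
  tf <- tensor_field(t6, array(TRUE, c(1, 2, 2)), ref)
  sch <- gradient_scheme(c(0, rep(350, 12)),
                         rbind(c(0, 0, 0), default_directions()))
  dwi <- synthesize_dwi(tf, sch, s0 = 100, snr = Inf)
  # b = 0 gives s0 exactly; any direction gives exp(-b d) for isotropic D
  expect_true(all(dwi$volumes[[1]]$data == 100))
  for (j in 2:13)
    expect_equal(as.vector(dwi$volumes[[j]]$data),
                 rep(100 * exp(-0.525), 4), tolerance = 1e-12)
  expect_error(synthesize_dwi(tf, sch, s0 = -1), "nonnegative")
})

test_that("Rician noise has the predicted moments", {
  # sigma = 0 is the exact identity
  x <- array(runif(100), c(4, 5, 5))
  expect_identical(add_rician_noise(x, 0), x)
  expect_error(add_rician_noise(x, -1), "nonnegative")
  # magnitude output is nonnegative and mean matches the Rician moment
  sig <- matrix(100, 200, 100)  # 2e4 samples at SNR 16
  noisy <- add_rician_noise(sig, 6.25, seed = 11)
  expect_true(all(noisy >= 0))
  expect_equal(mean(noisy), rician_mean_oracle(100, 6.25), tolerance = 0.02)
  # at zero signal the output is Rayleigh with variance (2 - pi/2) sigma^2
  z <- add_rician_noise(rep(0, 1e5), 2, seed = 12)
  expect_equal(var(z), (2 - pi / 2) * 4, tolerance = 0.03)
})

test_that("the noise-free phantom segments back to its truth labels", {
  cfg <- small_phantom_config(
    lge_intensity = c(mu_remote = 100, sigma_remote = 0,
                      mu_infarct = 300, sigma_infarct = 0),
    lge_background = c(20, 0))
  ph <- make_lv_phantom(cfg)
  rois <- phantom_rois(ph$truth_labels_diastole)
  thr <- estimate_region_stats(ph$lge, rois$remote, rois$infarct)
  lab <- classify_voxels(ph$lge, thr, ph$truth_labels_diastole$data > 0)
  myo <- ph$truth_labels_diastole$data > 0
  agree <- mean(lab$data[myo] == ph$truth_labels_diastole$data[myo])
  expect_gte(agree, 0.99)
})

test_that("regional RD medians on the default phantom order infarct > border > remote", {
  ph <- make_lv_phantom(small_phantom_config())
  fit <- fit_tensor_loglinear(ph$dwi, mask = ph$truth_labels_systole$data > 0)
  maps <- invariant_maps(fit)
  pooled <- pool_by_region(maps["RD"], ph$truth_labels_systole)
  med <- tapply(pooled$value, pooled$region, median)
  expect_true(med["infarct"] > med["border"])
  expect_true(med["border"] > med["remote"])
})
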