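# Short-duration configs keep the walk tests fast while leaving the
# physics intact.
short_cfg <- function(...) sim_config(duration_s = 0.0051, ...)

test_that("ECV measurement matches closed-form cylinder volumes", {
  cfg <- sim_config()
  s_empty <- build_cell_structure(1.0, cfg, seed = 1)
  expect_identical(measure_ecv(s_empty, 1e4, seed = 1)$ecv, 1.0)
  expect_equal(s_empty$measured_ecv, 1.0)
  expect_equal(nrow(s_empty$cylinders), 0L)
  # single axis-aligned cylinder spanning the cube: ECV = 1 - pi r^2 / e^2
  r <- 0.1
  cyl <- matrix(c(0.25, 0.25, -0.1, 0.25, 0.25, 0.6, r), 1, 7)
  s1 <- cardti:::new_cell_structure(cyl, 0.5, NA, NA)
  m <- measure_ecv(s1, 1e5, seed = 2)
  expect_lt(abs(m$ecv - (1 - pi * r^2 / 0.25)), 3 * m$se + 1e-9)
  expect_error(measure_ecv(s1, 100), "at least 1e4")
})

test_that("doubling the sample count halves the estimator variance", {
  r <- 0.08
  cyl <- matrix(c(0.25, 0.25, -0.1, 0.25, 0.25, 0.6, r), 1, 7)
  s1 <- cardti:::new_cell_structure(cyl, 0.5, NA, NA)
  v <- function(n, seeds) var(vapply(seeds, function(sd)
    measure_ecv(s1, n, seed = sd)$ecv, numeric(1)))
  set.seed(3)
  v1 <- v(1e4, 1:40)
  v2 <- v(2e4, 41:80)
  expect_lt(v2 / v1, 0.85)
})

test_that("compiled point-in-cylinder agrees with a plain R oracle", {
  cfg <- sim_config()
  s <- build_cell_structure(0.6, cfg, seed = 5)
  set.seed(6)
  pts <- matrix(runif(3 * 200, 0, 0.5), ncol = 3)
  got <- cardti:::cpp_points_inside(pts, s$cylinders, s$edge)
  want <- vapply(seq_len(200), function(i)
    r_point_in_cylinders(pts[i, ], s$cylinders, s$edge), logical(1))
  expect_identical(as.vector(got), want)
})

test_that("cell structures respect the configured diameters and ECV band", {
  cfg <- sim_config()
  for (target in c(0.4, 0.7)) {
    s <- build_cell_structure(target, cfg, seed = 7)
    expect_lte(abs(s$measured_ecv - target), 0.05)
    radii <- s$cylinders[, "r"] * 2000  # diameters in um
    expect_true(all(radii >= 9 - 1e-9 & radii <= 20 + 1e-9))
  }
})

test_that("free diffusion obeys the Einstein relation", {
  cfg <- sim_config(n_walkers = 4000L, seed = 13L)
  s <- build_cell_structure(1.0, cfg)
  w <- simulate_walkers(s, cfg)
  msd <- rowSums(w$displacements^2)
  se <- sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - 6 * cfg$d0_extra * cfg$duration_s), 3 * se)
  # per-axis displacement variance 2 D0 t
  for (ax in 1:3) {
    v <- var(w$displacements[, ax])
    expect_equal(v, 2 * cfg$d0_extra * cfg$duration_s, tolerance = 0.1)
  }
})

test_that("zero-duration walks return zero displacements", {
  cfg <- sim_config(duration_s = 0, n_walkers = 50L)
  s <- build_cell_structure(1.0, cfg)
  w <- simulate_walkers(s, cfg)
  expect_true(all(w$displacements == 0))
})

test_that("walks are bitwise deterministic for a fixed seed", {
  cfg <- short_cfg(n_walkers = 200L, seed = 17L)
  s <- build_cell_structure(0.6, cfg, seed = 18L)
  w1 <- simulate_walkers(s, cfg)
  w2 <- simulate_walkers(s, cfg)
  expect_identical(w1$displacements, w2$displacements)
})

test_that("extracellular walkers never end up inside a cylinder", {
  cfg <- short_cfg(n_walkers = 200L, seed = 19L)
  s <- build_cell_structure(0.5, cfg, seed = 20L)
  w <- simulate_walkers(s, cfg)
  inside <- cardti:::cpp_points_inside(w$final, s$cylinders, s$edge)
  expect_false(any(inside))
  inside0 <- cardti:::cpp_points_inside(w$start, s$cylinders, s$edge)
  expect_false(any(inside0))
})

test_that("tensor readout recovers a known anisotropic Gaussian", {
  set.seed(23)
  t <- 0.051
  lam <- c(2, 1, 0.5) * 1e-3
  n <- 20000
  disp <- cbind(rnorm(n, 0, sqrt(2 * t * lam[1])),
                rnorm(n, 0, sqrt(2 * t * lam[2])),
                rnorm(n, 0, sqrt(2 * t * lam[3])))
  fit <- displacements_to_tensor(disp, t = t)
  rec <- c(fit$invariants$e1, fit$invariants$e2, fit$invariants$e3)
  se <- lam * sqrt(2 / n)
  expect_true(all(abs(rec - lam) < 3.5 * se))
  # rank-1 limit: all displacement along x
  disp1 <- cbind(rnorm(n, 0, sqrt(2 * t * 1e-3)), 0, 0)
  fit1 <- displacements_to_tensor(disp1, t = t)
  expect_lt(abs(fit1$invariants$e2), 1e-9)
  expect_equal(fit1$invariants$FA, 1, tolerance = 1e-6)
  # degenerate direction set is refused
  expect_error(displacements_to_tensor(disp, directions = cbind(1, 0, 0)[rep(1, 12), ],
                                       t = t), "degenerate")
})

test_that("restriction lowers MD and the principal axis follows the trees", {
  cfg <- sim_config(n_walkers = 1500L, seed = 29L)
  s <- build_cell_structure(0.4, cfg, seed = 30L)
  w <- simulate_walkers(s, cfg)
  fit <- displacements_to_tensor(w)
  expect_lt(fit$invariants$MD, cfg$d0_extra)
  expect_lt(fit$invariants$RD, fit$invariants$e1)
  # e1 direction within 10 degrees of the tree axis (z) at ECV <= 0.5
  e1dir <- fit$invariants$vectors[, 1]
  expect_gt(abs(e1dir[3]), cos(10 * pi / 180))
})

test_that("the reflecting-membrane alternative preserves the invariants", {
  cfg <- short_cfg(n_walkers = 400L, seed = 31L, membrane = "reflect")
  s <- build_cell_structure(0.5, cfg, seed = 32L)
  w <- simulate_walkers(s, cfg)
  inside <- cardti:::cpp_points_inside(w$final, s$cylinders, s$edge)
  expect_false(any(inside))
  fit <- displacements_to_tensor(w)
  expect_lt(fit$invariants$MD, cfg$d0_extra)
})

test_that("sweep tables are deterministic and carry per-run biomarkers", {
  cfg <- short_cfg(n_walkers = 300L, seed = 37L)
  sw1 <- run_ecv_sweep(cfg, target_ecvs = c(0.6, 1.0),
                       structures_per_ecv = 1L, repeats = 2L)
  sw2 <- run_ecv_sweep(cfg, target_ecvs = c(0.6, 1.0),
                       structures_per_ecv = 1L, repeats = 2L)
  expect_identical(sw1$runs, sw2$runs)
  expect_equal(nrow(sw1$runs), 4)
  expect_named(sw1$clusters, c("target_ecv", "measured_ecv", "MD", "FA",
                               "e1", "e2", "e3", "RD"))
})

test_that("sim config validates its time base", {
  expect_error(sim_config(dt_s = 0), "positive")
  expect_error(sim_config(duration_s = 0.0515, dt_s = 1e-2), "multiple")
  expect_error(build_cell_structure(0.1, sim_config()), "0.2")
})
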