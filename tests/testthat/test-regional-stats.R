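test_that("pooling assigns every labeled voxel to exactly one region", {
  lab <- label_map(array(c(0L, 1L, 1L, 2L, 3L, 3L, 3L, 0L), c(2, 2, 2)),
                   spacing_mm = c(8, 2, 2))
  m <- array(seq_len(8), c(2, 2, 2))
  pooled <- pool_by_region(list(MD = m), lab)
  expect_equal(nrow(pooled), 6)  # conservation: labeled voxel count
  expect_equal(as.vector(table(pooled$region)), c(2, 1, 3))
  # all-remote labels leave border and infarct empty
  lab2 <- label_map(array(1L, c(2, 2, 2)), spacing_mm = c(8, 2, 2))
  pooled2 <- pool_by_region(list(MD = m), lab2)
  expect_equal(sum(pooled2$region == "border"), 0)
  expect_equal(sum(pooled2$region == "infarct"), 0)
  # excluded voxels are dropped from the pool
  valid <- array(TRUE, c(2, 2, 2)); valid[1, 2, 2] <- FALSE
  expect_equal(nrow(pool_by_region(list(MD = m), lab, valid = valid)), 5)
  expect_error(pool_by_region(list(MD = m[1, , ]), lab), "grid mismatch")
})

test_that("pooled region means recover the generator's configured means", {
  set.seed(21)
  lab <- label_map(array(sample(1:3, 4000, TRUE), c(10, 20, 20)),
                   spacing_mm = c(8, 2, 2))
  mu <- c(1, 5, 9)
  m <- array(rnorm(4000, mu[lab$data], 0.5), c(10, 20, 20))
  pooled <- pool_by_region(list(q = m), lab)
  got <- tapply(pooled$value, pooled$region, mean)
  expect_equal(as.numeric(got), mu, tolerance = 0.05)
})

test_that("the Anderson-Darling test behaves under null and gross non-normality", {
  set.seed(31)
  x <- rnorm(500)
  res <- anderson_darling(x)
  expect_gte(res$A2, 0)
  expect_gt(res$p, 0.01)
  bimodal <- c(rnorm(250, -5), rnorm(250, 5))
  expect_lt(anderson_darling(bimodal)$p, 0.01)
  expect_error(anderson_darling(rnorm(5)), "n >= 8")
  expect_error(anderson_darling(rep(1, 20)), "constant")
})

test_that("two-group Kruskal-Wallis H matches the brute-force rank oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  res <- kruskal_wallis_pairwise(g)
  expect_equal(res$H, brute_force_kw_h(g$a, g$b), tolerance = 1e-12)
  expect_equal(res$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  # with ties the tie-corrected oracle still agrees
  g2 <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4, 6))
  expect_equal(kruskal_wallis_pairwise(g2)$H,
               brute_force_kw_h(g2$a, g2$b), tolerance = 1e-12)
  # identical samples: H = 0, adjusted p = 1
  res <- kruskal_wallis_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$H, 0)
  expect_equal(res$p_adj, 1)
  expect_error(kruskal_wallis_pairwise(list(a = 1, b = c(1, 2))),
               "fewer than 2")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(41)
  a <- rnorm(40); b <- rnorm(40, 1)
  h1 <- kruskal_wallis_pairwise(list(a = a, b = b))$H
  h2 <- kruskal_wallis_pairwise(list(a = exp(a), b = exp(b)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("three-group pairwise testing applies a Bonferroni factor of 3", {
  set.seed(51)
  g <- list(remote = rnorm(500), border = rnorm(500, 2),
            infarct = rnorm(500, 4))
  res <- kruskal_wallis_pairwise(g)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adj, pmin(1, 3 * res$p))
  expect_true(all(res$p_adj < 0.01))
  expect_true(all(res$significant))
})

test_that("regional summaries use the linear-interpolation quantile convention", {
  df <- data.frame(subject = "S1", region = "remote", quantity = "MD",
                   value = c(1, 2, 3, 4))
  s <- summarize_regions(df)
  expect_equal(s$median, 2.5); expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25); expect_equal(s$mean, 2.5)
  # constant and singleton samples collapse to the value
  for (v in list(rep(7, 5), 7)) {
    s <- summarize_regions(data.frame(subject = "S1", region = "remote",
                                      quantity = "MD", value = v))
    expect_true(all(c(s$mean, s$median, s$q1, s$q3) == 7))
  }
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
})

test_that("percent change of medians keeps magnitude and sign", {
  expect_equal(percent_change_of_medians(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(percent_change_of_medians(1.62, 1.22),
               100 * (1.62 - 1.22) / 1.22)
  expect_equal(percent_change_of_medians(1.62, 1.22), 32.79, tolerance = 1e-3)
  expect_equal(percent_change_of_medians(0.23, 0.29), -20.69,
               tolerance = 1e-3)
  expect_error(percent_change_of_medians(1, c(-1, 1)), "zero reference")
})
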