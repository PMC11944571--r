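test_that("PCA recovers exact low-rank structure and centres scores", {
  set.seed(2)
  t1 <- rnorm(20)
  X <- outer(t1, runif(10)) + 5        # rank 1 in 10-D
  pc <- fit_pca(X, var_explained = 0.99)
  expect_equal(pc$k, 1L)
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  Y <- matrix(rnorm(60), 12, 5)
  pc2 <- fit_pca(Y, k = 5)
  expect_equal(sum(pc2$explained), 1, tolerance = 1e-12)  # k = rank
  expect_lt(max(abs(colMeans(pc2$scores))), 1e-10)
  expect_lt(max(abs(crossprod(pc2$loadings) - diag(5))), 1e-8)
  # projecting the training data reproduces the scores
  expect_equal(predict(pc2, Y), pc2$scores, tolerance = 1e-10)
  expect_error(fit_pca(Y, k = 6), "rank")
})

test_that("Gaussian KDE matches its definition exactly", {
  grid <- seq(-8, 8, length.out = 512)
  # single sample at 0, h = 1: the standard normal density
  expect_lt(max(abs(kde_gaussian(0, grid, 1) - dnorm(grid))), 1e-12)
  # two samples: direct sum of scaled kernels
  s <- c(-1, 1); h <- 0.5
  manual <- (dnorm((grid + 1) / h) + dnorm((grid - 1) / h)) / (2 * h)
  expect_lt(max(abs(kde_gaussian(s, grid, h) - manual)), 1e-12)
  # mass on a generous grid integrates to 1
  set.seed(6)
  x <- rnorm(40, 2, 3)
  g2 <- seq(min(x) - 5, max(x) + 5, length.out = 2048)
  dens <- kde_gaussian(x, g2, 1)
  expect_equal(sum(diff(g2) * (dens[-1] + dens[-2048]) / 2), 1,
               tolerance = 1e-4)
  expect_error(kde_gaussian(x, g2, 0), "h must be > 0")
  expect_error(kde_gaussian(numeric(0), g2, 1), "at least one")
})

test_that("squared density distance matches the Gaussian overlap integral", {
  grid <- seq(-6, 7, length.out = 2048)
  d2 <- density_distance_sq(kde_gaussian(1, grid, 1),
                            kde_gaussian(0, grid, 1), grid)
  # int (N(x;1,1) - N(x;0,1))^2 dx = (1/sqrt(pi)) (1 - exp(-1/4))
  expect_equal(d2, (1 / sqrt(pi)) * (1 - exp(-0.25)), tolerance = 1e-6)
  # identical densities give exactly zero
  p <- kde_gaussian(c(0, 2), grid, 1)
  expect_identical(density_distance_sq(p, p, grid), 0)
  # doubling the resolution barely moves the value
  g4 <- seq(-6, 7, length.out = 4096)
  d2b <- density_distance_sq(kde_gaussian(1, g4, 1),
                             kde_gaussian(0, g4, 1), g4)
  expect_lt(abs(d2 - d2b), 1e-6)
  expect_error(density_distance_sq(p[-1], p, grid), "grid mismatch")
})

test_that("MSD statistic averages per-component distances", {
  set.seed(10)
  pop <- matrix(rnorm(200), 50, 4)
  res <- msd_stat(pop, pop)
  expect_equal(res$msd, 0)
  expect_equal(res$msd, mean(res$d2), tolerance = 1e-12)
  expect_true(all(res$d2 >= 0))

  sub <- pop[1:10, , drop = FALSE]
  r1 <- msd_stat(sub[, 1, drop = FALSE], pop[, 1, drop = FALSE])
  expect_equal(r1$msd, r1$d2[1])      # k = 1: mean of one
  # column permutation leaves the mean unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(msd_stat(sub[, perm], pop[, perm])$msd,
               msd_stat(sub, pop)$msd, tolerance = 1e-12)
  expect_error(msd_stat(sub[, 1:2], pop), "same number")
  expect_error(msd_stat(matrix(0, 3, 0), matrix(0, 5, 0)), "k = 0")
})

test_that("the subset-size sweep nominates deterministically and the full
           calibration set is the floor", {
  cfg <- tiny_cfg()
  ds <- simulate_leaf_dataset(cfg, seed = 12)
  pre <- preprocess_spectra(ds$spectra)
  cal <- pre[1:9]; val <- pre[10:12]
  sw <- msd_sweep(cal, val, sizes = c(4, 6, 8, 9), k = 2)
  expect_equal(nrow(sw$table), 4L)
  expect_true(sw$nominated %in% c(4, 6, 8, 9))
  expect_equal(sum(sw$table$nominated), 1L)
  # deterministic: same inputs, same sweep
  sw2 <- msd_sweep(cal, val, sizes = c(4, 6, 8, 9), k = 2)
  expect_identical(sw$table, sw2$table)
  # subset = full calibration reaches the sweep floor
  expect_equal(which.min(sw$table$msd), 4L)
  expect_error(msd_sweep(cal, val, sizes = c(4, 20), k = 2), "exceed")
})
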