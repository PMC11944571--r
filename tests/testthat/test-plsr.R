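test_that("a noiseless univariate relation is recovered with one component", {
  set.seed(1)
  x <- rnorm(20)
  m <- fit_plsr(matrix(x), 2 * x, max_lv = 1)
  expect_equal(m$n_lv, 1L)
  expect_equal(unname(coef(m)[-1]), 2, tolerance = 1e-10)
  expect_lt(sqrt(mean(residuals(m) ^ 2)), 1e-8)
  expect_equal(predict(m, matrix(x)), 2 * x, tolerance = 1e-8)
})

test_that("prediction is affine in the spectra", {
  set.seed(2)
  X <- matrix(rnorm(200), 20)
  m <- fit_plsr(X, rnorm(20) + X[, 1], n_lv = 3)
  X1 <- matrix(rnorm(50), 5); X2 <- matrix(rnorm(50), 5)
  a <- 0.35
  expect_equal(predict(m, a * X1 + (1 - a) * X2),
               a * predict(m, X1) + (1 - a) * predict(m, X2),
               tolerance = 1e-10)
})

test_that("with as many components as predictors PLSR reproduces OLS", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30)
  y <- rnorm(30)
  m <- fit_plsr(X, y, n_lv = 4)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(drop(cbind(1, X) %*% ols$coefficients),
               predict(m, X), tolerance = 1e-6)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  X <- matrix(rnorm(40 * 12), 40)
  colnames(X) <- paste0("V", 1:12)
  y <- rnorm(40) + X[, 2] - X[, 7]
  m <- fit_plsr(X, y, n_lv = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  expect_equal(unname(predict(m, X)),
               unname(predict(ref, X)$predict[, 1, 3]), tolerance = 1e-10)
})

test_that("cross-validation picks the RMSE minimiser and scores stay
           orthogonal", {
  set.seed(5)
  n <- 40; p <- 15
  T3 <- matrix(rnorm(n * 3), n)
  X <- T3 %*% matrix(rnorm(3 * p), 3) + 0.05 * matrix(rnorm(n * p), n)
  y <- T3 %*% c(1, -2, 0.5) + 0.05 * rnorm(n)
  m <- fit_plsr(X, drop(y), max_lv = 8)
  expect_true(all(m$cv_rmse[m$n_lv] <= m$cv_rmse + 1e-12))
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("degenerate calibration problems are refused or clipped", {
  set.seed(6)
  X <- matrix(rnorm(30), 10)
  expect_error(fit_plsr(X, rep(1, 10)), "constant response")
  expect_error(fit_plsr(matrix(1, 10, 3), rnorm(10)), "constant")
  expect_warning(fit_plsr(X, rnorm(10) + X[, 1], n_lv = 40), "clipped")
})

test_that("VIP scores satisfy their normalisation identity", {
  # p = 1 forces VIP = 1 exactly
  set.seed(7)
  x <- rnorm(15)
  expect_equal(vip(fit_plsr(matrix(x), 3 * x + rnorm(15, 0, 0.1),
                            max_lv = 1)), 1, tolerance = 1e-10)
  for (seed in c(8, 9)) {
    set.seed(seed)
    X <- matrix(rnorm(35 * 20), 35)
    m <- fit_plsr(X, rnorm(35) + X[, 3] + 0.5 * X[, 11], max_lv = 6)
    v <- vip(m)
    expect_true(all(v >= 0))
    expect_equal(mean(v ^ 2), 1, tolerance = 1e-8)
  }
})

test_that("important_bands finds, merges and bounds threshold runs", {
  wl <- seq(480, 700, by = 10)
  expect_equal(nrow(important_bands(rep(0.5, length(wl)), wl)), 0L)

  v <- ifelse(wl >= 500 & wl <= 640, 1.5, 0.2)
  b <- important_bands(v, wl)
  expect_equal(b, data.frame(lo = 500, hi = 640))

  # two runs separated by a 20 nm gap merge when allowed
  v2 <- ifelse((wl >= 500 & wl <= 530) | (wl >= 550 & wl <= 580), 1.5, 0.2)
  expect_equal(nrow(important_bands(v2, wl)), 2L)
  expect_equal(important_bands(v2, wl, merge_gap = 20),
               data.frame(lo = 500, hi = 580))
  expect_error(important_bands(v2, wl[-1]), "equal length")
})

test_that("prediction guards the wavelength grid", {
  set.seed(10)
  s <- rand_spectra(12, 20, seed = 10)
  a <- absorbance(s)
  m <- fit_plsr(a$values, rnorm(12) + a$values[, 5], n_lv = 2,
                wavelengths = a$wavelengths)
  expect_length(predict(m, a), 12)
  expect_error(predict(m, a$values[, -1]), "columns")
  shifted <- spectra(a$values, a$wavelengths + 5, "absorbance", a$sample_ids)
  expect_error(predict(m, shifted), "grid")
})
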