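test_that("a tree too small to split is a single leaf equal to OLS", {
  set.seed(1)
  X <- matrix(rnorm(45), 15, 3)
  y <- drop(X %*% c(1, -1, 2)) + rnorm(15, 0, 0.1)
  tr <- fit_model_tree(X, y)           # n = 15 < 2 * min_leaf
  expect_identical(tr$root$type, "leaf")
  ols <- stats::lm.fit(cbind(1, X), y)
  Xn <- matrix(rnorm(30), 10, 3)
  expect_equal(predict(tr, Xn),
               drop(cbind(1, Xn) %*% ols$coefficients), tolerance = 1e-8)
  # the c = 1, k = 0 model is the same single tree
  cb <- cubist_lite(X, y, committees = 1, neighbors = 0)
  expect_equal(predict(cb, Xn), predict(tr, Xn), tolerance = 1e-12)
})

test_that("a piecewise-linear kink is located and fitted accurately", {
  set.seed(5)
  x <- runif(200, -2, 2)
  y <- ifelse(x < 0, x, -x) + 1        # slope 1 below 0, -1 above
  tr <- fit_model_tree(matrix(x), y)
  expect_identical(tr$root$type, "split")
  expect_lt(abs(tr$root$threshold), 0.1)
  xt <- runif(200, -2, 2)
  pred <- predict(tr, matrix(xt))
  expect_lt(sqrt(mean((pred - (ifelse(xt < 0, xt, -xt) + 1)) ^ 2)), 0.05)
})

test_that("pure noise produces a depth-zero tree", {
  set.seed(11)
  x <- rnorm(100)
  y <- rnorm(100)
  expect_identical(fit_model_tree(matrix(x), y)$root$type, "leaf")
  # all-identical rows cannot split either
  expect_identical(fit_model_tree(matrix(1, 30, 2), rnorm(30))$root$type,
                   "leaf")
})

test_that("committees reflect residuals and average their members", {
  set.seed(6)
  x <- runif(120, -2, 2)
  y <- ifelse(x < 0, x, -x) + rnorm(120, 0, 0.2)
  X <- matrix(x)
  c1 <- cubist_lite(X, y, committees = 1)
  c4 <- cubist_lite(X, y, committees = 4)
  expect_length(c4$trees, 4L)
  rmse_tr <- function(m) sqrt(mean((predict(m, X) - y) ^ 2))
  expect_lte(rmse_tr(c4), rmse_tr(c1) + 1e-12)
  # ensemble prediction is the arithmetic mean over members
  member <- vapply(c4$trees, predict, numeric(nrow(X)), newdata = X)
  expect_equal(predict(c4, X), rowMeans(member), tolerance = 1e-12)
})

test_that("nearest-neighbour correction collapses and disables correctly", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  cb <- cubist_lite(X, y, committees = 1, neighbors = 0)
  raw <- predict(cb, X, neighbors = 0)
  expect_equal(predict(cb, X), raw)    # k = 0: untouched
  # query equal to a training row with k = 1 and w_nn = 1 returns its y
  corrected <- nn_correct(raw[3], X[3, , drop = FALSE], X, y,
                          cb$train_pred, k = 1, w_nn = 1)
  expect_equal(corrected, y[3])
  expect_error(nn_correct(raw[1], X[1, , drop = FALSE],
                          X[0, , drop = FALSE], numeric(0), numeric(0), 1),
               "empty")
  expect_error(nn_correct(raw, X, X, y, cb$train_pred, k = 21), "archive")
})

test_that("neighbour correction helps when the model is locally biased", {
  set.seed(8)
  x <- runif(200, -2, 2)
  y <- x ^ 2 + rnorm(200, 0, 0.05)     # smooth curvature, linear model
  cb <- cubist_lite(matrix(x), y, committees = 1, min_split_frac = 10)
  xt <- runif(150, -1.8, 1.8)
  yt <- xt ^ 2 + rnorm(150, 0, 0.05)
  r0 <- sqrt(mean((predict(cb, matrix(xt), neighbors = 0) - yt) ^ 2))
  r10 <- sqrt(mean((predict(cb, matrix(xt), neighbors = 10) - yt) ^ 2))
  expect_lt(r10, r0)
})

test_that("the hyperparameter grid is evaluated fairly and reproducibly", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 5), n)
  y <- drop(X %*% c(2, -1, 0, 0.5, 0)) + 0.3 * X[, 1] ^ 2 + rnorm(n, 0, 0.2)
  g1 <- cubist_grid(X, y, folds = 10, seed = 17)
  expect_equal(nrow(g1$cv_table), 16L)
  expect_setequal(unique(g1$cv_table$committees), c(2, 4, 6, 8))
  expect_setequal(unique(g1$cv_table$neighbors), c(10, 20, 30, 40))
  best <- g1$cv_table$rmse[g1$cv_table$committees == g1$committees &
                             g1$cv_table$neighbors == g1$neighbors]
  expect_true(all(best <= g1$cv_table$rmse))
  # one shared fold partition, reproducible from the seed
  g2 <- cubist_grid(X, y, folds = 10, seed = 17)
  expect_identical(g1$folds_assign, g2$folds_assign)
  expect_identical(g1$cv_table, g2$cv_table)
  expect_equal(predict(g1, X), predict(g2, X), tolerance = 1e-15)
  expect_error(cubist_grid(X[1:10, ], y[1:10]), "at least 20")
})
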