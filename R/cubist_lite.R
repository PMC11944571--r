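#' Cubist-style rule-based regression ("Cubist-lite")
#'
#' A native re-implementation of the published Cubist mechanism (not a
#' bit-compatible clone of the proprietary code): an M5-type model tree with
#' least-squares linear models in the leaves and error-weighted smoothing
#' up the path,
#' committee ensembles trained on residual-reflected pseudo-targets, and an
#' instance-based (nearest-neighbour) correction applied at prediction
#' time.
#'
#' With high-dimensional spectra the leaf regressions are kept well-posed
#' by predictor screening: each node's linear model uses the features on
#' its path plus the globally strongest split candidates (by root-level
#' variance reduction), capped by the node sample count.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y numeric response vector.
#' @param committees number of committee members (default 1).
#' @param neighbors default neighbour count used at prediction (default 0 =
#'   no instance correction).
#' @param min_leaf minimum samples per leaf (default 10).
#' @param max_depth maximum tree depth (default 6).
#' @param min_split_frac a split must remove at least this fraction of the
#'   node's sum of squares (default 0.1); stops noise-chasing splits.
#' @param screen number of globally screened predictors available to node
#'   models (default 50).
#' @param w_nn weight of the neighbour-corrected prediction in the final
#'   average (default 0.5).
#' @return an object of class `cubist_lite`: list with `trees`, `X_train`,
#'   `y_train`, `train_pred` (ensemble predictions on the archive),
#'   `committees`, `neighbors`, `w_nn`, settings, and (after
#'   [cubist_grid()]) a `cv_table`.
#' @seealso [cubist_grid()] for the hyperparameter search.
#' @export
cubist_lite <- function(X, y, committees = 1, neighbors = 0,
                        min_leaf = 10, max_depth = 6, min_split_frac = 0.1,
                        screen = 50, w_nn = 0.5) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  committees <- as.integer(committees)
  if (committees < 1) stop("committees must be >= 1")
  if (neighbors < 0) stop("neighbors must be >= 0")

  trees <- fit_committees(X, y, committees, min_leaf = min_leaf,
                          max_depth = max_depth,
                          min_split_frac = min_split_frac, screen = screen)
  fit <- structure(list(trees = trees, X_train = X, y_train = y,
                        committees = committees,
                        neighbors = as.integer(neighbors), w_nn = w_nn,
                        min_leaf = min_leaf, max_depth = max_depth,
                        min_split_frac = min_split_frac,
                        screen = screen),
                   class = "cubist_lite")
  fit$train_pred <- predict_ensemble(trees, X)
  fit
}

#' @export
print.cubist_lite <- function(x, ...) {
  nl <- vapply(x$trees, count_leaves, integer(1))
  cat(sprintf(
    "<cubist_lite> %d committee(s), %d neighbor(s), leaves per tree: %s\n",
    x$committees, x$neighbors, paste(nl, collapse = " ")))
  if (!is.null(x$cv_table)) {
    best <- x$cv_table[which.min(x$cv_table$rmse), ]
    cat(sprintf("  grid-search winner: committees = %d, neighbors = %d (CV RMSE %.4g)\n",
                best$committees, best$neighbors, best$rmse))
  }
  invisible(x)
}

#' @export
summary.cubist_lite <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_table)) {
    cat("CV RMSE over the hyperparameter grid:\n")
    print(object$cv_table, row.names = FALSE)
  }
  invisible(object)
}

count_leaves <- function(tree) {
  n_leaves <- function(node) {
    if (node$type == "leaf") return(1L)
    n_leaves(node$left) + n_leaves(node$right)
  }
  n_leaves(if (inherits(tree, "cubist_tree")) tree$root else tree)
}

## ---- model tree -----------------------------------------------------------

#' Fit a single model tree
#'
#' Greedy variance-reduction splits; every node (internal and leaf) carries
#' a least-squares linear model on screened predictors, used for leaf
#' prediction and path smoothing. Degenerate inputs (too few rows, no
#' admissible split, all rows identical) yield a single-leaf tree whose
#' prediction is the node OLS fit.
#'
#' @inheritParams cubist_lite
#' @return a recursive tree structure (class `cubist_tree`).
#' @export
fit_model_tree <- function(X, y, min_leaf = 10, max_depth = 6,
                           min_split_frac = 0.1, screen = 50) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  screened <- screen_features(X, y, min_leaf, screen)
  tree <- grow_node(X, y, seq_len(nrow(X)), depth = 0L,
                    path = integer(0), screened = screened,
                    min_leaf = min_leaf, max_depth = max_depth,
                    min_split_frac = min_split_frac)
  structure(list(root = tree, p = ncol(X)), class = "cubist_tree")
}

# rank features by sequential variance reduction of the root linear model:
# each pick is the wavelength most correlated with the residual of the OLS
# fit on the wavelengths already picked (greedy forward selection). With
# collinear spectra this spreads the screened set across bands instead of
# stacking near-duplicates of the single best one.
screen_features <- function(X, y, min_leaf, screen) {
  n <- nrow(X); p <- ncol(X)
  k <- min(screen, p, max(1L, n - 2L))
  sds <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, pmax(sds, 1e-300), "/")
  keep <- integer(0)
  r <- y - mean(y)
  for (i in seq_len(k)) {
    if (sqrt(mean(r ^ 2)) < 1e-10 * (stats::sd(y) + 1e-300)) break
    cors <- abs(drop(crossprod(Xs, r)))
    cors[keep] <- -Inf
    cors[sds == 0] <- -Inf
    j <- which.max(cors)
    if (!is.finite(cors[j])) break
    keep <- c(keep, j)
    fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), y)
    r <- fit$residuals
  }
  if (!length(keep)) keep <- 1L
  keep
}

# For each feature: the best split of the node rows, scored by the drop in
# summed squared error when each side gets its own simple linear regression
# on the split feature (computable from running sums of x, y, x^2, y^2,
# xy). Unlike a mean-based criterion this finds kinks of piecewise-linear
# relations -- a symmetric kink leaves group means equal but is located
# exactly by the per-side regressions. Returns a 2 x p matrix (red, thr);
# red is relative to the node mean-model sum of squares.
best_split_per_feature <- function(X, y, rows, min_leaf) {
  yr <- y[rows]
  n <- length(rows)
  side_sse <- function(sx, sy, sxx, syy, sxy, m) {
    vy <- syy - sy ^ 2 / m
    vx <- sxx - sx ^ 2 / m
    cxy <- sxy - sx * sy / m
    sse <- vy - ifelse(vx > 1e-300, cxy ^ 2 / vx, 0)
    pmax(sse, 0)
  }
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[rows, j]
    o <- order(x)
    xs <- x[o]; ys <- yr[o]
    cx <- cumsum(xs); cy <- cumsum(ys)
    cxx <- cumsum(xs ^ 2); cyy <- cumsum(ys ^ 2); cxy <- cumsum(xs * ys)
    i <- seq_len(n - 1)
    ssl <- side_sse(cx[i], cy[i], cxx[i], cyy[i], cxy[i], i)
    ssr <- side_sse(cx[n] - cx[i], cy[n] - cy[i], cxx[n] - cxx[i],
                    cyy[n] - cyy[i], cxy[n] - cxy[i], n - i)
    red <- (cyy[n] - cy[n] ^ 2 / n) - ssl - ssr
    red[i < min_leaf | i > n - min_leaf | xs[i] >= xs[i + 1]] <- -Inf
    b <- which.max(red)
    if (!is.finite(red[b])) c(-Inf, NA) else c(red[b], (xs[b] + xs[b + 1]) / 2)
  }, numeric(2)) -> out
  rownames(out) <- c("red", "thr")
  out
}

grow_node <- function(X, y, rows, depth, path, screened, min_leaf,
                      max_depth, min_split_frac) {
  n <- length(rows)
  model <- node_lm(X, y, rows, union(path, screened))
  ss <- sum((y[rows] - mean(y[rows])) ^ 2)
  make_leaf <- function()
    list(type = "leaf", n = n, model = model, s2_eff = model$s2)

  if (n < 2 * min_leaf || depth >= max_depth || ss <= 0) return(make_leaf())
  # split candidates are the screened features: with thousands of collinear
  # bands the informative splits live where the models do, and the search
  # stays linear in the screen size
  bs <- best_split_per_feature(X[, screened, drop = FALSE], y, rows,
                               min_leaf)
  js <- which.max(bs["red", ])
  red <- bs["red", js]
  if (!is.finite(red) || red < min_split_frac * ss) return(make_leaf())
  j <- screened[js]
  thr <- bs["thr", js]
  left <- rows[X[rows, j] <= thr]
  right <- rows[X[rows, j] > thr]
  node <- list(type = "split", n = n, model = model, feature = j,
               threshold = thr,
               left = grow_node(X, y, left, depth + 1L, c(path, j),
                                screened, min_leaf, max_depth,
                                min_split_frac),
               right = grow_node(X, y, right, depth + 1L, c(path, j),
                                 screened, min_leaf, max_depth,
                                 min_split_frac))
  # error-based smoothing weights: each branch prediction is blended with
  # this node model by inverse estimated error variance (df-adjusted), so
  # accurate subtrees keep their predictions and noisy ones defer upward
  eps <- 1e-12 * (stats::var(y) + 1e-300)
  node$w_left <- (model$s2 + eps) /
    (model$s2 + node$left$s2_eff + 2 * eps)
  node$w_right <- (model$s2 + eps) /
    (model$s2 + node$right$s2_eff + 2 * eps)
  v_left <- 1 / (1 / (node$left$s2_eff + eps) + 1 / (model$s2 + eps))
  v_right <- 1 / (1 / (node$right$s2_eff + eps) + 1 / (model$s2 + eps))
  node$s2_eff <- (length(left) * v_left + length(right) * v_right) / n
  node
}

# least-squares model on allowed features, capped so the system stays
# overdetermined; rank-deficient coefficients are dropped (treated as 0)
node_lm <- function(X, y, rows, feats) {
  n <- length(rows)
  cap <- max(1L, min(length(feats), floor(n / 3)))
  feats <- feats[seq_len(cap)]
  Z <- cbind(1, X[rows, feats, drop = FALSE])
  fit <- stats::lm.fit(Z, y[rows])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # estimated generalisation variance: training MSE inflated by the M5
  # penalty (n + nu)/(n - nu), nu = fitted parameters; small leaves with
  # many coefficients are distrusted accordingly
  nu <- fit$rank
  pen <- if (n - nu >= 1) (n + nu) / (n - nu) else Inf
  list(intercept = beta[1], coef = beta[-1], feats = feats,
       s2 = sum(fit$residuals ^ 2) / n * pen ^ 2)
}

node_lm_predict <- function(model, X, rows) {
  drop(model$intercept +
         X[rows, model$feats, drop = FALSE] %*% model$coef)
}

#' Predict from a single model tree
#'
#' @param object a `cubist_tree` from [fit_model_tree()].
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of smoothed tree predictions.
#' @export
predict.cubist_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; tree expects ", object$p)
  predict_node(object$root, newdata, seq_len(nrow(newdata)))
}

predict_node <- function(node, X, rows) {
  own <- node_lm_predict(node$model, X, rows)
  if (node$type == "leaf" || length(rows) == 0) return(own)
  go_left <- X[rows, node$feature] <= node$threshold
  child <- numeric(length(rows))
  wgt <- numeric(length(rows))
  child[go_left] <- predict_node(node$left, X, rows[go_left])
  child[!go_left] <- predict_node(node$right, X, rows[!go_left])
  wgt[go_left] <- node$w_left
  wgt[!go_left] <- node$w_right
  wgt * child + (1 - wgt) * own
}

## ---- committees -----------------------------------------------------------

#' Fit a committee ensemble of model trees
#'
#' Member `m + 1` is trained on residual-reflected pseudo-targets
#' `y_adj = y - (ensemble_m(X) - y)`: where the running ensemble
#' overshoots, the next member is pulled below the observation, and vice
#' versa. The ensemble prediction is the arithmetic mean over members.
#'
#' @inheritParams cubist_lite
#' @return list of `cubist_tree` objects.
#' @export
fit_committees <- function(X, y, committees, min_leaf = 10, max_depth = 6,
                           min_split_frac = 0.1, screen = 50) {
  trees <- vector("list", committees)
  ens <- NULL
  target <- y
  for (m in seq_len(committees)) {
    trees[[m]] <- fit_model_tree(X, target, min_leaf = min_leaf,
                                 max_depth = max_depth,
                                 min_split_frac = min_split_frac,
                                 screen = screen)
    pm <- predict(trees[[m]], X)
    ens <- if (is.null(ens)) pm else ens + (pm - ens) / m
    target <- y - (ens - y)
  }
  trees
}

predict_ensemble <- function(trees, X, n_trees = length(trees)) {
  preds <- vapply(trees[seq_len(n_trees)], predict, numeric(nrow(X)),
                  newdata = X)
  if (n_trees == 1) drop(preds) else rowMeans(preds)
}

## ---- nearest-neighbour correction -----------------------------------------

#' Instance-based correction of model predictions
#'
#' For each query, the `k` nearest training samples (Euclidean distance in
#' predictor space, ties to the lowest index) adjust the raw model output:
#' `corrected = mean_i [ y_i + model(x) - model(x_i) ]`, and the final
#' prediction is `w_nn * corrected + (1 - w_nn) * model(x)`. `k = 0`
#' disables the correction.
#'
#' @param raw numeric vector of raw model predictions for the queries.
#' @param X_query query predictor matrix (rows match `raw`).
#' @param X_train,y_train,train_pred training archive: predictors, observed
#'   responses and raw model predictions.
#' @param k neighbour count, `0 <= k <= nrow(X_train)`.
#' @param w_nn weight of the corrected component (default 0.5).
#' @return numeric vector of corrected predictions.
#' @export
nn_correct <- function(raw, X_query, X_train, y_train, train_pred, k,
                       w_nn = 0.5) {
  if (nrow(X_train) == 0) stop("empty training archive")
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0")
  if (k > nrow(X_train)) stop("k exceeds the archive size")
  if (k == 0) return(raw)
  X_query <- as.matrix(X_query)
  d2 <- outer(rowSums(X_query ^ 2), rowSums(X_train ^ 2), "+") -
    2 * tcrossprod(X_query, X_train)
  corrected <- vapply(seq_len(nrow(X_query)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]        # stable: ties -> lowest index
    mean(y_train[nb] + raw[i] - train_pred[nb])
  }, numeric(1))
  w_nn * corrected + (1 - w_nn) * raw
}

#' Predict chlorophyll with a Cubist-lite model
#'
#' @param object a `cubist_lite` fit.
#' @param newdata numeric matrix or [spectra] with the training columns.
#' @param neighbors neighbour count for the instance-based correction;
#'   defaults to the value stored in the model.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cubist_lite <- function(object, newdata, neighbors = NULL, ...) {
  m <- spectra_matrix(newdata)
  if (is.null(neighbors)) neighbors <- object$neighbors
  raw <- predict_ensemble(object$trees, m)
  nn_correct(raw, m, object$X_train, object$y_train, object$train_pred,
             k = neighbors, w_nn = object$w_nn)
}

#' @export
residuals.cubist_lite <- function(object, ...) {
  object$y_train - predict(object, object$X_train)
}

## ---- grid search -----------------------------------------------------------

#' Hyperparameter grid search for Cubist-lite
#'
#' Evaluates every (committees, neighbors) cell of the grid -- by default
#' committees in \{2, 4, 6, 8\} crossed with neighbors in \{10, 20, 30,
#' 40\} -- under k-fold cross-validation with one fixed fold partition
#' shared by all cells, selects the cell with minimum mean CV RMSE (ties:
#' fewer committees, then fewer neighbours), and refits on all rows.
#'
#' Committee ensembles are nested (member `m` does not depend on later
#' members), so each fold fits `max(committees)` trees once and evaluates
#' every cell from prefixes.
#'
#' @inheritParams cubist_lite
#' @param committees,neighbors grid values.
#' @param folds number of CV folds (default 10); `n >= folds` required.
#' @param seed integer seed for the fold partition (recorded in the
#'   result).
#' @return a `cubist_lite` fitted at the winning cell, with `cv_table`
#'   (columns `committees`, `neighbors`, `rmse`), `folds_assign` and
#'   `fold_seed` attached.
#' @export
cubist_grid <- function(X, y, committees = c(2, 4, 6, 8),
                        neighbors = c(10, 20, 30, 40), folds = 10,
                        seed = 17, min_leaf = 10, max_depth = 6,
                        min_split_frac = 0.1, screen = 50, w_nn = 0.5) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 20) stop("grid search needs at least 20 samples")
  if (n < folds) stop("fewer samples than folds")
  committees <- sort(as.integer(committees))
  neighbors <- sort(as.integer(neighbors))
  cmax <- max(committees)

  assign <- local_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- expand.grid(neighbors = neighbors, committees = committees)[, 2:1]
  fold_rmse <- matrix(0, folds, nrow(grid))

  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[te, , drop = FALSE]
    trees <- fit_committees(Xtr, ytr, cmax, min_leaf = min_leaf,
                            max_depth = max_depth,
                            min_split_frac = min_split_frac,
                            screen = screen)
    for (ci in seq_along(committees)) {
      cc <- committees[ci]
      raw_te <- predict_ensemble(trees, Xte, cc)
      raw_tr <- predict_ensemble(trees, Xtr, cc)
      for (ki in seq_along(neighbors)) {
        pred <- nn_correct(raw_te, Xte, Xtr, ytr, raw_tr,
                           k = min(neighbors[ki], length(tr)), w_nn = w_nn)
        cell <- (ci - 1) * length(neighbors) + ki
        fold_rmse[f, cell] <- sqrt(mean((pred - y[te]) ^ 2))
      }
    }
  }
  cv <- data.frame(committees = grid$committees, neighbors = grid$neighbors,
                   rmse = colMeans(fold_rmse))
  best <- which.min(cv$rmse)            # ties -> first row: fewer c, fewer k
  fit <- cubist_lite(X, y, committees = cv$committees[best],
                     neighbors = cv$neighbors[best], min_leaf = min_leaf,
                     max_depth = max_depth, min_split_frac = min_split_frac,
                     screen = screen, w_nn = w_nn)
  fit$cv_table <- cv
  fit$folds_assign <- assign
  fit$fold_seed <- seed
  fit
}

# run expr under a temporary RNG state; restores the caller's stream
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
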