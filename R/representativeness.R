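#' Principal component projection of spectra
#'
#' Mean-centred PCA (no variance scaling, the spectroscopy convention) of an
#' absorbance matrix or [spectra] object. The number of retained components
#' is either fixed (`k`) or the smallest number whose cumulative explained
#' variance reaches `var_explained`.
#'
#' @param x numeric matrix (samples x wavelengths) or a [spectra] object.
#' @param k fixed number of components to retain; must not exceed the rank.
#' @param var_explained cumulative variance fraction target in `(0, 1]`,
#'   used when `k` is `NULL` (default 0.99).
#' @return a `pc_projection`: list with `loadings` (p x k, orthonormal
#'   columns), `center`, `scores` (n x k), `explained` (variance fractions
#'   of the retained components), `explained_all`, and `k`.
#' @export
fit_pca <- function(x, k = NULL, var_explained = 0.99) {
  m <- spectra_matrix(x)
  if (nrow(m) < 2) stop("PCA needs at least 2 samples")
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev ^ 2
  frac <- ev / sum(ev)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-9)
  if (is.null(k)) {
    if (var_explained <= 0 || var_explained > 1)
      stop("var_explained must be in (0, 1]")
    k <- which(cumsum(frac) >= var_explained - 1e-12)[1]
    if (is.na(k)) k <- rank
    k <- min(k, rank)
  } else {
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    if (k > rank) stop("k = ", k, " exceeds the data rank (", rank, ")")
  }
  structure(list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 center = pr$center,
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 explained = frac[seq_len(k)],
                 explained_all = frac,
                 k = k),
            class = "pc_projection")
}

#' @export
print.pc_projection <- function(x, ...) {
  cat(sprintf("<pc_projection> k = %d, explained = %s (cum %.1f%%)\n",
              x$k, paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
              100 * sum(x$explained)))
  invisible(x)
}

#' Project new samples onto a fitted PC basis
#'
#' @param object a `pc_projection` from [fit_pca()].
#' @param newdata matrix or [spectra] with the same wavelength columns as
#'   the training data.
#' @param ... unused.
#' @return score matrix (n_new x k).
#' @export
predict.pc_projection <- function(object, newdata, ...) {
  m <- spectra_matrix(newdata)
  if (ncol(m) != length(object$center))
    stop("newdata has ", ncol(m), " columns; projection expects ",
         length(object$center))
  sweep(m, 2, object$center) %*% object$loadings
}

spectra_matrix <- function(x) {
  if (inherits(x, "spectra")) x$values
  else if (inherits(x, "leaf_dataset")) x$spectra$values
  else as.matrix(x)
}

#' Gaussian kernel density estimate on a fixed grid
#'
#' Direct-summation Gaussian KDE:
#' `f(x) = (1/(n h)) * sum_i phi((x - s_i) / h)` with `phi` the standard
#' normal density, evaluated exactly at the supplied grid points. No FFT
#' binning is used, so the estimate is exact to floating point -- a property
#' the density-distance statistic below relies on.
#'
#' @param samples numeric vector of observations (length >= 1).
#' @param grid numeric vector of evaluation points.
#' @param h bandwidth, `> 0`.
#' @return numeric vector of density values, one per grid point.
#' @export
kde_gaussian <- function(samples, grid, h) {
  if (length(samples) < 1) stop("need at least one sample")
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("bandwidth h must be > 0")
  z <- outer(grid, samples, "-") / h
  rowMeans(stats::dnorm(z)) / h
}

# composite trapezoid rule on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Squared Euclidean distance between two densities
#'
#' `d^2 = integral over [a, b] of (p_pop(x) - p_subset(x))^2 dx`, computed
#' by the composite trapezoid rule on the shared grid. This is the per-PC
#' building block of the MSD representativeness statistic.
#'
#' @param p_pop,p_subset density values on `grid` (same length as `grid`).
#' @param grid shared evaluation grid.
#' @return non-negative scalar `d^2`.
#' @export
density_distance_sq <- function(p_pop, p_subset, grid) {
  if (length(p_pop) != length(grid) || length(p_subset) != length(grid))
    stop("densities and grid must share the same length (grid mismatch)")
  trapz(grid, (p_pop - p_subset) ^ 2)
}

#' MSD: mean squared density distance between subset and population scores
#'
#' For each of the `k` score columns, a Gaussian KDE of the subset scores
#' and one of the population scores are built with a *shared* kernel and
#' bandwidth (Silverman's rule-of-thumb computed on the population scores),
#' on a shared grid spanning the union of both score ranges padded by
#' `pad * h`; the squared Euclidean distance between the two densities is
#' integrated by the trapezoid rule. The MSD is the mean of the `k`
#' per-component distances. A small MSD means the subset's score
#' distribution closely matches the population's, i.e. the subset is
#' representative.
#'
#' @param subset_scores,pop_scores numeric matrices with the same number of
#'   columns (PC scores; rows = samples).
#' @param grid_n number of grid points per component (default 512).
#' @param pad grid padding in bandwidth units (default 3).
#' @return an `msd_result`: list with `d2` (k-vector), `msd` (mean of
#'   `d2`), `k`, `n_subset`, `n_pop`, `bandwidths`.
#' @export
msd_stat <- function(subset_scores, pop_scores, grid_n = 512, pad = 3) {
  subset_scores <- as.matrix(subset_scores)
  pop_scores <- as.matrix(pop_scores)
  k <- ncol(subset_scores)
  if (k == 0) stop("k = 0: no score columns")
  if (ncol(pop_scores) != k)
    stop("subset and population must have the same number of score columns")
  d2 <- numeric(k); bw <- numeric(k)
  for (j in seq_len(k)) {
    s <- subset_scores[, j]; p <- pop_scores[, j]
    h <- stats::bw.nrd0(p)
    a <- min(s, p) - pad * h
    b <- max(s, p) + pad * h
    grid <- seq(a, b, length.out = grid_n)
    d2[j] <- density_distance_sq(kde_gaussian(p, grid, h),
                                 kde_gaussian(s, grid, h), grid)
    bw[j] <- h
  }
  structure(list(d2 = d2, msd = mean(d2), k = k,
                 n_subset = nrow(subset_scores), n_pop = nrow(pop_scores),
                 bandwidths = bw),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("<msd_result> k = %d PCs, n_subset = %d, msd = %.6g\n",
              x$k, x$n_subset, x$msd))
  invisible(x)
}

#' Sweep MSD across nested Kennard-Stone subset sizes
#'
#' Fits a PCA on the calibration spectra only (validation samples are
#' projected with the calibration loadings, so no information leaks), draws
#' nested Kennard-Stone subsets of the requested sizes in the PC space
#' retaining `var_ks` variance, and computes the MSD statistic between each
#' subset's first-`k` PC scores and the validation population's. The
#' nominated size is the smallest whose MSD is within `tol` (relative) of
#' the sweep minimum -- an explicit elbow rule.
#'
#' @param calibration,validation absorbance matrices or [spectra] objects
#'   on the same wavelength grid.
#' @param sizes increasing subset sizes (default `seq(60, 260, 40)`).
#' @param k number of PCs entering the MSD average (default 6).
#' @param var_ks variance fraction retained for the Kennard-Stone selection
#'   space (default 0.99).
#' @param grid_n,pad KDE grid settings, see [msd_stat()].
#' @param tol relative tolerance of the nomination rule (default 0.1).
#' @return an `msd_sweep`: list with `table` (data.frame: size, per-PC
#'   `d2_pc*`, `msd`, `nominated`), `subsets` (index lists into the
#'   calibration set), `nominated` (size), `pca`, and the settings used.
#' @export
msd_sweep <- function(calibration, validation,
                      sizes = seq(60, 260, by = 40), k = 6,
                      var_ks = 0.99, grid_n = 512, pad = 3, tol = 0.1) {
  cal <- spectra_matrix(calibration)
  val <- spectra_matrix(validation)
  sizes <- as.integer(sizes)
  if (any(sizes > nrow(cal)))
    stop("subset sizes exceed the calibration size")
  pca <- fit_pca(cal, var_explained = var_ks)
  if (pca$k < k) {
    # need at least k score columns for the MSD average
    pca <- fit_pca(cal, k = k)
  }
  ks_space <- min(pca$k, which(cumsum(pca$explained_all) >= var_ks - 1e-12)[1],
                  na.rm = TRUE)
  subsets <- nested_subsets(pca$scores[, seq_len(ks_space), drop = FALSE],
                            sizes)
  val_scores <- predict(pca, val)[, seq_len(k), drop = FALSE]
  res <- lapply(subsets, function(idx)
    msd_stat(pca$scores[idx, seq_len(k), drop = FALSE], val_scores,
             grid_n = grid_n, pad = pad))
  msd <- vapply(res, `[[`, numeric(1), "msd")
  d2 <- t(vapply(res, `[[`, numeric(k), "d2"))
  colnames(d2) <- paste0("d2_pc", seq_len(k))
  nominated <- sizes[which(msd <= min(msd) * (1 + tol))[1]]
  tab <- data.frame(size = sizes, d2, msd = msd,
                    nominated = sizes == nominated, row.names = NULL)
  structure(list(table = tab, subsets = subsets, nominated = nominated,
                 pca = pca, k = k, var_ks = var_ks, grid_n = grid_n,
                 pad = pad, tol = tol),
            class = "msd_sweep")
}

#' @export
print.msd_sweep <- function(x, ...) {
  cat(sprintf("<msd_sweep> %d sizes, k = %d PCs, nominated size = %d\n",
              nrow(x$table), x$k, x$nominated))
  print(x$table[, c("size", "msd", "nominated")], row.names = FALSE)
  invisible(x)
}

#' Plot an MSD sweep
#'
#' Left panel: MSD against subset size with the nominated size marked.
#' Right panel: subset (at the nominated size) vs population KDEs of the
#' first PC scores.
#'
#' @param x an `msd_sweep` object.
#' @param validation optional validation matrix/[spectra] to redraw the
#'   density panel; if missing only the MSD curve is drawn.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.msd_sweep <- function(x, validation = NULL, ...) {
  if (!is.null(validation)) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  graphics::plot(x$table$size, x$table$msd, type = "b", pch = 16,
                 xlab = "subset size", ylab = "MSD", ...)
  graphics::abline(v = x$nominated, lty = 2)
  if (!is.null(validation)) {
    idx <- x$subsets[[as.character(x$nominated)]]
    s1 <- x$pca$scores[idx, 1]
    v1 <- predict(x$pca, spectra_matrix(validation))[, 1]
    h <- stats::bw.nrd0(v1)
    grid <- seq(min(s1, v1) - 3 * h, max(s1, v1) + 3 * h, length.out = 512)
    dp <- kde_gaussian(v1, grid, h); ds <- kde_gaussian(s1, grid, h)
    graphics::plot(grid, dp, type = "l", xlab = "PC1 score",
                   ylab = "density", ylim = range(dp, ds))
    graphics::lines(grid, ds, lty = 2)
    graphics::legend("topright", legend = c("validation", "subset"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
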