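#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a univariate-response PLSR model by the NIPALS algorithm on
#' mean-centred predictors (no variance scaling -- the spectroscopy
#' convention, since all bands share units). The number of latent variables
#' is chosen by leave-one-out cross-validation minimising RMSE over
#' `1..max_lv`, after which the model is refit on all rows with the chosen
#' count. Pass `n_lv` to skip cross-validation and fit a fixed number of
#' components.
#'
#' @param X numeric predictor matrix (n x p), e.g. smoothed absorbance.
#' @param y numeric response vector (chlorophyll, mg per g).
#' @param max_lv maximum number of latent variables to consider
#'   (default 20); clipped with a warning if it exceeds `min(n - 1, p)` or
#'   the effective rank.
#' @param cv `"loo"` (default) or `"none"` (requires `n_lv`).
#' @param n_lv fixed component count, bypassing cross-validation.
#' @param wavelengths optional wavelength grid stored for band reporting
#'   and checked at prediction time.
#' @return an object of class `plsr_fit`: list with `coefficients`
#'   (p-vector), `intercept`, `x_center`, `y_center`, `weights` (p x A),
#'   `x_loadings`, `y_loadings`, `scores`, `n_lv`, `cv_rmse` (RMSE per
#'   candidate LV count, if cross-validated), `vip`, `fitted`, `residuals`,
#'   `wavelengths`.
#' @seealso [vip()], [important_bands()], [predict.plsr_fit()]
#' @export
fit_plsr <- function(X, y, max_lv = 20, cv = c("loo", "none"),
                     n_lv = NULL, wavelengths = NULL) {
  cv <- match.arg(cv)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (stats::sd(y) == 0) stop("constant response: nothing to calibrate")
  if (all(apply(X, 2, stats::sd) == 0))
    stop("all predictor columns are constant")
  if (!is.null(wavelengths) && length(wavelengths) != p)
    stop("wavelengths length must equal ncol(X)")

  lv_cap <- min(n - 1L, p)
  if (!is.null(n_lv)) {
    cv <- "none"
    max_lv <- as.integer(n_lv)
  }
  if (max_lv > lv_cap) {
    warning("max_lv clipped from ", max_lv, " to ", lv_cap)
    max_lv <- lv_cap
  }
  if (max_lv < 1) stop("max_lv must be >= 1")

  cv_rmse <- NULL
  if (cv == "loo") {
    press <- matrix(NA_real_, n, max_lv)
    for (i in seq_len(n)) {
      f <- nipals_pls1(X[-i, , drop = FALSE], y[-i], max_lv)
      pred <- pls1_predict_all(f, X[i, , drop = FALSE])
      a <- length(pred)
      press[i, seq_len(a)] <- (pred - y[i]) ^ 2
      if (a < max_lv) press[i, (a + 1):max_lv] <- press[i, a]
    }
    cv_rmse <- sqrt(colMeans(press))
    n_lv <- which.min(cv_rmse)
  } else if (is.null(n_lv)) {
    stop("cv = 'none' requires n_lv")
  } else {
    n_lv <- max_lv
  }

  f <- nipals_pls1(X, y, n_lv)
  n_lv <- f$A                       # may be fewer if rank ran out
  B <- f$W %*% solve(crossprod(f$P, f$W), f$q)
  fitted <- drop(f$ym + sweep(X, 2, f$xm) %*% B)
  structure(list(coefficients = drop(B), intercept = f$ym - sum(f$xm * B),
                 x_center = f$xm, y_center = f$ym,
                 weights = f$W, x_loadings = f$P, y_loadings = f$q,
                 scores = f$T, n_lv = n_lv, cv_rmse = cv_rmse,
                 vip = vip_from_fit(f), fitted = fitted,
                 residuals = y - fitted, y = y,
                 wavelengths = wavelengths),
            class = "plsr_fit")
}

# NIPALS for a single response; for PLS1 each component is closed-form
# (no inner iteration). Stops early if the residual covariance vanishes.
nipals_pls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  eps <- max(abs(crossprod(Xc, yc))) * 1e-12 + 1e-300
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w ^ 2))
    if (nw ^ 2 <= eps) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t ^ 2)
    if (tt <= 1e-300) break
    pa <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- t
    a_done <- a
  }
  if (a_done == 0L) stop("no covariance between predictors and response")
  idx <- seq_len(a_done)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       q = q[idx], T = Tm[, idx, drop = FALSE], xm = xm, ym = ym,
       A = a_done)
}

# predictions of one new row for every component count 1..A
pls1_predict_all <- function(f, xnew) {
  A <- f$A
  R <- f$W %*% solve(crossprod(f$P, f$W))   # p x A; B_a = R[,1:a] %*% q[1:a]
  xc <- drop(xnew) - f$xm
  contrib <- drop(crossprod(R, xc)) * f$q   # per-component contribution
  f$ym + cumsum(contrib)
}

vip_from_fit <- function(f) {
  ss <- f$q ^ 2 * colSums(f$T ^ 2)          # y-variance explained per LV
  wn <- sweep(f$W, 2, sqrt(colSums(f$W ^ 2)), "/")
  p <- nrow(f$W)
  sqrt(p * drop(wn ^ 2 %*% ss) / sum(ss))
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d predictors, %d latent variables\n",
              length(x$coefficients), x$n_lv))
  if (!is.null(x$cv_rmse))
    cat(sprintf("  LOO-CV RMSE at chosen LV: %.4g\n", x$cv_rmse[x$n_lv]))
  cat(sprintf("  training RMSE: %.4g\n", sqrt(mean(x$residuals ^ 2))))
  invisible(x)
}

#' @export
summary.plsr_fit <- function(object, ...) {
  cat(sprintf("PLSR fit: n = %d, p = %d, latent variables = %d\n",
              length(object$y), length(object$coefficients), object$n_lv))
  if (!is.null(object$cv_rmse)) {
    cat("LOO-CV RMSE by LV count:\n")
    print(round(object$cv_rmse, 5))
  }
  cat(sprintf("training RMSE %.4g, R2 %.4f\n",
              sqrt(mean(object$residuals ^ 2)),
              1 - sum(object$residuals ^ 2) /
                sum((object$y - mean(object$y)) ^ 2)))
  if (!is.null(object$wavelengths)) {
    b <- important_bands(object$vip, object$wavelengths)
    if (nrow(b))
      cat("VIP > 1 bands (nm):",
          paste(sprintf("[%g, %g]", b$lo, b$hi), collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
coef.plsr_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
residuals.plsr_fit <- function(object, ...) object$residuals

#' @export
fitted.plsr_fit <- function(object, ...) object$fitted

#' Predict chlorophyll from new spectra with a PLSR fit
#'
#' @param object a `plsr_fit`.
#' @param newdata matrix or [spectra] with the training predictor columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  m <- spectra_matrix(newdata)
  if (ncol(m) != length(object$coefficients))
    stop("newdata has ", ncol(m), " columns; model expects ",
         length(object$coefficients))
  if (!is.null(object$wavelengths) && inherits(newdata, "spectra") &&
      max(abs(newdata$wavelengths - object$wavelengths)) > 1e-9)
    stop("wavelength grid of newdata does not match the training grid")
  drop(object$intercept + m %*% object$coefficients)
}

#' Plot a PLSR fit
#'
#' Two panels: LOO-CV RMSE against latent-variable count (if available) and
#' the VIP spectrum with the conventional threshold line at 1.
#'
#' @param x a `plsr_fit`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.plsr_fit <- function(x, ...) {
  two <- !is.null(x$cv_rmse)
  if (two) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::plot(seq_along(x$cv_rmse), x$cv_rmse, type = "b", pch = 16,
                   xlab = "latent variables", ylab = "LOO-CV RMSE")
    graphics::abline(v = x$n_lv, lty = 2)
  }
  wl <- if (!is.null(x$wavelengths)) x$wavelengths else
    seq_along(x$vip)
  graphics::plot(wl, x$vip, type = "l",
                 xlab = if (!is.null(x$wavelengths)) "wavelength (nm)"
                        else "predictor index",
                 ylab = "VIP")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` where
#' `SS_a` is the response variance captured by latent variable `a`. The
#' squared scores average to exactly 1 over the `p` predictors, so VIP > 1
#' flags bands that carry more than their share of the predictive signal.
#'
#' @param object a fitted model with VIP support.
#' @param ... method arguments.
#' @return numeric p-vector of VIP scores.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.plsr_fit <- function(object, ...) object$vip

#' Contiguous wavelength bands exceeding a VIP threshold
#'
#' Finds maximal runs of consecutive wavelengths whose score exceeds
#' `threshold`, and merges runs separated by a gap of at most `merge_gap`
#' nm.
#'
#' @param scores numeric vector (e.g. VIP), one value per wavelength.
#' @param wavelengths numeric wavelength vector, same length.
#' @param threshold band inclusion threshold (default 1, the VIP
#'   convention).
#' @param merge_gap merge runs whose gap is `<= merge_gap` nm (default 0).
#' @return `data.frame` with columns `lo`, `hi` (nm), one row per band;
#'   zero rows when nothing exceeds the threshold.
#' @export
important_bands <- function(scores, wavelengths, threshold = 1,
                            merge_gap = 0) {
  if (length(scores) != length(wavelengths))
    stop("scores and wavelengths must have equal length")
  above <- scores > threshold
  if (!any(above)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lo <- wavelengths[starts[r$values]]
  hi <- wavelengths[ends[r$values]]
  # merge runs with small gaps
  keep_lo <- lo[1]; out_lo <- c(); out_hi <- c()
  cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] - cur_hi <= merge_gap) {
      cur_hi <- hi[i]
    } else {
      out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, cur_hi)
      keep_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  data.frame(lo = c(out_lo, keep_lo), hi = c(out_hi, cur_hi))
}
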