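#' Convert reflectance spectra to absorbance
#'
#' Applies the Beer--Lambert style transform `A = log10(1/R)` elementwise.
#' Requires reflectance input with all values in `(0, 1]`, which guarantees
#' the logarithm is defined and the result non-negative.
#'
#' @param x a [spectra] object in reflectance mode.
#' @return a [spectra] object in absorbance mode on the same grid.
#' @examples
#' s <- spectra(matrix(c(1, 0.1, 0.01), 1), c(500, 600, 700), "reflectance")
#' absorbance(s)$values  # 0, 1, 2
#' @export
absorbance <- function(x) {
  stopifnot(inherits(x, "spectra"))
  if (x$mode != "reflectance")
    stop("absorbance() expects reflectance input, got mode = ", x$mode)
  if (any(x$values <= 0)) stop("reflectance <= 0: log10(1/R) undefined")
  spectra(-log10(x$values), x$wavelengths, "absorbance", x$sample_ids)
}

#' Savitzky-Golay smoothing of spectra
#'
#' Smooths each spectrum (row-wise, never across samples) with a local
#' least-squares polynomial filter. The defaults -- first-order polynomial,
#' window of 15 bands -- are the standard noise-suppression setting for
#' handheld vis/NIR instruments. Requires a uniformly spaced wavelength
#' grid; resample first if the grid is irregular.
#'
#' Edge policies: `"poly"` (default) fits the boundary window's polynomial
#' and evaluates it at the edge positions, so no bands are discarded;
#' `"shrink"` refits a symmetric window that shrinks towards each edge
#' (order reduced to fit when necessary).
#'
#' @param x a [spectra] object (any mode).
#' @param window odd integer window width in bands (default 15).
#' @param polyorder polynomial order, `0 <= polyorder < window` (default 1).
#' @param edge `"poly"` or `"shrink"`.
#' @return a [spectra] object, same grid and mode, smoothed values.
#' @export
sg_smooth <- function(x, window = 15, polyorder = 1,
                      edge = c("poly", "shrink")) {
  stopifnot(inherits(x, "spectra"))
  edge <- match.arg(edge)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window < 3 || window %% 2 == 0) stop("window must be an odd integer >= 3")
  if (polyorder < 0 || polyorder >= window) stop("need 0 <= polyorder < window")
  p <- length(x$wavelengths)
  if (p < window) stop("spectrum has fewer bands than the filter window")
  d <- diff(x$wavelengths)
  if (max(abs(d - mean(d))) / mean(d) > 1e-6)
    stop("wavelength grid is not uniform; resample before SG smoothing")

  sm <- t(apply(x$values, 1, signal::sgolayfilt, p = polyorder, n = window))
  if (edge == "shrink") {
    h <- (window - 1L) / 2L
    for (i in seq_len(h)) {
      # symmetric window of half-width i-1 around position i (and mirrored
      # at the right edge); polynomial order reduced to keep the fit proper
      sm[, i] <- shrink_fit(x$values, i, i - 1L, polyorder)
      sm[, p - i + 1L] <- shrink_fit(x$values, p - i + 1L, i - 1L, polyorder)
    }
  }
  # absorbance smoothing can produce tiny negative overshoot near zero;
  # clamp at 0 to preserve the mode invariant
  if (x$mode == "absorbance") sm[sm < 0] <- 0
  spectra(sm, x$wavelengths, x$mode, x$sample_ids)
}

# local poly fit on columns (center-half)..(center+half), evaluated at center
shrink_fit <- function(values, center, half, polyorder) {
  idx <- (center - half):(center + half)
  ord <- min(polyorder, length(idx) - 1L)
  if (ord == 0L) return(rowMeans(values[, idx, drop = FALSE]))
  z <- seq(-half, half)
  Zb <- outer(z, 0:ord, "^")
  # projection row for evaluation at z = 0: e1' (Z'Z)^{-1} Z'
  w <- solve(crossprod(Zb), t(Zb))[1, ]
  drop(values[, idx, drop = FALSE] %*% w)
}

#' Trim a spectra object to a wavelength interval
#'
#' Keeps bands with `lo <= wavelength < hi` (half-open, nm). Useful for
#' discarding the noisy extremes of a portable spectrometer's range.
#'
#' @param x a [spectra] object.
#' @param lo,hi interval bounds in nm.
#' @return the trimmed [spectra] object.
#' @export
trim_spectra <- function(x, lo, hi) {
  stopifnot(inherits(x, "spectra"), lo < hi)
  keep <- x$wavelengths >= lo & x$wavelengths < hi
  if (!any(keep)) stop("no wavelengths in [", lo, ", ", hi, ")")
  spectra(x$values[, keep, drop = FALSE], x$wavelengths[keep],
          x$mode, x$sample_ids)
}

#' Standard preprocessing: absorbance then Savitzky-Golay smoothing
#'
#' Convenience wrapper applying [absorbance()] followed by [sg_smooth()],
#' the order used throughout the calibration workflow.
#'
#' @inheritParams sg_smooth
#' @param trim optional length-2 numeric `c(lo, hi)` applied first.
#' @return an absorbance-mode [spectra] object.
#' @export
preprocess_spectra <- function(x, window = 15, polyorder = 1,
                               edge = c("poly", "shrink"), trim = NULL) {
  if (!is.null(trim)) x <- trim_spectra(x, trim[1], trim[2])
  sg_smooth(absorbance(x), window = window, polyorder = polyorder,
            edge = match.arg(edge))
}
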