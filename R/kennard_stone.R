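#' Kennard-Stone sample selection
#'
#' Deterministic max--min selection of well-spread samples. The first two
#' selections are the globally most distant pair (Euclidean distance); each
#' subsequent selection maximises its minimum distance to the points already
#' selected. Ties are broken towards the lowest row index (for the initial
#' pair, the lexicographically smallest index pair).
#'
#' @param x numeric matrix of points (rows = samples); a vector is treated
#'   as a one-column matrix.
#' @param m number of samples to select, `2 <= m <= nrow(x)`.
#' @return integer vector of `m` distinct row indices in selection order.
#' @examples
#' kennard_stone(c(0, 2, 3, 10), 3)  # 1, 4, 3
#' @export
kennard_stone <- function(x, m) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  m <- as.integer(m)
  if (anyNA(x)) stop("NA in input points")
  if (m < 2) stop("m must be >= 2")
  if (m > n) stop("m exceeds the number of points")

  sq <- rowSums(x ^ 2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0

  # initial pair: lexicographically smallest among the maximally distant
  mx <- max(d2)
  cand <- which(d2 == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- c(cand[1, 1], cand[1, 2])

  mind <- pmin(d2[, sel[1]], d2[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < m) {
    nxt <- which.max(mind)            # ties -> lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, d2[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Nested Kennard-Stone subsets
#'
#' Runs a single Kennard-Stone pass of length `max(sizes)` and returns, for
#' each requested size, the first `size` selections. By construction the
#' subsets are nested: `subset[s1]` is a prefix of `subset[s2]` for
#' `s1 < s2`, and each prefix equals an independent [kennard_stone()] run of
#' that length.
#'
#' @param x numeric matrix of points (rows = samples).
#' @param sizes strictly increasing integer vector of subset sizes.
#' @return named list mapping each size to its integer index vector.
#' @export
nested_subsets <- function(x, sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0) stop("sizes is empty")
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  full <- kennard_stone(x, max(sizes))
  out <- lapply(sizes, function(s) full[seq_len(s)])
  names(out) <- as.character(sizes)
  out
}
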