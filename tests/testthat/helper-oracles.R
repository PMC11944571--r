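# Independent oracles and small data builders shared across test files.

# Brute-force Kennard-Stone: recomputes the full distance matrix at every
# step, no incremental bookkeeping. Tie rules match the documented ones
# (lexicographically smallest initial pair, lowest index thereafter).
ks_brute <- function(X, m) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X)) ^ 2
  cand <- which(D == max(D), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- c(cand[1, 1], cand[1, 2])
  while (length(sel) < m) {
    rest <- setdiff(seq_len(n), sel)
    md <- vapply(rest, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(md)])
  }
  as.integer(sel)
}

# Per-window local least-squares oracle for the Savitzky-Golay filter with
# polynomial-fit edge extension: interior points use the centred window;
# edge points reuse the boundary window's polynomial evaluated off-centre.
sg_oracle <- function(x, window, polyorder) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- min(max(i, h + 1), n - h)
    w <- (c0 - h):(c0 + h)
    z <- w - i
    fit <- if (polyorder == 0) stats::lm(x[w] ~ 1)
           else stats::lm(x[w] ~ stats::poly(z, polyorder, raw = TRUE))
    out[i] <- unname(fit$coefficients[1])
  }
  out
}

# random mid-range reflectance spectra on a uniform grid
rand_spectra <- function(n, p, seed, lo = 400, hi = 1400) {
  set.seed(seed)
  spectra(matrix(stats::runif(n * p, 0.2, 0.8), n),
          seq(lo, hi, length.out = p), "reflectance")
}

# 12-sample, 200-band generator configuration used by fast pipeline tests
tiny_cfg <- function() {
  g <- generator_config()
  generator_config(species = g$species[1:3],
                   species_mean = g$species_mean[1:3],
                   months = c(5L, 8L), n_reps = 2,
                   wavelengths = seq(400, 2400, length.out = 200))
}

run_tiny_pipeline <- function(out_dir, seed = 3, ...) {
  run_pipeline(out_dir, seed = seed, cfg = tiny_cfg(), cal_size = 9,
               sizes = c(4, 6, 8), k = 2, max_lv = 5,
               committees = 2, neighbors = 2, folds = 0, ...)
}
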