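test_that("the study design yields 350 samples, 70 per species", {
  meta <- simulate_chlorophyll(seed = 1)
  expect_equal(nrow(meta), 350L)
  expect_equal(as.vector(table(meta$species)), rep(70L, 5))
  expect_false(anyDuplicated(meta$sample_id) > 0)
  expect_true(all(meta$month %in% 2:11))
  expect_true(all(meta$chlorophyll >= 0.79 & meta$chlorophyll <= 3.03))
})

test_that("noise-free flat-season draws equal the species means exactly", {
  cfg <- generator_config(sigma_c = 0, seasonal_amp = 0)
  meta <- simulate_chlorophyll(cfg, seed = 2)
  expect_equal(meta$chlorophyll,
               cfg$species_mean[match(meta$species, cfg$species)])
})

test_that("monthly chlorophyll means peak in August across seeds", {
  months <- 2:11
  acc <- numeric(length(months))
  for (seed in 1:20) {
    meta <- simulate_chlorophyll(seed = seed)
    acc <- acc + tapply(meta$chlorophyll, meta$month, mean)[as.character(months)]
  }
  expect_equal(months[which.max(acc)], 8)
})

test_that("spectra are deterministic given the seed and chlorophyll-driven
           at the visible band", {
  cfg <- generator_config(sigma_a = 0, water_sd = 0, water_mean = 0,
                          wavelengths = seq(400, 1100, by = 5))
  meta <- data.frame(sample_id = sprintf("S%02d", 1:6),
                     chlorophyll = seq(0.8, 3.0, length.out = 6),
                     species = "Spathiphyllum", month = 8L,
                     replicate = 1:6)
  sp <- simulate_spectra(meta, cfg, seed = 3)
  a600 <- -log10(sp$values[, which(sp$wavelengths == 600)])
  expect_true(all(diff(a600) > 0))     # increasing in chlorophyll
  # equal chlorophyll, same species: identical spectra
  meta2 <- meta; meta2$chlorophyll <- rep(1.5, 6)
  sp2 <- simulate_spectra(meta2, cfg, seed = 3)
  expect_equal(max(apply(sp2$values, 2, function(col) diff(range(col)))), 0)
  # same seed reproduces, different seed does not
  ds1 <- simulate_leaf_dataset(tiny_cfg(), seed = 4)
  ds2 <- simulate_leaf_dataset(tiny_cfg(), seed = 4)
  ds3 <- simulate_leaf_dataset(tiny_cfg(), seed = 5)
  expect_identical(ds1$spectra$values, ds2$spectra$values)
  expect_false(isTRUE(all.equal(ds1$spectra$values, ds3$spectra$values)))
  expect_error(simulate_chlorophyll(), "seed")
})

test_that("fixtures have the documented shapes and regenerate
           byte-identically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture("tiny", d1, seed = 1)
  s <- read_spectra(p1["spectra"])
  expect_equal(dim(s$values), c(12L, 200L))
  expect_equal(nrow(read_metadata(p1["meta"])), 12L)
  p2 <- make_fixture("tiny", d2, seed = 1)
  expect_identical(readLines(p1["spectra"]), readLines(p2["spectra"]))
  expect_identical(readLines(p1["meta"]), readLines(p2["meta"]))

  p3 <- make_fixture("study", d2, seed = 1)
  s3 <- read_spectra(p3["spectra"])
  expect_equal(dim(s3$values), c(350L, 2151L))
})

test_that("the Kennard-Stone calibration set reproduces the field-study
           chlorophyll statistics", {
  ds <- simulate_leaf_dataset(seed = 1)
  pre <- preprocess_spectra(ds$spectra)
  pca <- fit_pca(pre, var_explained = 0.99)
  cal <- kennard_stone(pca$scores, 280)
  chl <- ds$meta$chlorophyll[cal]
  expect_lt(abs(mean(chl) - 1.57) / 1.57, 0.15)
  expect_lt(abs(sd(chl) - 0.46) / 0.46, 0.15)
})

test_that("prediction quality degrades monotonically with spectral noise", {
  wl <- seq(350, 2500, by = 10)
  r2 <- vapply(c(0, 0.005, 0.02, 0.1), function(sig) {
    cfg <- generator_config(wavelengths = wl, sigma_a = sig)
    ds <- simulate_leaf_dataset(cfg, seed = 6)
    pre <- preprocess_spectra(ds$spectra)
    set.seed(60)
    tr <- sample(350, 250)
    m <- fit_plsr(pre$values[tr, ], ds$meta$chlorophyll[tr], n_lv = 8)
    evaluate(ds$meta$chlorophyll[-tr], predict(m, pre$values[-tr, ]))$r2
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})
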