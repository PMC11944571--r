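test_that("wide CSV parses with ids in file order and wavelengths sorted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,410,400,420",
               "B,0.5,0.4,0.6",
               "A,0.2,0.1,0.3",
               "C,0.8,0.7,0.9"), f)
  s <- read_spectra(f)
  expect_s3_class(s, "spectra")
  expect_equal(dim(s$values), c(3L, 3L))
  expect_equal(s$sample_ids, c("B", "A", "C"))
  expect_equal(s$wavelengths, c(400, 410, 420))
  # columns realigned to the sorted grid
  expect_equal(unname(s$values["A", ]), c(0.1, 0.2, 0.3))
})

test_that("malformed spectral tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,400,410", "S1,0.5,0.5", "S1,0.6,0.6"), f)
  expect_error(read_spectra(f), "S1")
  writeLines(c("sample_id,400,bad", "S1,0.5,0.5"), f)
  expect_error(read_spectra(f), "non-numeric")
  writeLines(c("sample_id,400,410", "S1,0.5,1.5"), f)
  expect_error(read_spectra(f), "reflectance")
  expect_error(read_spectra(tempfile()), "not found")
})

test_that("reflectance bound violations name the offending cell", {
  expect_error(
    spectra(matrix(c(0.5, -0.1), 1), c(400, 410), "reflectance",
            sample_ids = "Q7"),
    "Q7.*410",
  )
  expect_error(spectra(matrix(c(0.5, NA), 1), c(400, 410), "reflectance"),
               "non-finite")
  expect_error(spectra(matrix(0.5, 1, 2), c(410, 400), "reflectance"),
               "increasing")
  expect_error(spectra(matrix(0.5, 1, 2), c(300, 400), "reflectance"),
               "350")
})

test_that("write/read round-trips are bit-identical in both layouts", {
  s <- rand_spectra(4, 7, seed = 21)
  for (layout in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s, f, layout = layout)
    s2 <- read_spectra(f, layout = layout)
    expect_identical(unname(s2$values), unname(s$values))
    expect_identical(s2$wavelengths, s$wavelengths)
    expect_identical(s2$sample_ids, s$sample_ids)
  }
})

test_that("metadata joins are order-stable and count drops", {
  s <- rand_spectra(5, 4, seed = 8)
  meta <- data.frame(sample_id = rev(s$sample_ids),
                     chlorophyll = seq(1, 2, length.out = 5),
                     species = "A", month = 5L, replicate = 1:5)
  ds <- join_metadata(s, meta)
  expect_identical(ds$meta$sample_id, s$sample_ids)  # spectra order wins
  expect_identical(attr(ds, "dropped"), 0L)

  # lenient mode drops unmatched spectra with a warning
  expect_warning(ds2 <- join_metadata(s, meta[-1, ], strict = FALSE),
                 "dropped 1")
  expect_identical(attr(ds2, "dropped"), 1L)
  expect_equal(nrow(ds2$spectra$values), 4L)

  expect_error(join_metadata(s, meta[-1, ], strict = TRUE), "missing")
  meta$sample_id <- paste0("zz", meta$sample_id)
  expect_error(join_metadata(s, meta), "no sample ids shared")
})

test_that("metadata validation enforces the study-window invariants", {
  meta <- data.frame(sample_id = "S1", chlorophyll = 1.5, species = "A",
                     month = 12L, replicate = 1L)
  expect_error(read_metadata_check <- chlorospec:::validate_metadata(meta),
               "February-November")
  meta$month <- 5L
  meta$chlorophyll <- -1
  expect_error(chlorospec:::validate_metadata(meta), ">= 0")
  meta$chlorophyll <- NA_real_   # prediction-only samples are allowed
  expect_silent(chlorospec:::validate_metadata(meta))
})
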