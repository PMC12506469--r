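test_that("loading normalizes intensities and applies the calibration", {
  dir <- withr::local_tempdir()
  px <- matrix(seq(0, 255) / 255, 16, 16)
  png::writePNG(px, file.path(dir, "img.png"))
  calib <- scale_calibration(c(img.png = 20))
  img <- load_micrograph(file.path(dir, "img.png"), calib)
  expect_s3_class(img, "micrograph")
  expect_equal(range(img$pixels), c(0, 1))
  expect_equal(img$scale, 1 / 20)
  expect_equal(img$name, "img.png")
})

test_that("a constant image normalizes to zeros with a warning", {
  expect_warning(out <- normalize_intensity(matrix(0.5, 8, 8)),
                 "zero dynamic range")
  expect_true(all(out == 0))
})

test_that("16-bit TIFF round trip preserves the normalized array", {
  dir <- withr::local_tempdir()
  set.seed(42)
  px <- matrix(runif(64 * 64), 64, 64)
  px <- (px - min(px)) / (max(px) - min(px))
  path <- file.path(dir, "rt.tif")
  write_micrograph(px, path)
  img <- load_micrograph(path, scale_calibration(c(rt.tif = 10)))
  expect_lt(max(abs(img$pixels - px)), 2 / 65535)
})

test_that("grayscale conversion uses the 709 luma weights", {
  rgb <- array(0, dim = c(2, 2, 3))
  rgb[, , 1] <- 1
  expect_equal(to_grayscale(rgb), matrix(0.2125, 2, 2))
  white <- array(1, dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(white)), 1)
  gray <- matrix(runif(9), 3, 3)
  expect_identical(to_grayscale(gray), gray)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "channels")
})

test_that("the normalize-grayscale chain is idempotent", {
  set.seed(1)
  px <- matrix(runif(100), 10, 10)
  once <- normalize_intensity(to_grayscale(px))
  twice <- normalize_intensity(to_grayscale(once))
  expect_equal(twice, once)
})

test_that("calibration lookup is strict and exact", {
  calib <- scale_calibration(c(a.tif = 8, b.tif = 12.5))
  expect_equal(calibration_scale(calib, "a.tif"), 1 / 8)
  expect_identical(calibration_scale(calib, "b.tif"), 1 / 12.5)
  expect_error(calibration_scale(calib, "missing.tif"), "no calibration entry")
  expect_error(scale_calibration(c(a.tif = 0)), "strictly positive")
  expect_error(scale_calibration(c(a.tif = -3)), "strictly positive")
})

test_that("calibration JSON files round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "calibration.json")
  jsonlite::write_json(list(x.tif = 20, y.png = 7.5), path, auto_unbox = TRUE)
  calib <- read_calibration(path)
  expect_equal(calibration_scale(calib, "y.png"), 1 / 7.5)
})

test_that("micrograph construction validates its invariants", {
  expect_error(micrograph(matrix(c(0, 2), 1, 2)), "\\[0, 1\\]")
  expect_error(micrograph(matrix(NA_real_, 1, 1)), "finite")
  expect_error(micrograph(matrix(0.5, 2, 2), scale = -1), "positive")
  m <- micrograph(matrix(0.5, 2, 3), name = "t", scale = 0.1)
  expect_equal(dim(m), c(2L, 3L))
})
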