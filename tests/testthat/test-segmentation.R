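test_that("Otsu thresholding matches its definition on forced cases", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  t1 <- otsu_threshold(v)
  expect_gt(t1, 0.1)
  expect_lt(t1, 0.9)
  t2 <- otsu_threshold(c(0, 0, 0, 1))
  expect_gt(t2, 0)
  expect_lt(t2, 1)
  expect_equal(sum(c(0, 0, 0, 1) > t2), 1L)
  expect_error(otsu_threshold(rep(0.5, 10)), "degenerate")
})

test_that("histogram Otsu equals the exhaustive search oracle", {
  set.seed(21)
  for (i in 1:8) {
    v <- c(rnorm(150, 0.3, 0.05), rnorm(100, 0.7, 0.08))
    v <- pmin(pmax(v, 0), 1)
    expect_equal(otsu_threshold(v), brute_otsu(v))
  }
})

test_that("three-class Otsu separates three intensity plateaus", {
  set.seed(4)
  v <- c(rnorm(500, 0.05, 0.02), rnorm(200, 0.45, 0.03), rnorm(300, 0.8, 0.04))
  thr <- multiotsu_threshold(v)
  expect_lt(thr[1], 0.45); expect_gt(thr[1], 0.05)
  expect_lt(thr[2], 0.8); expect_gt(thr[2], 0.45)
})

test_that("biofilm thresholding counts vessel pixels and honors zeros", {
  R <- matrix(0, 10, 10)
  expect_warning(bm <- threshold_biofilm(R), "all-zero")
  expect_equal(bm$vessel_pixels, 0L)

  R[2:4, 2:4] <- 0.5
  bm <- threshold_biofilm(R, method = "manual", manual_value = 0.25)
  expect_equal(bm$vessel_pixels, 9L)
  expect_true(!any(bm$mask & R == 0))
})

test_that("connected labeling is 8-connected by request and 4 otherwise", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("disc morphology and hole filling behave geometrically", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 10:30] <- TRUE
  er <- mask_erode(m, 3)
  expect_true(all(which(er, arr.ind = TRUE) >= 13))
  op <- mask_open(m, 3)
  expect_gt(sum(op & m) / sum(m), 0.95)
  holed <- m; holed[20, 20] <- FALSE
  expect_true(all(fill_holes(holed, 5)[10:30, 10:30]))
})

test_that("a lone rod is classified as a bacterium", {
  sc <- test_scene(101, n_hyphae = 0L, n_bacteria = 1L, n_filaments = 0L,
                   target_eps_coverage = 0)
  resp <- multiscale_response(sc$rendered, 1, 8, 4)
  bio <- suppressWarnings(threshold_biofilm(resp))
  labs <- classify_components(sc$rendered, bio)
  expect_equal(sum(labs$classes$class == "bacterium"), 1L)
  expect_equal(sum(labs$classes$class == "hypha"), 0L)
})

test_that("class masks are disjoint, exhaustive over labels, and deterministic", {
  sc <- test_scene(7)
  resp <- multiscale_response(sc$rendered)
  bio <- threshold_biofilm(resp)
  labs <- classify_components(sc$rendered, bio)
  overlap <- (labs$hyphae & labs$bacteria) | (labs$hyphae & labs$eps) |
    (labs$bacteria & labs$eps)
  expect_false(any(overlap))
  expect_equal(sort(unique(as.integer(labs$labels[labs$labels > 0]))),
               sort(labs$classes$label))
  expect_equal(labs$classes$area_px,
               as.integer(table(factor(labs$labels[labs$labels > 0],
                                       levels = labs$classes$label))),
               ignore_attr = TRUE)
  labs2 <- classify_components(sc$rendered, bio)
  expect_identical(labs$labels, labs2$labels)
  expect_identical(labs$classes, labs2$classes)
})

test_that("an uncalibrated image cannot be classified", {
  img <- micrograph(matrix(runif(64), 8, 8))
  bm <- structure(list(mask = matrix(TRUE, 8, 8), vessel_pixels = 64L,
                       threshold = 0.1, source = "matrix"),
                  class = "biofilm_mask")
  expect_error(classify_components(img, bm), "uncalibrated")
})
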