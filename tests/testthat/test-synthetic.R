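test_that("scenes are bit-reproducible from the seed", {
  p <- scene_params(size = 256L, n_hyphae = 1L, n_bacteria = 3L,
                    n_filaments = 2L, target_eps_coverage = 5, seed = 9L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$rendered$pixels, b$rendered$pixels)
  expect_identical(a$truth_eps, b$truth_eps)
  expect_identical(a$geometry$bacteria, b$geometry$bacteria)
  expect_identical(a$truth_coverage, b$truth_coverage)
})

test_that("the generator honors counts, coverage, and mask disjointness", {
  sc <- test_scene(7)
  p <- sc$params
  expect_equal(nrow(sc$geometry$bacteria), p$n_bacteria)
  expect_equal(length(sc$geometry$filaments), p$n_filaments)
  expect_equal(length(sc$geometry$hyphae), p$n_hyphae)
  expect_false(any(sc$truth_eps & (sc$truth_bacteria | sc$truth_hyphae)))
  expect_false(any(sc$truth_bacteria & sc$truth_hyphae))
  expect_equal(sc$truth_coverage,
               100 * sum(sc$truth_eps) / prod(dim(sc$rendered$pixels)))
  expect_lte(abs(sc$truth_coverage - p$target_eps_coverage), p$coverage_tol)
  expect_true(all(sc$rendered$pixels >= 0 & sc$rendered$pixels <= 1))
})

test_that("rod dimensions follow the truncated-normal study distributions", {
  set.seed(77)
  len <- epsquant:::rtrunc_norm(500, 1.4, 0.4, 0.53, 2.6)
  wid <- epsquant:::rtrunc_norm(500, 0.5, 0.1, 0.25, 0.85)
  expect_gt(mean(len), 1.3); expect_lt(mean(len), 1.5)
  expect_gt(mean(wid), 0.45); expect_lt(mean(wid), 0.55)
  expect_gte(min(len), 0.53); expect_lte(max(len), 2.6)
  expect_gte(min(wid), 0.25); expect_lte(max(wid), 0.85)
  # scene-level dimensions come from the same truncated distributions
  sc <- test_scene(7)
  expect_true(all(sc$geometry$bacteria$length_um >= 0.53 &
                  sc$geometry$bacteria$length_um <= 2.6))
  expect_true(all(sapply(sc$geometry$hyphae, `[[`, "width_um") >= 2.3 &
                  sapply(sc$geometry$hyphae, `[[`, "width_um") <= 4.2))
})

test_that("truth-mask attachment recovery matches the drawn filaments", {
  hits <- 0L; total <- 0L
  for (seed in c(7, 23)) {
    sc <- test_scene(seed)
    att <- measure_attachments(sc$truth_eps, sc$truth_bacteria,
                               sc$truth_hyphae, sc$rendered$scale,
                               adjacency_tol = 2.6, end_rule = "surface")
    rods <- sc$geometry$bacteria
    ar <- rods[rods$attached, , drop = FALSE]
    truth <- vapply(sc$geometry$filaments, `[[`, numeric(1), "length_um")
    for (i in seq_len(nrow(ar))) {
      d <- sqrt((att$anchor_r - ar$center_r[i])^2 +
                (att$anchor_c - ar$center_c[i])^2)
      j <- which.min(d)
      total <- total + 1L
      if (length(j) == 1L &&
          d[j] <= ar$length_um[i] / 2 / sc$rendered$scale + 4 &&
          abs(att$length_um[j] - truth[i]) / truth[i] <= 0.2)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.7)
})

test_that("fixtures round-trip through files", {
  dir <- withr::local_tempdir()
  p <- scene_params(size = 192L, n_hyphae = 1L, n_bacteria = 2L,
                    n_filaments = 1L, target_eps_coverage = 4, seed = 3L)
  sc <- suppressWarnings(generate_scene(p))
  files <- scene_to_fixtures(sc, dir)
  calib <- read_calibration(files$calibration)
  expect_equal(unname(calib[[p$name]]), p$pixels_per_micron)
  img <- load_micrograph(files$image, calib)
  # loading min-max normalizes; compare after normalizing the original
  want <- suppressWarnings(normalize_intensity(sc$rendered$pixels))
  expect_lt(max(abs(img$pixels - want)), 2 / 65535)
  truth <- jsonlite::read_json(files$truth)
  expect_equal(length(truth$bacteria), nrow(sc$geometry$bacteria))
  expect_equal(length(truth$filaments), length(sc$geometry$filaments))
  expect_equal(truth$truth_coverage, sc$truth_coverage, tolerance = 1e-12)
})

test_that("an unsatisfiable coverage target warns and reports what was achieved", {
  p <- scene_params(size = 192L, n_hyphae = 1L, n_bacteria = 0L,
                    n_filaments = 0L, target_eps_coverage = 90, seed = 2L)
  expect_warning(sc <- generate_scene(p), "budget|coverage")
  expect_lt(sc$truth_coverage, 90)
})
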