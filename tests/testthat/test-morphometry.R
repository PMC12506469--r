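test_that("area report reproduces the worked example and edge cases", {
  img <- micrograph(matrix(0.5, 10, 10), scale = 0.5)
  mask <- matrix(FALSE, 10, 10)
  mask[1:5, 1:5] <- TRUE          # 25 vessel pixels
  rep <- area_report(mask, img)
  expect_equal(rep$A_v, 6.25)
  expect_equal(rep$A_t, 25)
  expect_equal(rep$P_v, 25)

  empty <- area_report(matrix(FALSE, 10, 10), img)
  expect_equal(empty$A_v, 0); expect_equal(empty$P_v, 0)
  full <- area_report(matrix(TRUE, 10, 10), img)
  expect_equal(full$A_v, full$A_t); expect_equal(full$P_v, 100)
})

test_that("area identities hold on random masks and calibrations", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(5:40, 1); n <- sample(5:40, 1)
    scale <- runif(1, 0.01, 2)
    mask <- matrix(runif(m * n) < runif(1), m, n)
    img <- micrograph(matrix(0.5, m, n), scale = scale)
    rep <- area_report(mask, img)
    expect_equal(rep$A_v, sum(mask) * scale^2, tolerance = 1e-12)
    expect_equal(rep$A_t, m * n * scale^2, tolerance = 1e-12)
    expect_equal(rep$P_v, 100 * sum(mask) / (m * n), tolerance = 1e-12)
    expect_gte(rep$P_v, 0); expect_lte(rep$P_v, 100)
    # P_v does not depend on the calibration; areas scale quadratically
    img2 <- micrograph(matrix(0.5, m, n), scale = 2 * scale)
    rep2 <- area_report(mask, img2)
    expect_equal(rep2$P_v, rep$P_v)
    expect_equal(rep2$A_v, 4 * rep$A_v, tolerance = 1e-12)
  }
})

test_that("rod measurement recovers ellipse axes, discs, and rotations", {
  dims <- c(96, 96)
  # 1.4 x 0.5 um at 20 px/um -> 28 x 10 px ellipse
  rod <- ellipse_mask(dims, c(48, 48), 14, 5, 0.3)
  m <- measure_rod(rod, 0.05)
  expect_lt(abs(m[["length"]] - 1.4), 0.05)
  expect_lt(abs(m[["width"]] - 0.5), 0.05)
  expect_gte(m[["length"]], m[["width"]])

  disc <- ellipse_mask(dims, c(48, 48), 12, 12, 0)
  md <- measure_rod(disc, 0.05)
  expect_lt(abs(md[["length"]] / md[["width"]] - 1), 0.02)

  rot <- ellipse_mask(dims, c(48, 48), 14, 5, 0.3 + 37 * pi / 180)
  mr <- measure_rod(rot, 0.05)
  expect_lt(abs(mr[["length"]] - m[["length"]]), 0.05)
  expect_lt(abs(mr[["width"]] - m[["width"]]), 0.05)
  expect_error(measure_rod(matrix(FALSE, 4, 4), 0.05), "empty")
})

test_that("tube width is recovered for straight, thin, and curved tubes", {
  m <- matrix(FALSE, 80, 200)
  m[30:50, 10:190] <- TRUE       # 21 px wide, 1.05 um at 0.05 um/px
  expect_equal(measure_tube_width(m, 0.05), 1.05, tolerance = 0.03)

  line <- matrix(FALSE, 20, 60)
  line[10, 5:55] <- TRUE
  expect_warning(w <- measure_tube_width(line, 0.05), "pixel-limited")
  expect_equal(w, 0.05)

  # curved tube: annulus sector of constant width 12 px
  rr <- matrix(seq_len(160), 160, 160)
  cc <- matrix(seq_len(160), 160, 160, byrow = TRUE)
  rad <- sqrt((rr - 160)^2 + (cc - 160)^2)
  arc <- rad >= 94 & rad <= 106 & rr < 150 & cc < 150
  expect_lt(abs(measure_tube_width(arc, 0.05) - 13 * 0.05), 2 * 0.05)
})

test_that("attachment measurement traces rod-tube bridges and ignores others", {
  dims <- c(80, 80)
  tube <- matrix(FALSE, dims[1], dims[2]); tube[1:20, ] <- TRUE
  rod <- ellipse_mask(dims, c(35, 40), 12, 5, pi / 2)
  eps <- matrix(FALSE, dims[1], dims[2])
  eps[21:29, 40] <- TRUE          # straight 9 px bridge, gap rows 21..29
  eps <- eps & !tube & !rod
  att <- measure_attachments(eps, rod, tube, 0.05, adjacency_tol = 2,
                             end_rule = "surface")
  expect_equal(nrow(att), 1L)
  truth <- (35 - 5 - 20) * 0.05    # rod top surface at row 30, tube at 20
  expect_lt(abs(att$length_um - truth) / truth, 0.15)

  # filament touching two bacteria but no hypha contributes nothing
  rod2 <- ellipse_mask(dims, c(60, 40), 12, 5, pi / 2)
  eps2 <- matrix(FALSE, dims[1], dims[2]); eps2[44:52, 40] <- TRUE
  eps2 <- eps2 & !rod & !rod2
  none <- matrix(FALSE, dims[1], dims[2])
  att2 <- measure_attachments(eps2, rod | rod2, none, 0.05)
  expect_equal(nrow(att2), 0L)

  expect_equal(nrow(measure_attachments(none, rod, tube, 0.05)), 0L)
  expect_error(measure_attachments(eps[1:10, ], rod, tube, 0.05), "shape")
  expect_error(measure_attachments(rod, rod, tube, 0.05), "disjoint")
})

test_that("exclusion flags partial and deformed objects per the rules", {
  obj <- data.frame(
    sample_id = "s", label = 1:4,
    class = c("bacterium", "bacterium", "bacterium", "hypha"),
    length_um = c(1, 1.2, 1.4, 20), width_um = c(0.5, 0.4, 0.5, 3),
    solidity = c(0.95, 0.6, 0.9, NA),
    min_row = c(1, 40, 40, 1), max_row = c(10, 60, 60, 100),
    min_col = c(5, 40, 40, 1), max_col = c(15, 60, 60, 100))
  out <- exclusion_filter(obj, c(100, 100))
  expect_true(out$excluded[1]); expect_equal(out$reason[1], "partial")
  expect_true(out$excluded[2]); expect_equal(out$reason[2], "deformed")
  expect_false(out$excluded[3])
  expect_false(out$excluded[4])  # frame-crossing tube is still measurable

  # a bent (C-shaped) region really has low solidity
  rr <- matrix(seq_len(60), 60, 60)
  cc <- matrix(seq_len(60), 60, 60, byrow = TRUE)
  rad <- sqrt((rr - 30)^2 + (cc - 30)^2)
  cshape <- rad >= 15 & rad <= 22 & cc < 33
  expect_lt(epsquant:::component_solidity(cshape), 0.8)
  solid <- ellipse_mask(c(60, 60), c(30, 30), 14, 6, 0.5)
  expect_gt(epsquant:::component_solidity(solid), 0.9)
})

test_that("summaries compute population statistics and flag empty metrics", {
  obj <- data.frame(
    sample_id = rep(c("a", "b"), c(3, 1)),
    class = "bacterium",
    length_um = c(1, 2, 3, 5), width_um = c(0.4, 0.5, 0.6, 0.5),
    excluded = c(FALSE, FALSE, FALSE, FALSE))
  s <- summarize_measures(obj)
  pooled <- s$pooled
  row <- pooled[pooled$metric == "bacteria_length_um", ]
  want <- brute_mean_sd(c(1, 2, 3, 5))
  expect_equal(row$mean, want[["mean"]])
  expect_equal(row$sd, want[["sd"]], tolerance = 1e-12)
  expect_equal(row$n, 4L)
  a <- s$per_sample[s$per_sample$sample_id == "a" &
                    s$per_sample$metric == "bacteria_length_um", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, sqrt(2 / 3), tolerance = 1e-12)
  b <- s$per_sample[s$per_sample$sample_id == "b" &
                    s$per_sample$metric == "bacteria_length_um", ]
  expect_equal(b$sd, 0)
  hy <- pooled[pooled$metric == "hyphae_width_um", ]
  expect_equal(hy$n, 0L)
  expect_true(is.na(hy$mean))
})
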