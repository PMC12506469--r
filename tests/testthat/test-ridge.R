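test_that("Hessian of analytic images matches calculus", {
  const <- matrix(0.7, 48, 48)
  h <- compute_hessian(const, 2)
  expect_equal(max(abs(h$Ixx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(h$Ixy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(h$Iyy)), 0, tolerance = 1e-12)

  # I(x, y) = x^2 with x along the second (column) index
  x2 <- outer(rep(1, 80), (1:80)^2)
  for (s in c(1, 3)) {
    h <- compute_hessian(x2, s)
    r <- ceiling(4 * s) + 1L
    interior <- (r + 1):(80 - r)
    expect_equal(h$Ixx[interior, interior],
                 matrix(2, length(interior), length(interior)),
                 tolerance = 1e-9)
    expect_equal(max(abs(h$Iyy[interior, interior])), 0, tolerance = 1e-9)
    expect_equal(max(abs(h$Ixy[interior, interior])), 0, tolerance = 1e-9)
  }
  expect_error(compute_hessian(x2, 0), "positive")
})

test_that("separable convolution equals the dense 2-D oracle", {
  set.seed(11)
  for (i in 1:3) {
    img <- matrix(runif(64 * 64), 64, 64)
    g0 <- gaussian_kernel(1.5, 0)
    g2 <- gaussian_kernel(1.5, 2)
    got <- convolve_separable(img, g0, g2)
    want <- dense_conv2_reflect(img, g0, g2)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("closed-form eigenvalues match the generic solver and its ordering", {
  # diagonal case
  h <- structure(list(Ixx = matrix(-1), Ixy = matrix(0), Iyy = matrix(-4),
                      sigma = 1, normalized = FALSE), class = "hessian_field")
  e <- hessian_eigenvalues(h)
  expect_equal(as.numeric(e$lambda1), -1)
  expect_equal(as.numeric(e$lambda2), -4)

  # magnitude tie broken toward the more positive value
  h <- structure(list(Ixx = matrix(0), Ixy = matrix(3), Iyy = matrix(0),
                      sigma = 1, normalized = FALSE), class = "hessian_field")
  e <- hessian_eigenvalues(h)
  expect_equal(as.numeric(e$lambda1), 3)
  expect_equal(as.numeric(e$lambda2), -3)

  set.seed(5)
  for (i in 1:50) {
    A <- matrix(rnorm(4), 2); A <- (A + t(A)) / 2
    h <- structure(list(Ixx = matrix(A[1, 1]), Ixy = matrix(A[1, 2]),
                        Iyy = matrix(A[2, 2]), sigma = 1, normalized = FALSE),
                   class = "hessian_field")
    e <- hessian_eigenvalues(h)
    want <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(c(e$lambda1, e$lambda2)), sort(want), tolerance = 1e-12)
    expect_lte(abs(e$lambda1), abs(e$lambda2) + 1e-12)
  }
})

test_that("eigenvalue fields conserve trace and determinant", {
  set.seed(8)
  img <- matrix(runif(60 * 60), 60, 60)
  h <- compute_hessian(img, 2)
  e <- hessian_eigenvalues(h)
  expect_equal(e$lambda1 + e$lambda2, h$Ixx + h$Iyy, tolerance = 1e-9)
  expect_equal(e$lambda1 * e$lambda2, h$Ixx * h$Iyy - h$Ixy^2, tolerance = 1e-9)
})

test_that("the hard ridge condition selects exactly its branch cases", {
  ef <- function(l1, l2) structure(list(lambda1 = matrix(l1),
                                        lambda2 = matrix(l2), sigma = 1),
                                   class = "eigen_field")
  p <- ridge_params(alpha = 0.25, tau = 0)
  expect_equal(as.numeric(sato_response(ef(0, -5), p)$R), 5)
  expect_equal(as.numeric(sato_response(ef(3, -5), p)$R), 0)
  expect_equal(as.numeric(sato_response(ef(0, 5), p)$R), 0)
  # dark polarity flips the sign test
  pd <- ridge_params(alpha = 0.25, tau = 0, polarity = "dark")
  expect_equal(as.numeric(sato_response(ef(0, 5), pd)$R), 5)
  expect_error(ridge_params(alpha = 2), "\\[0, 1\\]")
  expect_error(ridge_params(tau = -1), "non-negative")
})

test_that("the response is invariant to intensity offset and linear in gain", {
  set.seed(13)
  base <- matrix(runif(48 * 48), 48, 48) * 0.5
  p <- ridge_params()
  r1 <- sato_response(hessian_eigenvalues(compute_hessian(base, 1.5)), p)$R
  r2 <- sato_response(hessian_eigenvalues(compute_hessian(base + 0.3, 1.5)), p)$R
  expect_equal(r1, r2, tolerance = 1e-10)
  r3 <- sato_response(hessian_eigenvalues(compute_hessian(base * 2, 1.5)), p)$R
  expect_equal(r3, 2 * r1, tolerance = 1e-10)
})

test_that("the multi-scale sweep reduces to single scale and dominates it", {
  set.seed(3)
  img <- matrix(runif(48 * 48), 48, 48)
  single <- sato_response(hessian_eigenvalues(compute_hessian(img, 1, normalized = TRUE)))
  multi1 <- multiscale_response(img, 1, 1, 1)
  expect_equal(multi1$R, single$R, tolerance = 1e-12)
  multi <- multiscale_response(img, 1, 6, 4)
  for (s in multi$sigmas) {
    rs <- sato_response(hessian_eigenvalues(compute_hessian(img, s, normalized = TRUE)))$R
    expect_true(all(multi$R - rs >= -1e-12))
  }
  expect_error(multiscale_response(img, 2, 1, 3), "sigma_min")
})

test_that("argmax scale tracks the profile scale of a Gaussian ridge", {
  s_true <- 3
  x <- seq_len(96)
  profile <- exp(-(x - 48)^2 / (2 * s_true^2))
  img <- matrix(rep(profile, each = 96), 96, 96, byrow = TRUE)  # ridge along rows
  resp <- multiscale_response(img, 1, 12, 8)
  # oracle: evaluate the closed-form normalized response on the same grid
  want_sigma <- resp$sigmas[which.max(gaussian_ridge_response(resp$sigmas, s_true))]
  got <- resp$argmax_sigma[48, 40:56]
  step <- resp$sigmas[2] / resp$sigmas[1]
  expect_true(all(got / want_sigma <= step + 1e-9 & got / want_sigma >= 1 / step - 1e-9))
})

test_that("a straight ridge response is robust to rotation", {
  x <- seq_len(128)
  profile <- exp(-(x - 64.5)^2 / (2 * 2^2))
  img <- matrix(rep(profile, times = 128), 128, 128)  # vertical ridge
  p <- ridge_params()
  r_then_rot <- rotate_bilinear(
    sato_response(hessian_eigenvalues(compute_hessian(img, 2)), p)$R, 30)
  rot_then_r <- sato_response(
    hessian_eigenvalues(compute_hessian(rotate_bilinear(img, 30), 2)), p)$R
  interior <- 33:96
  a <- r_then_rot[interior, interior]
  b <- rot_then_r[interior, interior]
  core <- a > 0.5 * max(a) & b > 0.5 * max(b)
  expect_gt(sum(core), 50)
  rel <- abs(a[core] - b[core]) / pmax(a[core], b[core])
  expect_lt(stats::median(rel), 0.05)
})
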