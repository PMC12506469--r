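# Hessian-eigenvalue ridge detection: the hard-conditioned Sato response.
#
# At scale sigma the image is convolved with Gaussian second-derivative
# kernels to give the symmetric Hessian H = [[Ixx, Ixy], [Ixy, Iyy]] at
# every pixel. With eigenvalues ordered |lambda1| <= |lambda2|, a bright
# ridge is present where lambda1 ~ 0 (slow variation along the structure)
# and lambda2 << 0 (strong concavity across it), and the response is then
# R = |lambda2|, else 0. The qualitative conditions are operationalized by
# ridge_params(): |lambda1| <= alpha * |lambda2| and lambda2 < -tau.

#' Gaussian-derivative Hessian of a micrograph
#'
#' Computes the three second partial derivatives `Ixx`, `Ixy`, `Iyy` by
#' separable convolution with Gaussian-derivative kernels at scale
#' `sigma` (pixels), reflect boundary. With `normalized = TRUE` each
#' entry is multiplied by `sigma^2` (gamma-normalization), which makes
#' responses comparable across a scale sweep.
#'
#' @param img A [micrograph()] or numeric matrix.
#' @param sigma Scale in pixels, strictly positive.
#' @param normalized Multiply entries by `sigma^2`? Default `FALSE`.
#' @return Object of class `hessian_field` with fields `Ixx`, `Ixy`,
#'   `Iyy`, `sigma`, `normalized`.
#' @export
compute_hessian <- function(img, sigma, normalized = FALSE) {
  px <- if (inherits(img, "micrograph")) img$pixels else img
  if (!is.matrix(px)) stop("`img` must be a micrograph or matrix", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number of pixels", call. = FALSE)
  g0 <- gaussian_kernel(sigma, 0L)
  g1 <- gaussian_kernel(sigma, 1L)
  g2 <- gaussian_kernel(sigma, 2L)
  # first matrix index is y, second is x
  Ixx <- convolve_separable(px, g0, g2)
  Iyy <- convolve_separable(px, g2, g0)
  Ixy <- convolve_separable(px, g1, g1)
  if (normalized) {
    s2 <- sigma^2
    Ixx <- Ixx * s2; Iyy <- Iyy * s2; Ixy <- Ixy * s2
  }
  structure(list(Ixx = Ixx, Ixy = Ixy, Iyy = Iyy, sigma = sigma,
                 normalized = isTRUE(normalized)),
            class = "hessian_field")
}

#' Per-pixel eigenvalues of the Hessian field
#'
#' Uses the closed form for a symmetric 2x2 matrix,
#' `trace/2 +- sqrt((Ixx - Iyy)^2 / 4 + Ixy^2)`, then orders the pair so
#' that `|lambda1| <= |lambda2|`. A magnitude tie is broken by taking the
#' more positive value as `lambda1`.
#'
#' @param h A `hessian_field` from [compute_hessian()].
#' @return Object of class `eigen_field` with fields `lambda1`, `lambda2`,
#'   `sigma`.
#' @export
hessian_eigenvalues <- function(h) {
  if (!inherits(h, "hessian_field")) stop("`h` must be a hessian_field", call. = FALSE)
  half_tr <- (h$Ixx + h$Iyy) / 2
  disc <- sqrt(((h$Ixx - h$Iyy) / 2)^2 + h$Ixy^2)
  e_hi <- half_tr + disc   # the more positive eigenvalue
  e_lo <- half_tr - disc
  swap <- abs(e_hi) > abs(e_lo)
  lambda1 <- ifelse(swap, e_lo, e_hi)
  lambda2 <- ifelse(swap, e_hi, e_lo)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma = h$sigma),
            class = "eigen_field")
}

#' Ridge-detection parameters
#'
#' Operationalizes the qualitative ridge conditions: "lambda1 ~ 0"
#' becomes `|lambda1| <= alpha * |lambda2|` and "lambda2 << 0" becomes
#' `lambda2 < -tau` (for bright ridges; dark ridges test
#' `lambda2 > tau`). The relative `alpha` test keeps the condition
#' invariant to intensity rescaling; `tau = 0` accepts any strict
#' concavity, leaving noise rejection to the response threshold.
#'
#' @param alpha Relative tolerance in `[0, 1]`; default 0.25.
#' @param tau Non-negative absolute threshold on `|lambda2|`; default 0.
#' @param polarity `"bright"` (default) for bright ridges on a dark
#'   background, `"dark"` for the opposite.
#' @return Object of class `ridge_params`.
#' @export
ridge_params <- function(alpha = 0.25, tau = 0, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, tau = tau, polarity = polarity),
            class = "ridge_params")
}

#' Single-scale hard-conditioned Sato response
#'
#' `R = |lambda2|` where the ridge condition holds, 0 otherwise:
#' for bright polarity the condition is
#' `|lambda1| <= alpha * |lambda2|` and `lambda2 < -tau`;
#' for dark polarity the sign test is `lambda2 > tau`.
#'
#' @param e An `eigen_field` from [hessian_eigenvalues()].
#' @param params A [ridge_params()].
#' @return Object of class `ridge_response` with fields `R` (non-negative
#'   matrix), `sigmas`, and `argmax_sigma` (`NULL` for single scale).
#' @export
sato_response <- function(e, params = ridge_params()) {
  if (!inherits(e, "eigen_field")) stop("`e` must be an eigen_field", call. = FALSE)
  if (!inherits(params, "ridge_params")) stop("`params` must be ridge_params", call. = FALSE)
  sign_ok <- if (params$polarity == "bright") e$lambda2 < -params$tau
             else e$lambda2 > params$tau
  cond <- (abs(e$lambda1) <= params$alpha * abs(e$lambda2)) & sign_ok
  structure(list(R = abs(e$lambda2) * cond, sigmas = e$sigma, argmax_sigma = NULL),
            class = "ridge_response")
}

#' Multi-scale Sato response (maximum over a geometric scale sweep)
#'
#' Evaluates the sigma^2-normalized single-scale response at `n_scales`
#' geometrically spaced scales in `[sigma_min, sigma_max]` and keeps the
#' per-pixel maximum, recording the scale attaining it. With a single
#' scale the result equals the single-scale response (times `sigma^2`).
#'
#' @param img A [micrograph()] or matrix.
#' @param sigma_min,sigma_max Sweep endpoints in pixels,
#'   `0 < sigma_min <= sigma_max`.
#' @param n_scales Number of scales, at least 1.
#' @param params A [ridge_params()].
#' @return A `ridge_response` with `argmax_sigma` set where `R > 0`.
#' @export
multiscale_response <- function(img, sigma_min = 1, sigma_max = 50,
                                n_scales = 10, params = ridge_params()) {
  if (!is.numeric(sigma_min) || !is.numeric(sigma_max) ||
      sigma_min <= 0 || sigma_min > sigma_max)
    stop("need 0 < sigma_min <= sigma_max", call. = FALSE)
  n_scales <- as.integer(n_scales)
  if (n_scales < 1L) stop("`n_scales` must be at least 1", call. = FALSE)
  sigmas <- if (n_scales == 1L) sigma_min
            else exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales))
  R <- NULL
  arg <- NULL
  for (s in sigmas) {
    e <- hessian_eigenvalues(compute_hessian(img, s, normalized = TRUE))
    r <- sato_response(e, params)$R
    if (is.null(R)) {
      R <- r
      arg <- array(s, dim = dim(r))
    } else {
      better <- r > R
      R[better] <- r[better]
      arg[better] <- s
    }
  }
  arg[R == 0] <- NA_real_
  structure(list(R = R, sigmas = sigmas, argmax_sigma = arg),
            class = "ridge_response")
}
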