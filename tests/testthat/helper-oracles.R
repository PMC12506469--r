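# Independent oracles used across the suite. Each is a deliberately
# naive implementation kept separate from the package's code paths.

# brute-force dense 2-D convolution (correlation form) with half-sample
# symmetric reflection, looping over kernel taps
dense_conv2_reflect <- function(x, wy, wx) {
  m <- nrow(x); n <- ncol(x)
  ry <- (length(wy) - 1L) %/% 2L
  rx <- (length(wx) - 1L) %/% 2L
  refl <- function(i, n) {
    p <- (i - 1L) %% (2L * n)
    ifelse(p < n, p + 1L, 2L * n - p)
  }
  xp <- x[refl(seq.int(1L - ry, m + ry), m),
          refl(seq.int(1L - rx, n + rx), n), drop = FALSE]
  out <- matrix(0, m, n)
  for (ky in seq_along(wy)) {
    for (kx in seq_along(wx)) {
      out <- out + wy[ky] * wx[kx] *
        xp[(ky - 1L) + seq_len(m), (kx - 1L) + seq_len(n), drop = FALSE]
    }
  }
  out
}

# exhaustive Otsu: for every candidate upper bin edge, compute the
# between-class variance from the histogram counts with explicit sums
brute_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  best_bcv <- -Inf
  best_edge <- NA_real_
  for (t in seq_len(n_bins - 1L)) {
    w0 <- 0; s0 <- 0; w1 <- 0; s1 <- 0
    for (b in seq_len(n_bins)) {
      if (b <= t) { w0 <- w0 + counts[b]; s0 <- s0 + counts[b] * mids[b] }
      else { w1 <- w1 + counts[b]; s1 <- s1 + counts[b] * mids[b] }
    }
    if (w0 == 0 || w1 == 0) next
    n <- w0 + w1
    bcv <- (w0 / n) * (w1 / n) * (s0 / w0 - s1 / w1)^2
    if (bcv > best_bcv) {
      best_bcv <- bcv
      best_edge <- breaks[t + 1L]
    }
  }
  best_edge
}

# population mean / SD by an explicit loop
brute_mean_sd <- function(x, ddof = 0L) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / n
  q <- 0
  for (v in x) q <- q + (v - mu)^2
  c(mean = mu, sd = if (n - ddof > 0) sqrt(q / (n - ddof)) else 0)
}

# bilinear rotation of a matrix about its center (zero fill)
rotate_bilinear <- function(x, angle_deg) {
  m <- nrow(x); n <- ncol(x)
  th <- angle_deg * pi / 180
  cy <- (m + 1) / 2; cx <- (n + 1) / 2
  out <- matrix(0, m, n)
  rr <- matrix(seq_len(m), m, n)
  cc <- matrix(seq_len(n), m, n, byrow = TRUE)
  # inverse map
  sr <- cy + cos(th) * (rr - cy) + sin(th) * (cc - cx)
  sc <- cx - sin(th) * (rr - cy) + cos(th) * (cc - cx)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 < m & c0 >= 1 & c0 < n
  idx <- function(r, c) (c - 1L) * m + r
  v <- numeric(m * n)
  v[ok] <- (1 - fr[ok]) * (1 - fc[ok]) * x[idx(r0[ok], c0[ok])] +
    fr[ok] * (1 - fc[ok]) * x[idx(r0[ok] + 1L, c0[ok])] +
    (1 - fr[ok]) * fc[ok] * x[idx(r0[ok], c0[ok] + 1L)] +
    fr[ok] * fc[ok] * x[idx(r0[ok] + 1L, c0[ok] + 1L)]
  matrix(v, m, n)
}

# closed-form sigma-normalized center response of a Gaussian line
# profile with spatial scale s, up to a common amplitude factor
gaussian_ridge_response <- function(sigma, s) {
  sigma^2 * s / (s^2 + sigma^2)^1.5
}
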