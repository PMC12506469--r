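# Thresholding and component classification: reproduce the processing
# chain original image -> ridge response -> biofilm mask -> segmentation
# of biofilm (EPS) from fungal and bacterial structures.

#' Otsu threshold over a 256-bin histogram
#'
#' Returns the threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over the upper edges of a 256-bin histogram
#' spanning the data range. Ties take the lowest such edge, which makes
#' the result deterministic.
#'
#' @param values Numeric vector, matrix or `ridge_response`; must contain
#'   at least two distinct values.
#' @param n_bins Number of histogram bins, default 256.
#' @return The threshold (a bin edge); pixels are foreground when
#'   strictly above it.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  if (inherits(values, "ridge_response")) values <- values$R
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite values to threshold", call. = FALSE)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("degenerate input: all values are equal, no threshold exists", call. = FALSE)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  s <- cumsum(counts * mids)
  n <- w[n_bins]; tot <- s[n_bins]
  t <- seq_len(n_bins - 1L)                 # split after bin t
  w0 <- w[t]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[t] / w0
  mu1 <- (tot - s[t]) / w1
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  breaks[which.max(bcv) + 1L]
}

#' Two-threshold (three-class) Otsu
#'
#' Exhaustively maximizes the three-class between-class variance over all
#' ordered pairs of bin edges. Used to separate the three intensity
#' populations of a coculture micrograph: dark background, mid-bright EPS
#' material, and bright cell bodies (hyphae, bacteria).
#'
#' @param values Numeric vector or matrix with at least three distinct
#'   values.
#' @param n_bins Histogram bins, default 128 (the search is quadratic in
#'   the bin count).
#' @return Numeric vector `c(lower, upper)` of the two thresholds.
#' @export
multiotsu_threshold <- function(values, n_bins = 128L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(unique(v)) < 3L)
    stop("need at least three distinct values for a three-class threshold",
         call. = FALSE)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  W <- c(0, cumsum(counts))
  S <- c(0, cumsum(counts * mids))
  n <- W[n_bins + 1L]
  class_term <- function(a, b) {      # bins (a+1)..b as one class
    w <- W[b + 1L] - W[a + 1L]
    s <- S[b + 1L] - S[a + 1L]
    ifelse(w > 0, s^2 / w, 0)
  }
  best <- -Inf; best_t <- c(NA_real_, NA_real_)
  for (t1 in seq_len(n_bins - 2L)) {
    t2 <- seq.int(t1 + 1L, n_bins - 1L)
    obj <- class_term(0L, t1) + class_term(t1, t2) + class_term(t2, n_bins)
    j <- which.max(obj)
    if (obj[j] > best) {
      best <- obj[j]
      best_t <- c(breaks[t1 + 1L], breaks[t2[j] + 1L])
    }
  }
  best_t
}

#' Threshold a ridge response into a biofilm mask
#'
#' Pixels strictly above the threshold become biofilm ("vessel") pixels.
#' Pixels with zero response are never in the mask. An all-zero response
#' yields an empty mask with a warning, not an error.
#'
#' @param response A `ridge_response` (or numeric matrix).
#' @param method `"otsu"` (default) or `"manual"`.
#' @param manual_value Threshold used when `method = "manual"`.
#' @return Object of class `biofilm_mask`: `mask` (logical matrix),
#'   `vessel_pixels` (count), `threshold`, `source`.
#' @export
threshold_biofilm <- function(response, method = c("otsu", "manual"),
                              manual_value = NULL) {
  method <- match.arg(method)
  R <- if (inherits(response, "ridge_response")) response$R else response
  src <- if (inherits(response, "ridge_response")) "ridge_response" else "matrix"
  if (all(R == 0)) {
    warning("all-zero response: empty biofilm mask")
    mask <- array(FALSE, dim = dim(R))
    return(structure(list(mask = mask, vessel_pixels = 0L,
                          threshold = NA_real_, source = src),
                     class = "biofilm_mask"))
  }
  thr <- if (method == "manual") {
    if (is.null(manual_value)) stop("manual method needs `manual_value`", call. = FALSE)
    as.numeric(manual_value)
  } else otsu_threshold(R)
  mask <- R > thr & R > 0
  structure(list(mask = mask, vessel_pixels = sum(mask), threshold = thr,
                 source = src),
            class = "biofilm_mask")
}

#' Morphological class bounds (in microns)
#'
#' Size and shape criteria separating hyphae, bacteria and EPS, expressed
#' in microns so classification is resolution independent. Defaults are
#' derived from the morphometry ranges observed in cocultures of this
#' kind: hyphal tubes are wider than 1.5 um; rod bacteria have lengths
#' about 0.5-2.6 um and widths 0.25-0.85 um (the bounds carry margin).
#'
#' @param hypha_min_width Minimum local width of a hypha, um.
#' @param hypha_max_width Maximum plausible width of a single hypha, um
#'   (observed coculture widths reach about 4.5 um; the default carries
#'   margin like the rod bounds).
#' @param bact_length_range Admissible rod length range, um.
#' @param bact_width_range Admissible rod width range, um.
#' @param elongation_min Major/minor axis ratio above which a component
#'   counts as elongated.
#' @param solidity_min Minimum solidity for an approximately convex rod.
#' @param min_object_px Components smaller than this many pixels are
#'   dropped as noise.
#' @return Object of class `morph_class_bounds`.
#' @export
morph_class_bounds <- function(hypha_min_width = 1.5,
                               hypha_max_width = 5,
                               bact_length_range = c(0.25, 3.0),
                               bact_width_range = c(0.2, 1.0),
                               elongation_min = 3,
                               solidity_min = 0.8,
                               min_object_px = 10L) {
  structure(list(hypha_min_width = hypha_min_width,
                 hypha_max_width = hypha_max_width,
                 bact_length_range = bact_length_range,
                 bact_width_range = bact_width_range,
                 elongation_min = elongation_min,
                 solidity_min = solidity_min,
                 min_object_px = as.integer(min_object_px)),
            class = "morph_class_bounds")
}

#' Segment biofilm components from fungal and bacterial structures
#'
#' Splits the detected structures of a calibrated micrograph into hyphae,
#' bacteria and residual EPS/biofilm:
#' \enumerate{
#'   \item A three-class Otsu on the grayscale image separates background,
#'     EPS-bright material and cell-bright material; cell pixels are those
#'     above the upper threshold.
#'   \item Hyphae are extracted from the cell mask by a disc opening of
#'     radius `hypha_min_width / 2`, which removes everything narrower
#'     than a hypha; elongation is checked per component.
#'   \item Bacteria are the remaining cell components that survive a small
#'     opening and whose moment-ellipse length, width and solidity fall in
#'     the rod bounds; failures are labeled `excluded`.
#'   \item EPS is residual: ridge-detected pixels that are brighter than
#'     the background class (above the lower Otsu threshold) and not part
#'     of any cell. This mirrors a segmentation in which biofilm is what
#'     remains after removing fungal and bacterial structures, and the
#'     brightness gate keeps the mask at the photometric width of the
#'     filaments rather than the wider support of the ridge response.
#' }
#'
#' @param img Calibrated [micrograph()].
#' @param biofilm A `biofilm_mask` from [threshold_biofilm()].
#' @param bounds A [morph_class_bounds()].
#' @param brightness_gate Apply the lower-threshold brightness gate to the
#'   EPS class? Default `TRUE`.
#' @return Object of class `component_labels`: `labels` (integer matrix),
#'   `classes` (data.frame label/class/area_px), and the per-class logical
#'   masks `hyphae`, `bacteria`, `eps`.
#' @export
classify_components <- function(img, biofilm, bounds = morph_class_bounds(),
                                brightness_gate = TRUE) {
  if (!inherits(img, "micrograph")) stop("`img` must be a micrograph", call. = FALSE)
  if (is.null(img$scale))
    stop("micrograph is uncalibrated: scale is required to classify", call. = FALSE)
  if (!inherits(biofilm, "biofilm_mask"))
    stop("`biofilm` must come from threshold_biofilm()", call. = FALSE)
  if (!all(dim(biofilm$mask) == dim(img$pixels)))
    stop("mask shape does not match the micrograph", call. = FALSE)
  ppm <- 1 / img$scale
  px <- img$pixels

  thr <- tryCatch(multiotsu_threshold(px), error = function(e) NULL)
  if (is.null(thr)) {          # (near-)flat image: nothing to classify
    lab <- array(0L, dim = dim(px))
    empty <- array(FALSE, dim = dim(px))
    return(structure(list(labels = lab,
                          classes = data.frame(label = integer(0),
                                               class = character(0),
                                               area_px = integer(0)),
                          hyphae = empty, bacteria = empty, eps = empty,
                          thresholds = c(NA_real_, NA_real_)),
                     class = "component_labels"))
  }
  # cell mask: bright class, despeckled (r = 1 opening) and with
  # pixel-noise holes filled so that the wide-disc opening below sees
  # solid structures
  r_h <- bounds$hypha_min_width / 2 * ppm
  cells <- mask_open(px > thr[2L], 1)
  cells <- fill_holes(cells, ceiling(r_h^2))

  # hyphae: opening at half the minimum hyphal width
  hyph <- mask_open(cells, r_h)
  hyph_lab <- label_components(hyph)
  if (max(hyph_lab) > 0L) {
    for (l in seq_len(max(hyph_lab))) {
      comp <- hyph_lab == l
      if (sum(comp) < bounds$min_object_px ||
          medial_elongation(comp) < bounds$elongation_min) {
        hyph[comp] <- FALSE    # blob, not a tube; goes back to the pool
      }
    }
  }

  # bacteria: what is left of the cell mask, cleaned of thin EPS-scale
  # debris by a small opening, then vetted as rods
  pool <- cells & !hyph
  r_b <- bounds$bact_width_range[1L] / 2 * ppm
  seeds <- mask_open(pool, r_b)
  seed_lab <- label_components(seeds)
  bact <- array(FALSE, dim = dim(px))
  excl <- array(FALSE, dim = dim(px))
  if (max(seed_lab) > 0L) {
    for (l in seq_len(max(seed_lab))) {
      seed <- seed_lab == l
      comp <- grow_component(seed, pool, r_b)
      if (sum(comp) < bounds$min_object_px) next
      m <- measure_rod(comp, img$scale)
      is_rod <- m["length"] >= bounds$bact_length_range[1L] &&
        m["length"] <= bounds$bact_length_range[2L] &&
        m["width"] >= bounds$bact_width_range[1L] &&
        m["width"] <= bounds$bact_width_range[2L] &&
        component_solidity(comp) >= bounds$solidity_min
      if (is_rod) bact[comp] <- TRUE else excl[comp] <- TRUE
    }
  }

  # EPS: residual, not part of any cell. With the brightness gate (the
  # default), the ridge mask acts as the detector and the mid-brightness
  # intensity band (between the two Otsu thresholds) gives the extent:
  # band components holding ridge-detected seed pixels are kept whole.
  # The ridge response is reliably above threshold on a filament's
  # centerline but not across its full photometric width, so thresholded
  # ridge pixels alone would understate EPS area.
  band <- px > thr[1L] & !cells & !hyph & !bact & !excl
  if (isTRUE(brightness_gate)) {
    eps <- reconstruct_from_seeds(band, biofilm$mask & band, min_seed_px = 2L)
  } else {
    eps <- biofilm$mask & !cells & !hyph & !bact & !excl
  }
  eps <- drop_small_components(eps, bounds$min_object_px)

  out <- assemble_labels(hyph, bact, eps, excl, thresholds = thr)
  # photometric EPS support (mid-brightness band): wider than the
  # ridge-confirmed class; used for attachment tracing, where short
  # filaments squeezed between two bright cell walls carry no ridge
  # response (the along-structure eigenvalue is dominated by the walls)
  out$eps_band <- band & !out$hyphae & !out$bacteria
  out
}

# elongation = major/minor axis ratio of the second-moment ellipse
component_elongation <- function(mask) {
  ax <- moment_axes_px(mask)
  if (ax[2L] <= 0) Inf else ax[1L] / ax[2L]
}

# medial elongation: total length over local width, area / width^2 with
# the width taken as twice the median distance along the ridge of the
# distance transform. For a tube of length L and width w this is L/w;
# for a disc about pi/4. Unlike the moment-ellipse axis ratio it stays
# large for crossing tubes merged into one component, and the median
# keeps it stable when crossing regions inflate the transform locally.
medial_elongation <- function(mask) {
  d <- mask_distance(mask)
  ridge <- d > 0
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
    ridge <- ridge & d >= shift_mat(d, o[1L], o[2L])
  w <- 2 * stats::median(d[ridge])
  if (!is.finite(w) || w <= 0) return(0)
  sum(mask) / w^2
}

# keep the components of `mask` containing at least `min_seed_px` pixels
# of `seeds`
reconstruct_from_seeds <- function(mask, seeds, min_seed_px = 1L) {
  if (!any(mask) || !any(seeds)) return(array(FALSE, dim = dim(mask)))
  lab <- label_components(mask)
  k <- max(lab)
  seed_counts <- tabulate(lab[seeds & lab > 0L], k)
  array(lab %in% which(seed_counts >= min_seed_px), dim = dim(mask))
}

# solidity = pixel area / area of the convex hull of the pixel squares
component_solidity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 3L) return(1)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  x <- hp[, 1L]; y <- hp[, 2L]
  area <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  hull_area <- area + per / 2 + 1      # Pick-style correction to pixel area
  min(1, n / hull_area)
}

# geodesic reconstruction limited to one disc radius: recovers the pixels
# of `pool` within distance r of the opened seed (restores rod tips the
# opening trimmed without absorbing attached filaments)
grow_component <- function(seed, pool, r) {
  bb <- which(seed, arr.ind = TRUE)
  pad <- ceiling(r) + 2L
  r1 <- max(1L, min(bb[, 1L]) - pad); r2 <- min(nrow(seed), max(bb[, 1L]) + pad)
  c1 <- max(1L, min(bb[, 2L]) - pad); c2 <- min(ncol(seed), max(bb[, 2L]) + pad)
  sub <- mask_dilate(seed[r1:r2, c1:c2, drop = FALSE], r) &
    pool[r1:r2, c1:c2, drop = FALSE]
  out <- array(FALSE, dim = dim(seed))
  out[r1:r2, c1:c2] <- sub
  out
}

drop_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim = dim(mask))
}

assemble_labels <- function(hyph, bact, eps, excl, thresholds) {
  # priority: bacterium > hypha > eps (masks should already be disjoint)
  hyph <- hyph & !bact
  eps <- eps & !bact & !hyph
  excl <- excl & !bact & !hyph & !eps
  lab <- array(0L, dim = dim(hyph))
  classes <- data.frame(label = integer(0), class = character(0),
                        area_px = integer(0), stringsAsFactors = FALSE)
  nxt <- 0L
  for (cl in c("hypha", "bacterium", "eps", "excluded")) {
    m <- switch(cl, hypha = hyph, bacterium = bact, eps = eps, excluded = excl)
    if (!any(m)) next
    l <- label_components(m)
    k <- max(l)
    lab[m] <- l[m] + nxt
    classes <- rbind(classes,
                     data.frame(label = nxt + seq_len(k), class = cl,
                                area_px = as.integer(tabulate(l[l > 0L], k)),
                                stringsAsFactors = FALSE))
    nxt <- nxt + k
  }
  structure(list(labels = lab, classes = classes, hyphae = hyph,
                 bacteria = bact, eps = eps, thresholds = thresholds),
            class = "component_labels")
}
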