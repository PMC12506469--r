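# Area/coverage quantities and object measurements, in micron units.

#' Biofilm area and coverage of a mask
#'
#' Computes, exactly as defined for vessel-pixel counting:
#' `A_v = vessel_pixels * scale^2` (biofilm area, um^2),
#' `A_t = M * N * scale^2` (total imaged area, um^2), and
#' `P_v = 100 * vessel_pixels / (M * N)` (percent coverage).
#'
#' @param mask A `biofilm_mask`, or a logical matrix.
#' @param img The calibrated [micrograph()] the mask was derived from.
#' @return Object of class `area_report`: `A_v`, `A_t`, `P_v`,
#'   `vessel_pixels`, `scale`.
#' @export
area_report <- function(mask, img) {
  if (!inherits(img, "micrograph")) stop("`img` must be a micrograph", call. = FALSE)
  if (is.null(img$scale))
    stop("micrograph is uncalibrated: areas need a scale", call. = FALSE)
  m <- if (inherits(mask, "biofilm_mask")) mask$mask else mask > 0
  if (!all(dim(m) == dim(img$pixels)))
    stop("mask shape does not match the micrograph", call. = FALSE)
  vp <- sum(m)
  M <- nrow(m); N <- ncol(m)
  structure(list(A_v = vp * img$scale^2,
                 A_t = M * N * img$scale^2,
                 P_v = 100 * vp / (M * N),
                 vessel_pixels = as.integer(vp),
                 scale = img$scale),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("A_v = %.4g um^2, A_t = %.4g um^2, P_v = %.3f%% (%d vessel px)\n",
              x$A_v, x$A_t, x$P_v, x$vessel_pixels))
  invisible(x)
}

# Decompose medial-width samples of a (possibly merged) tubular region
# into per-tube modes. Gaussian mixtures are fitted for each number of
# components; among fits whose components are all tight (a real tube
# has near-constant width) the best-BIC one is taken, else the overall
# best. A mode only counts as a tube if its samples extend along the
# field: crossing regions — where the inscribed disc spans both tubes —
# produce modes whose samples cluster in a patch no longer than a
# couple of widths, whereas a tube's medial samples run its whole
# length. A hard width cap (`max_center`, from the classifier's
# maximum plausible hyphal width) backs this up. Modes closer than
# 1.5 px are fused (splits of one physical mode).
width_modes <- function(d, rc = NULL, max_modes = 6L, tight_sd = 2.5,
                        max_center = Inf, min_mode_elongation = 2) {
  fit_best <- function(d, gs) {
    fits <- list()
    for (g in gs[gs <= max(1L, length(unique(d)))])
      fits[[length(fits) + 1L]] <-
        tryCatch(Mclust(d, G = g, modelNames = "V", verbose = FALSE),
                 error = function(e) NULL)
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) return(NULL)
    bic <- vapply(fits, function(f) f$bic, numeric(1))
    tight <- vapply(fits, function(f)
      max(sqrt(f$parameters$variance$sigmasq)) <= tight_sd, logical(1))
    if (any(tight)) fits[tight][[which.max(bic[tight])]]
    else fits[[which.max(bic)]]
  }
  fit <- fit_best(d, seq_len(max_modes))
  if (is.null(fit)) stop("mixture fit failed")
  mu <- fit$parameters$mean
  keep <- fit$parameters$pro >= 0.05
  if (!any(keep)) keep <- rep(TRUE, length(mu))
  if (!is.null(rc) && sum(keep) > 1L) {
    for (k in which(keep)) {
      pts <- rc[fit$classification == k, , drop = FALSE]
      if (nrow(pts) < 2L) { keep[k] <- FALSE; next }
      extent <- sqrt(diff(range(pts[, 1L]))^2 + diff(range(pts[, 2L]))^2)
      if (extent < min_mode_elongation * 2 * mu[k]) keep[k] <- FALSE
    }
    if (!any(keep)) keep <- fit$parameters$pro >= 0.05
  }
  centers <- mu[keep & mu <= max_center]
  if (length(centers) == 0L) centers <- min(mu[keep])
  centers <- sort(centers)
  grp <- cumsum(c(TRUE, diff(centers) > 1.5))
  as.numeric(tapply(centers, grp, mean))
}

# second-moment ellipse axis extents of a pixel region, in pixels.
# The covariance gets the +1/12 unit-square correction so that a rendered
# ellipse recovers its true axes rather than the axes of its pixel-center
# cloud; full axis extents are 4 * sqrt(eigenvalue).
moment_axes_px <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) stop("empty region", call. = FALSE)
  if (n == 1L) return(c(1, 1))
  mu <- colMeans(pts)
  d <- sweep(pts, 2L, mu)
  C <- crossprod(d) / n + diag(1 / 12, 2L)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  4 * sqrt(pmax(ev, 0))
}

#' Length and width of a rod-shaped region
#'
#' Major- and minor-axis extents of the region's second-moment ellipse
#' (the descriptor is robust to boundary pixelation), converted to
#' microns; `length >= width` is enforced by swapping.
#'
#' @param label_mask Logical matrix with one connected non-empty region.
#' @param scale Microns per pixel.
#' @return Named numeric vector `c(length = , width = )` in um.
#' @export
measure_rod <- function(label_mask, scale) {
  ax <- sort(moment_axes_px(label_mask), decreasing = TRUE)
  c(length = ax[1L] * scale, width = ax[2L] * scale)
}

#' Width of a tubular region
#'
#' Samples twice the Euclidean distance-transform value, minus one pixel
#' (the transform measures to background pixel centers), along the
#' region's medial axis (the ridge of the distance transform). Samples
#' limited by the image frame rather than the structure's own boundary
#' are dropped (tubes typically run out of the field). The default
#' location estimator is a
#' symmetrically trimmed mean (25 percent per tail): like the median it
#' rejects the low tail from residual boundary spurs and the high tail
#' from crossing regions, but when two tubes of different width merge
#' into one region it averages their widths instead of picking whichever
#' tube contributes more skeleton. `estimator = "median"` gives the
#' plain skeleton median.
#'
#' @param label_mask Logical matrix with one connected elongated region.
#' @param scale Microns per pixel.
#' @param estimator `"trimmed"` (default), `"median"`, or `"modes"`.
#'   `"modes"` fits a one-dimensional Gaussian mixture to the medial
#'   samples and averages the component centers (components under 10
#'   percent weight are ignored as crossing artifacts): when several
#'   tubes of different width merge into one region, each tube is one
#'   mode, so they contribute equally irrespective of their lengths.
#' @param max_width_um With `estimator = "modes"`, modes implying a
#'   width above this bound are discarded as crossing artifacts
#'   (default `Inf`: keep all).
#' @param edge Boundary convention. `"pixel"` (default) measures to the
#'   far side of the last foreground pixel (`2 d - 1`), exact for crisp
#'   masks. `"center"` measures to background-pixel centers (`2 d`),
#'   appropriate for masks obtained by thresholding a blurred image,
#'   whose boundary sits about half a pixel inside the true surface per
#'   side (validated on rendered tubes of known width).
#' @return Width in um. Regions effectively thinner than 2 px return the
#'   pixel-limited estimate with a warning.
#' @export
measure_tube_width <- function(label_mask, scale,
                               estimator = c("trimmed", "median", "modes"),
                               edge = c("pixel", "center"),
                               max_width_um = Inf) {
  estimator <- match.arg(estimator)
  edge <- match.arg(edge)
  if (!any(label_mask)) stop("empty region", call. = FALSE)
  d_all <- mask_distance(label_mask)
  # medial axis as the ridge (local maxima) of the distance transform:
  # equivalent to a thinning skeleton for width sampling, and cheap on
  # wide structures
  skel <- d_all > 0
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
    skel <- skel & d_all >= shift_mat(d_all, o[1L], o[2L])
  if (!any(skel)) skel <- label_mask

  rc <- which(skel, arr.ind = TRUE)
  d <- d_all[skel]
  # drop samples whose distance is limited by the image frame rather
  # than by the structure's own boundary
  frame <- pmin(rc[, 1L], nrow(label_mask) + 1L - rc[, 1L],
                rc[, 2L], ncol(label_mask) + 1L - rc[, 2L])
  ok <- frame > d
  if (any(ok)) d <- d[ok]

  med <- switch(estimator,
    median = stats::median(d),
    trimmed = mean(d, trim = 0.25),
    modes = {
      max_center <- if (is.finite(max_width_um))
        (max_width_um / scale + if (edge == "pixel") 1 else 0) / 2 else Inf
      rc_used <- rc[if (any(ok)) ok else rep(TRUE, nrow(rc)), , drop = FALSE]
      centers <- tryCatch(width_modes(d, rc_used, max_center = max_center),
                          error = function(e) NULL)
      if (is.null(centers)) mean(d, trim = 0.25) else mean(centers)
    })
  off <- if (edge == "pixel") 1 else 0
  if (med <= 1) {
    warning("region thinner than 2 px: width estimate is pixel-limited")
    return(max(2 * med - off, 1) * scale)
  }
  (2 * med - off) * scale
}

#' Geodesic lengths of bacterium-hypha attachment structures
#'
#' For every bacterium with adjacent EPS material, finds the shortest
#' geodesic path along the EPS skeleton from that bacterium to a hypha,
#' extended by the gap between each terminal skeleton pixel and the
#' structure it contacts. A bacterium contributes an attachment only if
#' such a path exists and is no longer than `max_length_um` (longer
#' connections through the general EPS net are not anchoring
#' structures). EPS touching only bacteria, or only hyphae, yields
#' nothing. Working per bacterium, rather than per EPS component, keeps
#' the measurement well defined when EPS strands fuse into one connected
#' network.
#'
#' @param eps_mask,bacteria_mask,hyphae_mask Pairwise-disjoint logical
#'   masks of equal shape.
#' @param scale Microns per pixel.
#' @param adjacency_tol Maximum pixel distance between the EPS skeleton
#'   and a structure for them to count as touching; the default
#'   `sqrt(2)` is one-pixel (8-neighborhood) dilation. Pass a larger
#'   value when the EPS mask has been pulled back from the cell
#'   boundaries.
#' @param max_length_um Longest path still reported as an attachment.
#' @param max_tortuosity Largest accepted ratio of path length to the
#'   straight-line distance between its anchor points; anchoring
#'   filaments are near-direct connectors (slightly curved), whereas a
#'   meandering route through the general EPS net is not an attachment
#'   structure.
#' @return Data frame with one row per attached bacterium: `label`
#'   (bacterium component index), `length_um`, `width_um` (median EPS
#'   width along the path), path centroid and bounding box (pixels).
#' @export
measure_attachments <- function(eps_mask, bacteria_mask, hyphae_mask, scale,
                                adjacency_tol = sqrt(2),
                                max_length_um = 1.5,
                                max_tortuosity = 1.6,
                                end_rule = c("center", "surface")) {
  end_rule <- match.arg(end_rule)
  dims <- dim(eps_mask)
  if (!all(dim(bacteria_mask) == dims) || !all(dim(hyphae_mask) == dims))
    stop("masks must share the same shape", call. = FALSE)
  if (any(eps_mask & bacteria_mask) || any(eps_mask & hyphae_mask) ||
      any(bacteria_mask & hyphae_mask))
    stop("masks must be pairwise disjoint", call. = FALSE)
  out <- data.frame(label = integer(0), length_um = numeric(0),
                    width_um = numeric(0), centroid_r = numeric(0),
                    centroid_c = numeric(0), anchor_r = numeric(0),
                    anchor_c = numeric(0), min_row = integer(0),
                    max_row = integer(0), min_col = integer(0),
                    max_col = integer(0))
  if (!any(eps_mask) || !any(bacteria_mask) || !any(hyphae_mask)) return(out)

  skel <- skeletonize(eps_mask)
  if (!any(skel)) return(out)
  sk_idx <- which(skel)
  nr <- dims[1L]
  rank <- integer(prod(dims))
  rank[sk_idx] <- seq_along(sk_idx)
  r <- ((sk_idx - 1L) %% nr) + 1L
  cc <- ((sk_idx - 1L) %/% nr) + 1L
  edges <- integer(0); w <- numeric(0)
  # calibrated digital-length step weights (Vossepoel-Smeulders) rather
  # than 1 / sqrt(2): plain chain-code weights overestimate the length
  # of digitized curves at intermediate orientations
  for (o in list(c(1L, 0L, 0.948), c(0L, 1L, 0.948),
                 c(1L, 1L, 1.343), c(1L, -1L, 1.343))) {
    r2 <- r + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= dims[2L]
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- skel[j]
    if (any(ok2)) {
      edges <- c(edges, rbind(rank[sk_idx[ok]][ok2], rank[j][ok2]))
      w <- c(w, rep.int(o[3L], sum(ok2)))
    }
  }
  g <- igraph::make_graph(edges, n = length(sk_idx), directed = FALSE)

  dh <- mask_distance(!hyphae_mask)    # distance to nearest hypha pixel
  h_nodes <- which(dh[sk_idx] <= adjacency_tol)
  if (length(h_nodes) == 0L) return(out)
  d_eps <- mask_distance(eps_mask)

  blab <- label_components(bacteria_mask)
  max_px <- max_length_um / scale
  for (b in seq_len(max(blab))) {
    # per-rod distances computed in a window around the rod (everything
    # relevant lies within the maximum attachment length)
    bb <- which(blab == b, arr.ind = TRUE)
    pad <- ceiling(max_px) + 4L
    r1 <- max(1L, min(bb[, 1L]) - pad); r2 <- min(dims[1L], max(bb[, 1L]) + pad)
    c1 <- max(1L, min(bb[, 2L]) - pad); c2 <- min(dims[2L], max(bb[, 2L]) + pad)
    dbw <- mask_distance(blab[r1:r2, c1:c2, drop = FALSE] != b)
    in_win <- r >= r1 & r <= r2 & cc >= c1 & cc <= c2
    db_sk <- rep(Inf, length(sk_idx))
    db_sk[in_win] <- dbw[cbind(r[in_win] - r1 + 1L, cc[in_win] - c1 + 1L)]
    # every skeleton pixel adjacent to this bacterium is a candidate
    # start; the true filament stub then competes with (and beats) any
    # nearby strand of the general EPS net
    b_nodes <- which(db_sk <= adjacency_tol)
    if (length(b_nodes) == 0L) next
    geo <- igraph::distances(g, v = b_nodes, to = h_nodes, weights = w)
    # "center": gaps are center-to-center distances to the structure
    # masks; a thresholded mask's boundary-pixel centers track the true
    # surface (validated on rendered reference filaments of known
    # length). "surface": half a pixel less per end, exact for crisp
    # masks.
    end_off <- if (end_rule == "center") 0 else 0.5
    gap_b <- pmax(db_sk[b_nodes] - end_off, 0)
    gap_h <- pmax(dh[sk_idx[h_nodes]] - end_off, 0)
    tot <- sweep(sweep(geo, 2L, gap_h, `+`), 1L, gap_b, `+`)
    # straight-line anchor-to-anchor distance for every candidate pair
    chord <- sqrt(outer(r[b_nodes], r[h_nodes], `-`)^2 +
                  outer(cc[b_nodes], cc[h_nodes], `-`)^2) +
      outer(gap_b, gap_h, `+`)
    tort <- tot / pmax(chord, 1)
    cand <- is.finite(tot) & tot <= max_px & tort <= max_tortuosity
    if (!any(cand)) next
    # two-stage choice: restrict to the most direct connectors, then
    # take the shortest among them. Selecting by raw minimum length
    # over all routes biases the measurement downward; selecting by
    # directness alone admits long quasi-straight detours
    t_min <- min(tort[cand])
    cand <- cand & tort <= t_min + 0.2
    tot2 <- tot
    tot2[!cand] <- Inf
    jj <- arrayInd(which.min(tot2), dim(tot))
    path <- igraph::shortest_paths(g, from = b_nodes[jj[1L]],
                                   to = h_nodes[jj[2L]],
                                   weights = w)$vpath[[1L]]
    path_idx <- sk_idx[as.integer(path)]
    pr <- ((path_idx - 1L) %% nr) + 1L
    pc <- ((path_idx - 1L) %/% nr) + 1L
    # the length is measured on a lightly smoothed version of the pixel
    # path: the raw chain of skeleton pixels staircases around the true
    # curve and overestimates its arc length
    len_px <- smooth_path_length(pr, pc) +
      gap_b[jj[1L]] + gap_h[jj[2L]]
    if (!is.finite(len_px) || len_px > max_px) next
    out <- rbind(out, data.frame(
      label = b, length_um = len_px * scale,
      width_um = max(2 * stats::median(d_eps[path_idx]) - 1, 1) * scale,
      centroid_r = mean(pr), centroid_c = mean(pc),
      anchor_r = pr[1L], anchor_c = pc[1L],
      min_row = min(pr), max_row = max(pr),
      min_col = min(pc), max_col = max(pc)))
  }
  out
}

#' Flag partially visible or deformed objects
#'
#' Operationalizes the rule that occluded, deformed or partially visible
#' cells are not measured: objects whose bounding box touches the image
#' border are flagged `"partial"`; bacteria with solidity below
#' `solidity_min` are flagged `"deformed"`. Flagged objects are retained
#' in the table (with `excluded = TRUE`) but omitted from summaries.
#'
#' @param measures Data frame of object measures with columns `class`,
#'   `min_row`, `max_row`, `min_col`, `max_col` and (for bacteria)
#'   `solidity`.
#' @param image_shape `c(M, N)` of the source image.
#' @param solidity_min Solidity cutoff for "deformed", default 0.8.
#' @return The data frame with `excluded` (logical) and `reason`
#'   (character) columns filled in.
#' @export
exclusion_filter <- function(measures, image_shape, solidity_min = 0.8) {
  if (nrow(measures) == 0L) {
    measures$excluded <- logical(0)
    measures$reason <- character(0)
    return(measures)
  }
  # hyphae routinely run out of the frame; their measured quantity
  # (local width) is unaffected by truncation, so the border rule
  # applies to the discrete objects measured for extent
  partial <- measures$class != "hypha" &
    (measures$min_row <= 1L | measures$min_col <= 1L |
     measures$max_row >= image_shape[1L] | measures$max_col >= image_shape[2L])
  deformed <- !partial & measures$class == "bacterium" &
    !is.na(measures$solidity) & measures$solidity < solidity_min
  measures$excluded <- partial | deformed
  measures$reason <- ifelse(partial, "partial", ifelse(deformed, "deformed", ""))
  measures
}

# arc length of a pixel path regularized by a quadratic-arc fit: the
# raw chain of skeleton pixels staircases around the true curve and
# kinks where the EPS mask fuses with crossing strands, both of which
# inflate the summed step length. Attachment structures are smooth,
# gently curved arcs, so each coordinate is fitted as a quadratic in
# normalized arc position and the length is taken along the fitted
# curve; a straight digitized line comes out exact
smooth_path_length <- function(pr, pc) {
  n <- length(pr)
  if (n < 2L) return(0)
  if (n < 5L) {
    # too short to fit: straight chord between the path ends
    return(sqrt((pr[n] - pr[1L])^2 + (pc[n] - pc[1L])^2))
  }
  t <- c(0, cumsum(sqrt(diff(pr)^2 + diff(pc)^2)))
  t <- t / t[n]
  fr <- stats::lm.fit(cbind(1, t, t^2), pr)$coefficients
  fc <- stats::lm.fit(cbind(1, t, t^2), pc)$coefficients
  td <- seq(0, 1, length.out = 4L * n)
  X <- cbind(1, td, td^2)
  sum(sqrt(diff(X %*% fr)^2 + diff(X %*% fc)^2))
}

pop_sd <- function(x, ddof = 0L) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n - ddof <= 0L) return(0)
  sqrt(sum((x - mean(x))^2) / (n - ddof))
}

#' Per-sample and pooled summaries of object measures
#'
#' Mean, standard deviation and count per metric, per sample and pooled
#' over all samples, ignoring excluded objects. The SD is the population
#' form (`ddof = 0`) by default; a single value gets SD 0; a metric with
#' no usable values is reported with `n = 0` and `mean = NA` rather than
#' silently zero.
#'
#' @param measures Data frame with columns `sample_id`, `class`,
#'   `length_um`, `width_um`, `excluded`.
#' @param sd_ddof Degrees-of-freedom correction for the SD, default 0.
#' @return List with `per_sample` and `pooled` data frames (columns
#'   `sample_id`, `metric`, `mean`, `sd`, `n`).
#' @export
summarize_measures <- function(measures, sd_ddof = 0L) {
  metrics <- list(
    bacteria_length_um = function(d) d$length_um[d$class == "bacterium"],
    bacteria_width_um = function(d) d$width_um[d$class == "bacterium"],
    hyphae_width_um = function(d) d$width_um[d$class == "hypha"],
    attachment_length_um = function(d) d$length_um[d$class == "attachment"]
  )
  used <- measures[!measures$excluded, , drop = FALSE]
  one <- function(d, sid) {
    rows <- lapply(names(metrics), function(mn) {
      v <- metrics[[mn]](d)
      v <- v[is.finite(v)]
      data.frame(sample_id = sid, metric = mn,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v)) pop_sd(v, sd_ddof) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  per <- do.call(rbind, lapply(split(used, used$sample_id),
                               function(d) one(d, d$sample_id[1L])))
  rownames(per) <- NULL
  list(per_sample = per, pooled = one(used, "pooled"))
}
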