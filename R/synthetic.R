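# Synthetic SEM-like coculture scenes with exact ground truth.
#
# A scene is built in continuous pixel coordinates: smooth tube
# centerlines (hyphae), rod bacteria as filled ellipses placed adjacent
# to tubes, short curvilinear attachment filaments connecting rod
# boundaries to tube boundaries, and additional curvy EPS strands added
# until the EPS coverage target is met. Rendering is plateau intensities
# + Gaussian blur + additive Gaussian noise; the truth masks come from
# the same geometry before any degradation.

# inverse-CDF truncated normal: deterministic draw count per call
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rot90 <- function(v) c(-v[2L], v[1L])
rot_by <- function(v, ang) {
  c(cos(ang) * v[1L] - sin(ang) * v[2L], sin(ang) * v[1L] + cos(ang) * v[2L])
}

# stamp all pixels within `hw` of the segment p1--p2 into `mask`
stamp_segment <- function(mask, p1, p2, hw) {
  nr <- nrow(mask); nc <- ncol(mask)
  r1 <- max(1L, floor(min(p1[1L], p2[1L]) - hw - 1)); r2 <- min(nr, ceiling(max(p1[1L], p2[1L]) + hw + 1))
  c1 <- max(1L, floor(min(p1[2L], p2[2L]) - hw - 1)); c2 <- min(nc, ceiling(max(p1[2L], p2[2L]) + hw + 1))
  if (r1 > r2 || c1 > c2) return(mask)
  rr <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L)
  cc <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) {
    d2 <- (rr - p1[1L])^2 + (cc - p1[2L])^2
  } else {
    t <- pmin(pmax(((rr - p1[1L]) * v[1L] + (cc - p1[2L]) * v[2L]) / L2, 0), 1)
    d2 <- (rr - (p1[1L] + t * v[1L]))^2 + (cc - (p1[2L] + t * v[2L]))^2
  }
  sub <- mask[r1:r2, c1:c2, drop = FALSE]
  mask[r1:r2, c1:c2] <- sub | (d2 <= hw^2)
  mask
}

stamp_polyline <- function(mask, pts, hw) {
  for (i in seq_len(nrow(pts) - 1L))
    mask <- stamp_segment(mask, pts[i, ], pts[i + 1L, ], hw)
  mask
}

stamp_ellipse <- function(mask, center, a, b, phi) {
  nr <- nrow(mask); nc <- ncol(mask)
  r1 <- max(1L, floor(center[1L] - a - 1)); r2 <- min(nr, ceiling(center[1L] + a + 1))
  c1 <- max(1L, floor(center[2L] - a - 1)); c2 <- min(nc, ceiling(center[2L] + a + 1))
  rr <- matrix(r1:r2, r2 - r1 + 1L, c2 - c1 + 1L) - center[1L]
  cc <- matrix(c1:c2, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE) - center[2L]
  u <- cos(phi) * rr + sin(phi) * cc
  w <- -sin(phi) * rr + cos(phi) * cc
  inside <- (u / a)^2 + (w / b)^2 <= 1
  sub <- mask[r1:r2, c1:c2, drop = FALSE]
  mask[r1:r2, c1:c2] <- sub | inside
  mask
}

# ellipse boundary radius along a unit direction `d` for axes (a, b) at
# orientation phi
ellipse_radius <- function(a, b, phi, d) {
  psi <- atan2(d[2L], d[1L]) - phi
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

#' Parameters of a synthetic coculture scene
#'
#' Defaults encode the study conditions the generator emulates: rod
#' bacteria with length 1.4 +/- 0.4 um truncated to the observed
#' [0.53, 2.6] um and width 0.5 +/- 0.1 um truncated to [0.25, 0.85] um;
#' coculture hyphae of width 3.0 +/- 0.5 um truncated to [2.3, 4.2] um;
#' attachment filaments of length 0.3 +/- 0.1 um and width 0.08 um; and
#' an EPS coverage target of 18.33 percent of the field.
#'
#' @param size Image side in pixels (square raster).
#' @param pixels_per_micron Calibration, px/um.
#' @param n_hyphae,n_bacteria,n_filaments Object counts;
#'   `n_filaments <= n_bacteria` rods are attached via filaments.
#' @param hypha_width_mean,hypha_width_sd,hypha_width_range Tube width
#'   distribution, um.
#' @param bact_length_mean,bact_length_sd,bact_length_range Rod length
#'   distribution, um.
#' @param bact_width_mean,bact_width_sd,bact_width_range Rod width
#'   distribution, um.
#' @param filament_length_mean,filament_length_sd,filament_length_range
#'   Attachment length distribution, um.
#' @param filament_width EPS filament/strand width, um.
#' @param target_eps_coverage Target EPS coverage, percent of all pixels.
#' @param coverage_tol Acceptable shortfall before warning, percentage
#'   points.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param blur_sigma Rendering blur, px.
#' @param intensities Named plateau intensities for background, eps,
#'   hypha, bacterium.
#' @param seed Integer seed fixing the whole scene.
#' @param name Image name used for files and calibration entries.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(size = 1024L, pixels_per_micron = 20,
                         n_hyphae = 3L,
                         hypha_width_mean = 3.0, hypha_width_sd = 0.5,
                         hypha_width_range = c(2.3, 4.2),
                         n_bacteria = 12L,
                         bact_length_mean = 1.4, bact_length_sd = 0.4,
                         bact_length_range = c(0.53, 2.6),
                         bact_width_mean = 0.5, bact_width_sd = 0.1,
                         bact_width_range = c(0.25, 0.85),
                         n_filaments = 10L,
                         filament_length_mean = 0.3, filament_length_sd = 0.1,
                         filament_length_range = c(0.1, 0.6),
                         filament_width = 0.08,
                         target_eps_coverage = 18.33,
                         coverage_tol = 1,
                         noise_sd = 0.05, blur_sigma = 0.5,
                         intensities = c(background = 0.05, eps = 0.45,
                                         hypha = 0.7, bacterium = 0.85),
                         seed = 1L,
                         name = sprintf("scene_seed%04d.tif", seed)) {
  p <- as.list(environment())
  stopifnot(p$size >= 2 * p$hypha_width_range[2L] * p$pixels_per_micron,
            p$pixels_per_micron > 0,
            p$n_hyphae >= 0, p$n_bacteria >= 0, p$n_filaments >= 0,
            p$n_filaments <= p$n_bacteria)
  structure(p, class = "scene_params")
}

#' Generate a synthetic coculture scene with ground truth
#'
#' Fully determined by `params$seed`. Truth masks are pairwise disjoint
#' with priority bacterium > hypha > eps; `truth_coverage` is the exact
#' EPS pixel fraction. EPS strands are added until the coverage target is
#' within reach of one strand; if the placement budget is exhausted first
#' the achieved coverage is returned with a warning.
#'
#' @param params A [scene_params()].
#' @return Object of class `synthetic_scene`: `rendered` (a calibrated
#'   [micrograph()]), `truth_hyphae`, `truth_bacteria`, `truth_eps`
#'   (logical masks), `geometry` (hypha centerlines and widths, rod poses
#'   and dimensions, filament polylines and lengths, all lengths in um),
#'   `truth_coverage` (percent), `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  ppm <- params$pixels_per_micron
  S <- as.integer(params$size)
  dims <- c(S, S)
  hyph <- array(FALSE, dim = dims)
  bact <- array(FALSE, dim = dims)
  eps <- array(FALSE, dim = dims)

  # ---- hyphae: smooth wavy centerlines crossing the field ----
  tubes <- list()
  for (i in seq_len(params$n_hyphae)) {
    w_um <- rtrunc_norm(1L, params$hypha_width_mean, params$hypha_width_sd,
                        params$hypha_width_range[1L], params$hypha_width_range[2L])
    # redraw the course if it would run along (or hug) an existing
    # tube: fields where hyphae are indistinguishable are not
    # measurable, and a sub-resolution gap between near-parallel tubes
    # fuses under blur (point crossings are fine and are handled
    # downstream); keep the least conflicting course if no draw
    # satisfies the cap
    dnear <- if (any(hyph)) mask_distance(!hyph) else NULL
    best <- NULL; best_frac <- Inf
    for (try in seq_len(60L)) {
      anchor <- stats::runif(2L, 0.25 * S, 0.75 * S)
      theta <- stats::runif(1L, 0, pi)
      dir <- c(cos(theta), sin(theta))
      perp <- rot90(dir)
      amp <- stats::runif(1L, 0, 0.04 * S)
      wl <- stats::runif(1L, 0.6, 1.6) * S
      phase <- stats::runif(1L, 0, 2 * pi)
      t <- seq(-1.2 * S, 1.2 * S, by = 2)
      wig <- amp * sin(2 * pi * t / wl + phase)
      pts <- cbind(anchor[1L] + t * dir[1L] + wig * perp[1L],
                   anchor[2L] + t * dir[2L] + wig * perp[2L])
      keep <- pts[, 1L] > -0.1 * S & pts[, 1L] < 1.1 * S &
        pts[, 2L] > -0.1 * S & pts[, 2L] < 1.1 * S
      pts <- pts[keep, , drop = FALSE]
      cand <- stamp_polyline(array(FALSE, dim = dims), pts, w_um * ppm / 2)
      frac <- if (is.null(dnear)) 0
              else sum(hyph[cand] | dnear[cand] < 4) / max(1L, sum(cand))
      if (frac < best_frac) {
        best <- list(cand = cand, pts = pts)
        best_frac <- frac
      }
      if (frac <= 0.08) break
    }
    hyph <- hyph | best$cand
    tubes[[i]] <- list(width_um = w_um, centerline = best$pts)
  }

  # ---- bacteria (rods) adjacent to tubes, some attached by filaments ----
  rod_len <- rtrunc_norm(params$n_bacteria, params$bact_length_mean,
                         params$bact_length_sd,
                         params$bact_length_range[1L], params$bact_length_range[2L])
  rod_wid <- rtrunc_norm(params$n_bacteria, params$bact_width_mean,
                         params$bact_width_sd,
                         params$bact_width_range[1L], params$bact_width_range[2L])
  fil_len <- rtrunc_norm(params$n_filaments, params$filament_length_mean,
                         params$filament_length_sd,
                         params$filament_length_range[1L],
                         params$filament_length_range[2L])
  rods <- data.frame(center_r = numeric(0), center_c = numeric(0),
                     length_um = numeric(0), width_um = numeric(0),
                     angle = numeric(0), attached = logical(0))
  filaments <- list()
  dh_scene <- if (any(hyph)) mask_distance(!hyph) else NULL
  margin <- min((params$bact_length_range[2L] + params$filament_length_range[2L] + 1) * ppm / 2,
                0.25 * S)
  for (i in seq_len(params$n_bacteria)) {
    attach <- i <= params$n_filaments
    a <- rod_len[i] * ppm / 2
    b <- rod_wid[i] * ppm / 2
    placed <- FALSE
    for (try in seq_len(200L)) {
      if (length(tubes) > 0L) {
        tube <- tubes[[sample.int(length(tubes), 1L)]]
        j <- sample.int(nrow(tube$centerline) - 2L, 1L) + 1L
        pt <- tube$centerline[j, ]
        if (any(pt < margin) || any(pt > S - margin)) next
        tang <- tube$centerline[j + 1L, ] - tube$centerline[j - 1L, ]
        tang <- tang / sqrt(sum(tang^2))
        n <- rot90(tang) * sample(c(-1, 1), 1L)
        base <- pt + (tube$width_um * ppm / 2) * n
      } else {
        base <- stats::runif(2L, margin, S - margin)
        n <- rot_by(c(1, 0), stats::runif(1L, 0, 2 * pi))
      }
      d <- rot_by(n, stats::rnorm(1L, 0, 0.2))
      if (attach) {
        Lf <- fil_len[i] * ppm
        bend <- stats::rnorm(1L, 0, 0.15) * Lf
        ctrl <- base + 0.5 * Lf * d + bend * rot90(d)
        ends <- base + Lf * d
        tt <- seq(0, 1, length.out = 9L)
        bz <- cbind((1 - tt)^2 * base[1L] + 2 * (1 - tt) * tt * ctrl[1L] + tt^2 * ends[1L],
                    (1 - tt)^2 * base[2L] + 2 * (1 - tt) * tt * ctrl[2L] + tt^2 * ends[2L])
        arc <- sum(sqrt(rowSums(diff(bz)^2)))
        bz <- sweep(sweep(bz, 2L, base), 1L, rep(Lf / arc, 9L), `*`)
        bz <- sweep(bz, 2L, base, `+`)         # rescaled: arc length == Lf
        E <- bz[9L, ]
        d_end <- E - bz[8L, ]
        d_end <- d_end / sqrt(sum(d_end^2))
        gap_pts <- bz
      } else {
        g <- stats::runif(1L, 0.1, 0.4) * ppm
        E <- base + g * d
        d_end <- d
        gap_pts <- NULL
      }
      # rods lie along the hyphal surface (broadside attachment); a small
      # tilt only, so the filament stays the rod's closest connection
      phi <- atan2(d_end[2L], d_end[1L]) + pi / 2 + stats::rnorm(1L, 0, 0.12)
      rad <- ellipse_radius(a, b, phi, d_end)
      center <- E + rad * d_end
      if (any(center < a + 2) || any(center > S - a - 2)) next
      cand <- stamp_ellipse(array(FALSE, dim = dims), center, a, b, phi)
      if (any(cand & (bact | hyph))) next
      if (!is.null(dh_scene)) {
        gmin <- min(dh_scene[cand])
        req <- if (attach) 0.8 * fil_len[i] * ppm else 0.1 * ppm
        if (gmin < req + 0.5) next
      }
      bact <- bact | cand
      if (attach) {
        eps <- stamp_polyline(eps, gap_pts, params$filament_width * ppm / 2)
        filaments[[length(filaments) + 1L]] <-
          list(pts = gap_pts, length_um = fil_len[i],
               width_um = params$filament_width)
      }
      rods <- rbind(rods, data.frame(center_r = center[1L], center_c = center[2L],
                                     length_um = rod_len[i], width_um = rod_wid[i],
                                     angle = phi, attached = attach))
      placed <- TRUE
      break
    }
    if (!placed)
      warning(sprintf("could not place rod %d without overlap; scene is dense", i))
  }

  # ---- filler EPS strands up to the coverage target ----
  cell <- bact | hyph
  eps <- eps & !cell
  target_px <- params$target_eps_coverage / 100 * S * S
  eps_px <- sum(eps)
  strand_len_um <- c(2, 8)
  budget <- 200L + 5L * ceiling(target_px /
    max(1, mean(strand_len_um) * ppm * max(1, params$filament_width * ppm)))
  strands <- 0L
  while (eps_px < target_px && strands < budget) {
    len <- stats::runif(1L, strand_len_um[1L], strand_len_um[2L]) * ppm
    step <- 0.5 * ppm
    nst <- max(2L, ceiling(len / step))
    heading <- stats::runif(1L, 0, 2 * pi)
    pts <- matrix(NA_real_, nst + 1L, 2L)
    pts[1L, ] <- stats::runif(2L, 2, S - 2)
    for (k in seq_len(nst)) {
      heading <- heading + stats::rnorm(1L, 0, 0.35)
      pts[k + 1L, ] <- pts[k, ] + step * c(cos(heading), sin(heading))
    }
    # work in the strand's bounding window only
    hw <- params$filament_width * ppm / 2
    r1 <- max(1L, floor(min(pts[, 1L]) - hw - 2)); r2 <- min(S, ceiling(max(pts[, 1L]) + hw + 2))
    c1 <- max(1L, floor(min(pts[, 2L]) - hw - 2)); c2 <- min(S, ceiling(max(pts[, 2L]) + hw + 2))
    if (r1 > r2 || c1 > c2) { strands <- strands + 1L; next }
    sub <- stamp_polyline(array(FALSE, dim = c(r2 - r1 + 1L, c2 - c1 + 1L)),
                          sweep(pts, 2L, c(r1 - 1L, c1 - 1L)), hw)
    sub <- sub & !cell[r1:r2, c1:c2] & !eps[r1:r2, c1:c2]
    eps[r1:r2, c1:c2] <- eps[r1:r2, c1:c2] | sub
    eps_px <- eps_px + sum(sub)
    strands <- strands + 1L
  }
  truth_coverage <- 100 * eps_px / (S * S)
  if (truth_coverage < params$target_eps_coverage - params$coverage_tol)
    warning(sprintf(
      "placement budget exhausted: achieved EPS coverage %.2f%% (target %.2f%%)",
      truth_coverage, params$target_eps_coverage))

  # ---- truth masks (priority bacterium > hypha > eps) and rendering ----
  truth_bacteria <- bact
  truth_hyphae <- hyph & !bact
  truth_eps <- eps                      # already carved of cell overlap
  ints <- params$intensities
  img <- array(ints[["background"]], dim = dims)
  img[truth_eps] <- ints[["eps"]]
  img[truth_hyphae] <- ints[["hypha"]]
  img[truth_bacteria] <- ints[["bacterium"]]
  img <- gaussian_blur(img, params$blur_sigma)
  img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- dims
  rendered <- micrograph(img, name = params$name, scale = 1 / ppm)

  structure(list(rendered = rendered,
                 truth_hyphae = truth_hyphae,
                 truth_bacteria = truth_bacteria,
                 truth_eps = truth_eps,
                 geometry = list(hyphae = tubes, bacteria = rods,
                                 filaments = filaments),
                 truth_coverage = truth_coverage,
                 params = params),
            class = "synthetic_scene")
}

#' Write a synthetic scene to fixture files
#'
#' Writes the rendered micrograph as 16-bit TIFF, the three truth masks
#' as 8-bit PNG, updates (or creates) `calibration.json` in the output
#' directory, and writes a truth JSON with per-object dimensions in
#' microns and the exact coverage.
#'
#' @param scene A `synthetic_scene`.
#' @param out_dir Output directory, created if needed.
#' @return Named list of file paths, invisibly.
#' @export
scene_to_fixtures <- function(scene, out_dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- tools::file_path_sans_ext(scene$params$name)
  img_path <- file.path(out_dir, scene$params$name)
  write_micrograph(scene$rendered, img_path)
  masks <- list(hyphae = scene$truth_hyphae, bacteria = scene$truth_bacteria,
                eps = scene$truth_eps)
  mask_paths <- vapply(names(masks), function(nm) {
    p <- file.path(out_dir, sprintf("%s_truth_%s.png", stem, nm))
    png::writePNG(masks[[nm]] * 1.0, p)
    p
  }, character(1))
  calib_path <- file.path(out_dir, "calibration.json")
  calib <- if (file.exists(calib_path)) {
    sapply(jsonlite::read_json(calib_path), function(v) as.numeric(v[[1L]]))
  } else c()
  calib[[scene$params$name]] <- scene$params$pixels_per_micron
  calib <- as.list(calib[order(names(calib))])
  jsonlite::write_json(calib, calib_path, auto_unbox = TRUE, digits = NA)
  truth <- list(
    name = scene$params$name,
    pixels_per_micron = scene$params$pixels_per_micron,
    truth_coverage = scene$truth_coverage,
    hyphae = lapply(scene$geometry$hyphae, function(t) list(width_um = t$width_um)),
    bacteria = scene$geometry$bacteria[, c("length_um", "width_um", "attached",
                                           "center_r", "center_c")],
    filaments = lapply(scene$geometry$filaments, function(f)
      list(length_um = f$length_um, width_um = f$width_um,
           mid_r = f$pts[ceiling(nrow(f$pts) / 2), 1L],
           mid_c = f$pts[ceiling(nrow(f$pts) / 2), 2L]))
  )
  truth_path <- file.path(out_dir, sprintf("%s_truth.json", stem))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(image = img_path, masks = mask_paths,
                 calibration = calib_path, truth = truth_path))
}
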