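# Binary-mask primitives: 8-connected labeling, Euclidean distance
# transform (via EBImage::distmap), disc erosion/dilation/opening derived
# from the distance transform, and Zhang-Suen thinning. EBImage's own
# labeling is 4-connected, which would fragment diagonal one-pixel EPS
# filaments, so labeling is done here on an explicit 8-neighbor graph.

shift_mat <- function(m, dr, dc, fill = 0) {
  out <- array(fill, dim = dim(m))
  nr <- nrow(m); nc <- ncol(m)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Label connected components of a binary mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 for background, components numbered
#'   in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- array(0L, dim = dim(mask))
  if (length(fg) == 0L) return(lab)
  rank <- integer(nr * nc)
  rank[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  else if (connectivity != 4) stop("`connectivity` must be 4 or 8", call. = FALSE)
  edges <- integer(0)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- mask[j]
    if (any(ok2)) edges <- c(edges, rbind(rank[fg[ok]][ok2], rank[j][ok2]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in raster order of first occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  lab[fg] <- remap[memb]
  lab
}

#' Euclidean distance transform of a binary mask
#'
#' Distance from each foreground pixel to the nearest background pixel
#' (pixel-center metric); background pixels get 0.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances in pixels.
#' @export
mask_distance <- function(mask) {
  m <- EBImage::distmap(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)))
  matrix(as.numeric(m), nrow(mask), ncol(mask))
}

#' Disc erosion, dilation and opening of a binary mask
#'
#' Derived from the exact Euclidean distance transform: erosion keeps
#' pixels farther than `r` from the background, dilation adds background
#' pixels within `r` of the mask, opening is erosion then dilation. This
#' gives true disc structuring elements at any (non-integer) radius.
#'
#' @param mask Logical matrix.
#' @param r Disc radius in pixels.
#' @return Logical matrix.
#' @export
mask_erode <- function(mask, r) mask_distance(mask) > r

#' @rdname mask_erode
#' @export
mask_dilate <- function(mask, r) {
  mask <- mask > 0
  if (!any(mask)) return(mask)
  mask | (mask_distance(!mask) <= r)
}

#' @rdname mask_erode
#' @export
mask_open <- function(mask, r) {
  er <- mask_erode(mask, r)
  if (!any(er)) return(er)
  mask_dilate(er, r)
}

#' Fill small holes in a binary mask
#'
#' Background components (4-connected) that do not touch the image border
#' and are at most `max_px` pixels are set to foreground. Used to remove
#' pixel-noise holes before disc morphology, where a single false
#' background pixel would void a whole structuring disc under erosion.
#'
#' @param mask Logical matrix.
#' @param max_px Largest hole area to fill, pixels.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask, max_px) {
  mask <- mask > 0
  bg <- label_components(!mask, connectivity = 4)
  k <- max(bg)
  if (k == 0L) return(mask)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0L], k)
  fill <- setdiff(which(sizes <= max_px), border)
  mask | array(bg %in% fill, dim = dim(mask))
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels border pixels while preserving connectivity and line
#' ends, until stable. The result is a (mostly) one-pixel-wide 8-connected
#' medial line.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  p <- mask > 0
  if (!any(p)) return(p)
  neighbors <- function(p) {
    # clockwise from north: P2..P9 (first index is row/y, north = row - 1)
    list(P2 = shift_mat(p,  1L,  0L), P3 = shift_mat(p,  1L, -1L),
         P4 = shift_mat(p,  0L, -1L), P5 = shift_mat(p, -1L, -1L),
         P6 = shift_mat(p, -1L,  0L), P7 = shift_mat(p, -1L,  1L),
         P8 = shift_mat(p,  0L,  1L), P9 = shift_mat(p,  1L,  1L))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors(p)
      B <- Reduce(`+`, nb)
      seqn <- nb[c("P2","P3","P4","P5","P6","P7","P8","P9","P2")]
      A <- 0
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
      if (step == 1L) {
        c1 <- !(nb$P2 & nb$P4 & nb$P6)
        c2 <- !(nb$P4 & nb$P6 & nb$P8)
      } else {
        c1 <- !(nb$P2 & nb$P4 & nb$P8)
        c2 <- !(nb$P2 & nb$P6 & nb$P8)
      }
      del <- p & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        p <- p & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

#' Prune short skeleton branches
#'
#' Removes `n_iter` layers of endpoint pixels (pixels with at most one
#' 8-neighbor on the skeleton), deleting side spurs up to that length
#' while only shortening the main line at its ends. If pruning would
#' empty the skeleton the input is returned.
#'
#' @param skel Logical skeleton matrix.
#' @param n_iter Number of endpoint-removal passes.
#' @return Logical matrix.
#' @export
prune_skeleton <- function(skel, n_iter) {
  p <- skel > 0
  for (i in seq_len(n_iter)) {
    nb <- shift_mat(p, 1L, 0L) + shift_mat(p, -1L, 0L) +
      shift_mat(p, 0L, 1L) + shift_mat(p, 0L, -1L) +
      shift_mat(p, 1L, 1L) + shift_mat(p, 1L, -1L) +
      shift_mat(p, -1L, 1L) + shift_mat(p, -1L, -1L)
    ends <- p & nb <= 1
    if (!any(ends)) break
    q <- p & !ends
    if (!any(q)) return(skel > 0)
    p <- q
  }
  p
}

# shortest-path (geodesic) distance in pixels between two skeleton pixels,
# moving over 8-connected skeleton pixels with step costs 1 / sqrt(2)
skeleton_geodesic <- function(skel, from, to) {
  idx <- which(skel)
  if (length(idx) == 0L) return(NA_real_)
  nr <- nrow(skel)
  rank <- integer(length(skel))
  rank[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0); w <- numeric(0)
  for (o in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))) {
    r2 <- r + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- skel[j]
    if (any(ok2)) {
      edges <- c(edges, rbind(rank[idx[ok]][ok2], rank[j][ok2]))
      w <- c(w, rep.int(o[3L], sum(ok2)))
    }
  }
  if (rank[from] == 0L || rank[to] == 0L) return(NA_real_)
  if (from == to) return(0)
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  d <- igraph::distances(g, v = rank[from], to = rank[to], weights = w)
  as.numeric(d[1L, 1L])
}
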