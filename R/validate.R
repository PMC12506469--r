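# Scoring a pipeline run against the generator's ground truth.

match_nearest <- function(truth_rc, rec_rc, tol_px) {
  # greedy nearest matching, each recovered object used at most once
  m <- rep(NA_integer_, nrow(truth_rc))
  if (nrow(rec_rc) == 0L) return(m)
  used <- rep(FALSE, nrow(rec_rc))
  for (i in seq_len(nrow(truth_rc))) {
    d <- sqrt((rec_rc[, 1L] - truth_rc[i, 1L])^2 +
              (rec_rc[, 2L] - truth_rc[i, 2L])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_px) {
      m[i] <- j
      used[j] <- TRUE
    }
  }
  m
}

#' Score an analysis of a synthetic scene against its ground truth
#'
#' Matches recovered bacteria and attachment structures to the truth
#' geometry by proximity and tabulates per-object measurement errors,
#' plus coverage and hyphal-width recovery. Excluded (border/deformed)
#' recovered objects and truth rods whose match was excluded are omitted
#' from the measurement comparisons.
#'
#' @param scene A `synthetic_scene`.
#' @param analysis The result of [analyze_micrograph()] on
#'   `scene$rendered`.
#' @param match_tol_um Matching radius for object centers, um.
#' @return List: `coverage` (truth, recovered, error in percentage
#'   points), `rods` (data frame truth vs recovered length/width, um),
#'   `hyphae` (truth mean and recovered mean width, um), `filaments`
#'   (data frame truth vs recovered geodesic length with `detected`
#'   flag).
#' @export
score_scene <- function(scene, analysis, match_tol_um = 1.0) {
  stopifnot(inherits(scene, "synthetic_scene"))
  scale <- scene$rendered$scale
  tol_px <- match_tol_um / scale
  obj <- analysis$objects

  rods_t <- scene$geometry$bacteria
  rec_b <- obj[obj$class == "bacterium" & !obj$excluded, , drop = FALSE]
  m <- match_nearest(cbind(rods_t$center_r, rods_t$center_c),
                     cbind(rec_b$centroid_r, rec_b$centroid_c), tol_px)
  rods <- data.frame(truth_length = rods_t$length_um,
                     truth_width = rods_t$width_um,
                     rec_length = rec_b$length_um[m],
                     rec_width = rec_b$width_um[m])

  hy_t <- vapply(scene$geometry$hyphae, function(t) t$width_um, numeric(1))
  rec_h <- obj[obj$class == "hypha" & !obj$excluded, , drop = FALSE]
  hyphae <- c(truth_mean = if (length(hy_t)) mean(hy_t) else NA_real_,
              rec_mean = if (nrow(rec_h)) mean(rec_h$width_um) else NA_real_)

  # attachments belong to bacteria (one per attached rod): match each
  # truth filament through its rod, by the bacterium-side anchor of the
  # recovered path
  fil_t <- scene$geometry$filaments
  rec_a <- obj[obj$class == "attachment", , drop = FALSE]
  if (length(fil_t)) {
    att_rods <- rods_t[rods_t$attached, , drop = FALSE]
    reach <- att_rods$length_um / 2 / scale + 4
    m_f <- match_nearest(cbind(att_rods$center_r, att_rods$center_c),
                         cbind(rec_a$anchor_r, rec_a$anchor_c), max(reach))
    ok <- !is.na(m_f)
    d_anchor <- sqrt((rec_a$anchor_r[m_f] - att_rods$center_r)^2 +
                     (rec_a$anchor_c[m_f] - att_rods$center_c)^2)
    ok[ok] <- d_anchor[ok] <= reach[ok]
    filaments <- data.frame(truth_length = vapply(fil_t, `[[`, numeric(1), "length_um"),
                            rec_length = ifelse(ok, rec_a$length_um[m_f], NA_real_),
                            detected = ok)
  } else {
    filaments <- data.frame(truth_length = numeric(0), rec_length = numeric(0),
                            detected = logical(0))
  }

  list(coverage = c(truth = scene$truth_coverage,
                    recovered = analysis$area$P_v,
                    error = analysis$area$P_v - scene$truth_coverage),
       rods = rods, hyphae = hyphae, filaments = filaments)
}
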