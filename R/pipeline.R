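# Orchestration of the full analysis chain:
# grayscale -> multi-scale ridge response -> biofilm threshold ->
# component classification -> area report + object morphometry ->
# exclusion -> summaries.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default. The scale
#' sweep `[1, 50]` px with 10 geometric steps covers structures from
#' sub-pixel EPS filaments to the widest hyphae; `alpha`, `tau` and the
#' polarity parameterize the ridge condition (see [ridge_params()]);
#' class bounds are in microns (see [morph_class_bounds()]).
#'
#' @param sigma_min,sigma_max,n_scales Scale sweep (px).
#' @param alpha,tau,polarity Ridge condition parameters.
#' @param threshold_method `"otsu"` or `"manual"`.
#' @param manual_threshold Threshold when `threshold_method = "manual"`.
#' @param hypha_min_width,hypha_max_width,bact_length_range,bact_width_range,elongation_min,solidity_min,min_object_px
#'   Classification bounds, passed to [morph_class_bounds()].
#' @param brightness_gate Gate the EPS class on the lower intensity
#'   threshold (see [classify_components()]).
#' @param sd_ddof Degrees-of-freedom correction used in summaries.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(sigma_min = 1, sigma_max = 50, n_scales = 10,
                            alpha = 0.25, tau = 0,
                            polarity = c("bright", "dark"),
                            threshold_method = c("otsu", "manual"),
                            manual_threshold = NULL,
                            hypha_min_width = 1.5,
                            hypha_max_width = 5,
                            bact_length_range = c(0.25, 3.0),
                            bact_width_range = c(0.2, 1.0),
                            elongation_min = 3,
                            solidity_min = 0.8,
                            min_object_px = 10L,
                            brightness_gate = TRUE,
                            sd_ddof = 0L) {
  polarity <- match.arg(polarity)
  threshold_method <- match.arg(threshold_method)
  structure(as.list(environment()), class = "analysis_config")
}

config_bounds <- function(config) {
  morph_class_bounds(hypha_min_width = config$hypha_min_width,
                     hypha_max_width = config$hypha_max_width,
                     bact_length_range = config$bact_length_range,
                     bact_width_range = config$bact_width_range,
                     elongation_min = config$elongation_min,
                     solidity_min = config$solidity_min,
                     min_object_px = config$min_object_px)
}

component_bbox <- function(mask) {
  bb <- which(mask, arr.ind = TRUE)
  c(min_row = min(bb[, 1L]), max_row = max(bb[, 1L]),
    min_col = min(bb[, 2L]), max_col = max(bb[, 2L]),
    centroid_r = mean(bb[, 1L]), centroid_c = mean(bb[, 2L]))
}

#' Analyze one calibrated micrograph
#'
#' Runs the full chain on a single image and returns the area report
#' (computed on the residual EPS/biofilm mask), the per-object measure
#' table with exclusions applied, and the intermediate products.
#'
#' @param img Calibrated [micrograph()].
#' @param config An [analysis_config()].
#' @return List with elements `area` (an [area_report()]), `objects`
#'   (data frame), `labels` (a `component_labels`), `biofilm`
#'   (the thresholded `biofilm_mask`), `response` (the multi-scale
#'   `ridge_response`), `config`.
#' @export
analyze_micrograph <- function(img, config = analysis_config()) {
  stopifnot(inherits(img, "micrograph"), inherits(config, "analysis_config"))
  if (is.null(img$scale)) stop("micrograph is uncalibrated", call. = FALSE)
  rp <- ridge_params(config$alpha, config$tau, config$polarity)
  resp <- multiscale_response(img, config$sigma_min, config$sigma_max,
                              config$n_scales, rp)
  bio <- threshold_biofilm(resp, config$threshold_method, config$manual_threshold)
  labels <- classify_components(img, bio, config_bounds(config),
                                brightness_gate = config$brightness_gate)
  area <- area_report(labels$eps, img)

  rows <- list()
  cls <- labels$classes
  for (i in seq_len(nrow(cls))) {
    if (!cls$class[i] %in% c("hypha", "bacterium")) next
    comp <- labels$labels == cls$label[i]
    bb <- component_bbox(comp)
    if (cls$class[i] == "hypha") {
      wid <- suppressWarnings(measure_tube_width(
        comp, img$scale, estimator = "modes", edge = "center",
        max_width_um = config$hypha_max_width))
      len <- max(moment_axes_px(comp)) * img$scale
      sol <- NA_real_
    } else {
      m <- measure_rod(comp, img$scale)
      len <- m[["length"]]; wid <- m[["width"]]
      sol <- component_solidity(comp)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = img$name, label = cls$label[i], class = cls$class[i],
      length_um = max(len, wid), width_um = min(len, wid), solidity = sol,
      t(bb), anchor_r = NA_real_, anchor_c = NA_real_,
      stringsAsFactors = FALSE)
  }
  # the EPS mask hugs the cells through a thin mid-brightness rim at the
  # blurred cell edges; pull it back one pixel so individual attachment
  # filaments are separate components, and widen the adjacency tolerance
  # to compensate
  cells <- labels$hyphae | labels$bacteria
  eps_core <- labels$eps_band & !mask_dilate(cells, 1)
  att <- measure_attachments(eps_core, labels$bacteria, labels$hyphae,
                             img$scale, adjacency_tol = 3.6)
  if (nrow(att) > 0L) {
    for (i in seq_len(nrow(att))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = img$name, label = NA_integer_, class = "attachment",
        length_um = att$length_um[i], width_um = att$width_um[i],
        solidity = NA_real_, min_row = att$min_row[i], max_row = att$max_row[i],
        min_col = att$min_col[i], max_col = att$max_col[i],
        centroid_r = att$centroid_r[i], centroid_c = att$centroid_c[i],
        anchor_r = att$anchor_r[i], anchor_c = att$anchor_c[i],
        stringsAsFactors = FALSE)
    }
  }
  objects <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sample_id = character(0), label = integer(0),
                  class = character(0), length_um = numeric(0),
                  width_um = numeric(0), solidity = numeric(0),
                  min_row = integer(0), max_row = integer(0),
                  min_col = integer(0), max_col = integer(0),
                  centroid_r = numeric(0), centroid_c = numeric(0),
                  anchor_r = numeric(0), anchor_c = numeric(0),
                  stringsAsFactors = FALSE)
  objects <- exclusion_filter(objects, dim(img$pixels), config$solidity_min)
  rownames(objects) <- NULL
  list(area = area, objects = objects, labels = labels, biofilm = bio,
       response = resp, config = config)
}

analysis_images <- function(input_dir) {
  f <- list.files(input_dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  f <- f[!grepl("_truth_|_mask|_labels", f)]
  sort(f)
}

#' Analyze a directory of micrographs
#'
#' Loads every TIFF/PNG in `input_dir` (truth masks and outputs are
#' skipped), analyzes each against the calibration file, optionally
#' writes per-image outputs (object CSV, EPS mask PNG) and a summary
#' JSON, and returns the collected results. Per-image failures are
#' recorded and skipped, not fatal.
#'
#' @param input_dir Directory of images.
#' @param calibration_file Path to the calibration JSON.
#' @param config An [analysis_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `areas` (data frame per image), `objects` (combined
#'   data frame), `summary` (from [summarize_measures()]), `failures`
#'   (named character), `config`.
#' @export
analyze_directory <- function(input_dir, calibration_file,
                              config = analysis_config(), out_dir = NULL) {
  calib <- read_calibration(calibration_file)
  files <- analysis_images(input_dir)
  if (length(files) == 0L) stop("no readable images in ", input_dir, call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  areas <- list(); objects <- list(); failures <- character(0)
  for (f in files) {
    res <- tryCatch({
      img <- load_micrograph(file.path(input_dir, f), calib)
      analyze_micrograph(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[f] <- conditionMessage(res)
      next
    }
    areas[[f]] <- data.frame(sample_id = f, A_v = res$area$A_v,
                             A_t = res$area$A_t, P_v = res$area$P_v,
                             vessel_pixels = res$area$vessel_pixels,
                             stringsAsFactors = FALSE)
    objects[[f]] <- res$objects
    if (!is.null(out_dir)) {
      stem <- tools::file_path_sans_ext(f)
      utils::write.csv(res$objects,
                       file.path(out_dir, sprintf("%s_objects.csv", stem)),
                       row.names = FALSE)
      png::writePNG(res$labels$eps * 1.0,
                    file.path(out_dir, sprintf("%s_eps_mask.png", stem)))
    }
  }
  areas <- do.call(rbind, areas); rownames(areas) <- NULL
  objects <- do.call(rbind, objects); rownames(objects) <- NULL
  summ <- summarize_measures(objects, sd_ddof = config$sd_ddof)
  out <- list(areas = areas, objects = objects, summary = summ,
              failures = failures, config = config)
  if (!is.null(out_dir)) {
    json <- list(
      config = config[setdiff(names(config), "manual_threshold")],
      areas = areas,
      per_sample = summ$per_sample,
      pooled = summ$pooled,
      pooled_coverage = list(mean = mean(areas$P_v),
                             sd = pop_sd(areas$P_v, config$sd_ddof),
                             n = nrow(areas)),
      failures = as.list(failures))
    jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         pretty = TRUE)
  }
  out
}

#' Pool per-object CSV tables into a summary
#'
#' @param csv_paths Paths to per-object CSV files written by
#'   [analyze_directory()].
#' @param sd_ddof Degrees-of-freedom correction for the SD.
#' @return As [summarize_measures()].
#' @export
summarize_samples <- function(csv_paths, sd_ddof = 0L) {
  need <- c("sample_id", "class", "length_um", "width_um", "excluded")
  tabs <- lapply(csv_paths, function(p) {
    d <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed CSV '", p, "': ",
                                           conditionMessage(e), call. = FALSE))
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("malformed CSV '", p, "': missing columns ",
           paste(miss, collapse = ", "), call. = FALSE)
    d
  })
  summarize_measures(do.call(rbind, tabs), sd_ddof = sd_ddof)
}
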