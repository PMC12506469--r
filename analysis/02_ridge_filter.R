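#!/usr/bin/env Rscript
# The processing chain on one micrograph, panel by panel: original image,
# single-scale Sato response (sigma = 1), multi-scale response
# (sigma = [1, 50]), and the segmentation of biofilm components from the
# fungal and bacterial structures. Run 01_generate_scenes.R first.

suppressPackageStartupMessages(library(epsquant))

fix_dir <- "results/fixtures"
out_dir <- "results/figures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

calib <- read_calibration(file.path(fix_dir, "calibration.json"))
name <- names(calib)[1L]
img <- load_micrograph(file.path(fix_dir, name), calib)
message("image: ", name, " (", nrow(img$pixels), " x ", ncol(img$pixels),
        " px, ", signif(1 / img$scale, 3), " px/um)")

write_panel <- function(m, file) {
  rng <- range(m)
  if (rng[2] > rng[1]) m <- (m - rng[1]) / (rng[2] - rng[1])
  png::writePNG(m, file.path(out_dir, file))
}

write_panel(img$pixels, "panel_a_original.png")

single <- sato_response(hessian_eigenvalues(compute_hessian(img, 1)))
write_panel(single$R, "panel_b_sato_sigma1.png")
message(sprintf("single-scale response: %.1f%% of pixels pass the ridge condition",
                100 * mean(single$R > 0)))

multi <- multiscale_response(img)
write_panel(multi$R, "panel_c_sato_multiscale.png")

bio <- threshold_biofilm(multi)
labels <- classify_components(img, bio)
message(sprintf("threshold %.4g: %d vessel pixels", bio$threshold,
                bio$vessel_pixels))
seg <- array(0, dim = dim(img$pixels))
seg[labels$hyphae] <- 0.4
seg[labels$bacteria] <- 0.7
seg[labels$eps] <- 1
write_panel(seg, "panel_d_segmentation.png")

rep <- area_report(labels$eps, img)
message(sprintf("biofilm: A_v = %.2f um^2 of A_t = %.1f um^2 -> P_v = %.2f%%",
                rep$A_v, rep$A_t, rep$P_v))
message("panels written to ", out_dir)
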