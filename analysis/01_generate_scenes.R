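#!/usr/bin/env Rscript
# Generate a triplicate-like set of synthetic coculture micrographs with
# ground truth, standing in for the SEM image set (the real micrographs
# are not publicly deposited). Three scenes at the default study
# conditions: rods 1.4 x 0.5 um, hyphae 3.0 +/- 0.5 um, attachment
# filaments 0.3 +/- 0.1 um, EPS coverage target 18.33 %.

suppressPackageStartupMessages(library(epsquant))

out_dir <- "results/fixtures"
seeds <- c(101L, 102L, 103L)

for (s in seeds) {
  params <- scene_params(size = 512L, seed = s)
  scene <- generate_scene(params)
  files <- scene_to_fixtures(scene, out_dir)
  message(sprintf("seed %d: %s  truth coverage %.2f%%, %d rods, %d filaments",
                  s, basename(files$image), scene$truth_coverage,
                  nrow(scene$geometry$bacteria),
                  length(scene$geometry$filaments)))
}
message("fixtures written to ", out_dir)
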