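#!/usr/bin/env Rscript
# Simulate the imaging experiment: synthetic confocal-like images of
# layer-5 pyramidal somata ringed by GAD+ puncta, for an MS-like group
# (planted coverage 0.299 puncta/um^2, soma 403 um^2) and a control-like
# group (0.348, 531 um^2), plus one example of each QC defect.
# Writes a sample of TIFFs plus the full planted ground truth to results/.

suppressPackageStartupMessages(library(synapcover))

out_dir <- "results/images"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260930L

groups <- list(
  MS      = list(n_cases = 10, coverage = 0.299, soma = 403, offset = 0L),
  control = list(n_cases = 7,  coverage = 0.348, soma = 531, offset = 500L))

truth_rows <- list()
for (g in names(groups)) {
  cfg <- groups[[g]]
  renders <- simulate_case_images(
    n_cases = cfg$n_cases, neurons_per_case = 30,
    coverage_mean = cfg$coverage, soma_area_mean = cfg$soma,
    pixel_size = 0.2, seed = seed + cfg$offset,
    case_prefix = paste0(g, "_"))
  for (r in renders)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      group = g, case_id = r$image$case_id, image_id = r$image$image_id,
      soma_area_um2 = r$truth$soma_area_um2,
      raster_area_um2 = r$truth$raster_area_um2,
      n_membrane_puncta = r$truth$n_membrane_puncta,
      planted_coverage = r$truth$planted_coverage,
      intensity_scale = r$truth$intensity_scale,
      degenerate_kind = r$truth$degenerate_kind)
  # keep a handful of TIFFs on disk as visual/format examples
  for (r in renders[1:2])
    write_image_stack(r$image,
                      file.path(out_dir, paste0(r$image$image_id, ".tif")))
  saveRDS(renders, file.path("results", paste0("renders_", g, ".rds")))
}

for (k in c("poor_contrast", "multi_process", "two_neurons",
            "incorrect_neuron")) {
  d <- render_degenerate_image(k, seed = seed + 900L)
  d$image$image_id <- paste0("defect_", k)
  write_image_stack(d$image, file.path(out_dir, paste0("defect_", k, ".tif")))
  truth_rows[[length(truth_rows) + 1L]] <- data.frame(
    group = "qc_defect", case_id = "defect", image_id = d$image$image_id,
    soma_area_um2 = d$truth$soma_area_um2,
    raster_area_um2 = d$truth$raster_area_um2,
    n_membrane_puncta = d$truth$n_membrane_puncta,
    planted_coverage = d$truth$planted_coverage,
    intensity_scale = d$truth$intensity_scale,
    degenerate_kind = d$truth$degenerate_kind)
}

truth <- do.call(rbind, truth_rows)
write.csv(truth, "results/ground_truth.csv", row.names = FALSE)

cat(sprintf("rendered %d neurons (%d MS-like, %d control-like) + 4 QC defects\n",
            sum(truth$group != "qc_defect"),
            sum(truth$group == "MS"), sum(truth$group == "control")))
cat(sprintf("planted coverage means: MS %.3f, control %.3f puncta/um^2\n",
            mean(truth$planted_coverage[truth$group == "MS"]),
            mean(truth$planted_coverage[truth$group == "control"])))
cat("ground truth written to results/ground_truth.csv\n")
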