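#!/usr/bin/env Rscript
# Quantify the simulated imaging experiment: normalize, segment the soma,
# detect GAD+ puncta, compute C' = N_s/A(d) and neuron size per neuron,
# apply QC, aggregate per case, and contrast the groups.
# Requires 01_simulate_images.R to have produced results/renders_*.rds.

suppressPackageStartupMessages(library(synapcover))

per_neuron <- list()
for (g in c("MS", "control")) {
  renders <- readRDS(file.path("results", paste0("renders_", g, ".rds")))
  rows <- do.call(rbind, lapply(renders, function(r)
    process_image(r$image)))
  rows$group <- g
  per_neuron[[g]] <- rows
}
per_neuron <- do.call(rbind, per_neuron)
write.csv(per_neuron, "results/per_neuron.csv", row.names = FALSE)

qc <- summarize_qc(per_neuron)
print(qc)

per_case <- aggregate_case(per_neuron)
per_case$group <- per_neuron$group[match(per_case$case_id,
                                         per_neuron$case_id)]
write.csv(per_case, "results/per_case.csv", row.names = FALSE)

contrast <- group_contrast(per_case, "mean_coverage", "control", "MS",
                           covariates = NULL)
print(contrast)
size_contrast <- group_contrast(per_case, "mean_neuron_size", "control",
                                "MS", covariates = NULL)
print(size_contrast)

truth <- read.csv("results/ground_truth.csv")
truth_means <- tapply(truth$planted_coverage[truth$group != "qc_defect"],
                      truth$group[truth$group != "qc_defect"], mean)
cat(sprintf("planted reduction %.1f%%, recovered %.1f%%\n",
            100 * (1 - truth_means[["MS"]] / truth_means[["control"]]),
            contrast$percent_difference))
write.csv(
  data.frame(outcome = c("mean_coverage", "mean_neuron_size"),
             mean_control = c(contrast$mean_a, size_contrast$mean_a),
             mean_ms = c(contrast$mean_b, size_contrast$mean_b),
             percent_difference = c(contrast$percent_difference,
                                    size_contrast$percent_difference),
             p = c(contrast$adjusted_p, size_contrast$adjusted_p)),
  "results/group_contrasts.csv", row.names = FALSE)
cat("wrote results/per_neuron.csv, per_case.csv, group_contrasts.csv\n")
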