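#!/usr/bin/env Rscript
# DAB immunohistochemistry pixel extraction: render brightfield-like RGB
# fields with known DAB-positive fractions and recover them by colour
# deconvolution, reporting expression in millions of pixels/mm^2.

suppressPackageStartupMessages(library(synapcover))
dir.create("results", showWarnings = FALSE)

fracs <- c(0, 0.05, 0.10, 0.25, 0.50, 1)
rows <- do.call(rbind, lapply(seq_along(fracs), function(i) {
  r <- render_dab_image(fracs[i], area_mm2 = 0.01, pixel_size = 0.2,
                        seed = 600 + i)
  q <- quantify_dab(r$image, assessed_area_mm2 = 0.01)
  data.frame(planted_fraction = fracs[i],
             planted_positive = r$truth$n_positive_pixels,
             recovered_positive = q$positive_pixels,
             expression_mpx_mm2 = q$expression)
}))
rows$rel_error <- ifelse(rows$planted_positive > 0,
                         abs(rows$recovered_positive -
                               rows$planted_positive) /
                           rows$planted_positive, 0)
write.csv(rows, "results/dab_recovery.csv", row.names = FALSE)
print(rows, digits = 4)
cat(sprintf("max relative error on non-empty fields: %.3f%%\n",
            100 * max(rows$rel_error)))
cat("wrote results/dab_recovery.csv\n")
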