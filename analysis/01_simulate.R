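#!/usr/bin/env Rscript
# Step 1 — simulate the experiment.
#
# Generates the full synthetic nitrogen-deprivation run: 30 genotypes, three
# treatments (100/100, 50/10, 10/10 ammonium/nitrate) with 9/9/6 replicate
# plants, imaged daily on days 8-26. Writes the long trait table, per-plant
# hue histograms, the day-26 leaf ionome and the ground-truth labels, plus a
# pair of example rendered images (plant + mask) in plain-text PNM.

suppressMessages(library(phenokinetics))

seed <- 1L
outdir <- "results/01_simulate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- experiment_config(seed = seed)
print(cfg)
exp <- generate_experiment(cfg)

write_trait_table(exp$traits, file.path(outdir, "traits.csv"))
data.table::fwrite(exp$histograms, file.path(outdir, "hues.csv"))
data.table::fwrite(exp$ionome, file.path(outdir, "ionome.csv"))
data.table::fwrite(exp$truth$labels, file.path(outdir, "truth_labels.csv"))
data.table::fwrite(exp$truth$yellow, file.path(outdir, "truth_yellow.csv"))

# one early-stress and one control example image on the yellowing peak day
for (tr in c("100-100", "10-10")) {
  row <- exp$traits[grepl(paste0("^G01_", tr), plant_id) & day == 13][1]
  yf <- exp$truth$yellow[plant_id == row$plant_id & day == 13]$yellow_fraction
  img <- render_plant_image(min(round(row$area), 9000), yf,
                            canvas_size = c(120L, 120L), seed = seed)
  write_pnm(img$image, file.path(outdir, sprintf("example_%s_day13.ppm", tr)))
  write_pnm(img$mask * 1, file.path(outdir, sprintf("example_%s_day13_mask.pgm", tr)),
            maxval = 1)
}

cat(sprintf("wrote %d trait records for %d plants (%d genotypes) to %s\n",
            nrow(exp$traits), length(unique(exp$traits$plant_id)),
            length(cfg$genotypes), outdir))
cat(sprintf("ground truth: %d early-, %d late-responding genotypes\n",
            sum(cfg$growth$label == "early"), sum(cfg$growth$label == "late")))
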