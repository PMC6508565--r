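#!/usr/bin/env Rscript
# Step 5 — response timing.
#
# For every genotype and day, the QC-filtered areas of the 100/100 and 10/10
# treatments are compared by one-way ANOVA; the p-values get one global BH
# correction and the -log10 q profiles are clustered (Canberra distance,
# Ward's minimum variance) to split the panel into early and late responders.
# Genotypes are also ranked by day-26 size and by growth rate (days 10-22)
# in the low-nitrogen group.

suppressMessages(library(phenokinetics))

outdir <- "results/05_timing"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

traits <- read_trait_table("results/03_qc/traits_filtered.csv")
truth <- data.table::fread("results/01_simulate/truth_labels.csv")

qm <- qvalue_matrix(traits, pair = c("100/100", "10/10"))
print(qm)
data.table::fwrite(data.table::data.table(genotype = qm$genotypes, qm$q),
                   file.path(outdir, "qmatrix.csv"))

hc <- ward_dendrogram(canberra_matrix(qm$neglog_q))
jsonlite::write_json(list(merge = hc$merge, height = hc$height,
                          order = hc$order, labels = hc$labels),
                     file.path(outdir, "dendrogram.json"), digits = NA)

labels <- split_early_late(hc, qm, k = 2, alpha = 0.05)
data.table::fwrite(labels, file.path(outdir, "responder_labels.csv"))
m <- merge(labels, truth, by = "genotype")
cat(sprintf("early/late classification: %d early, %d late; accuracy vs ground truth %.2f\n",
            sum(labels$label == "early"), sum(labels$label == "late"),
            mean(m$label.x == m$label.y)))

rates <- growth_rate(traits, window = c(10, 22), treatment = "10/10")
data.table::fwrite(rates, file.path(outdir, "growth_rates_10_10.csv"))
top <- rates[order(-rate)][1:3]
cat("fastest growers under 10/10 (px/day):",
    paste(sprintf("%s (%.0f)", top$genotype, top$rate), collapse = ", "), "\n")

ends <- end_size_outperformers(traits, day = 26, treatment = "10/10", star_q = 0.01)
data.table::fwrite(ends, file.path(outdir, "end_size_10_10.csv"))
cat(sprintf("day-26 size: %d genotype(s) starred at q < 0.01\n", sum(ends$starred)))
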