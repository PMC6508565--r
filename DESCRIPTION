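Package: phenokinetics
Title: Temporal Genotype-by-Environment Analysis of Plant Stress Phenotyping Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput plant phenotyping experiments that
    track abiotic-stress responses over time. Extracts 16 shape features and per-degree
    hue histograms from masked plant images, removes influential image records with a
    Cook's distance rule, quantifies colour-based stress kinetics as trapezoidal areas
    under yellow (0-60 degrees) and green (61-120 degrees) hue bands, classifies
    genotypes into early and late responders from daily treatment-significance q-value
    profiles (Benjamini-Hochberg FDR, Canberra distance, Ward clustering), and
    partitions ionomic variance into genotype, treatment and interaction components
    (type III sums of squares). A seeded synthetic-experiment generator emulates the
    full design (30 genotypes, three nitrogen treatments, daily imaging) with known
    ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    data.table,
    jsonlite,
    lme4,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
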