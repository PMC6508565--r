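# phenokinetics

Temporal genotype-by-environment (G×E) analysis of plant abiotic-stress
phenotyping experiments.

High-throughput phenotyping platforms photograph a genotype panel daily while
the plants grow under contrasting environments — the design emulated here is a
nitrogen-deprivation experiment: 30 genotypes × 3 ammonium/nitrate treatments
("100/100", "50/10", "10/10") with 9/9/6 replicate plants, imaged on days
8–26, with a leaf ionome (18 elements, ppm) sampled at the end. The package
turns that stream of masked plant images (or pre-extracted trait tables) into
quantitative stress phenotypes:

* **Shape** — 16 features per mask (area, hull area, solidity, perimeter,
  width, height, longest axis, centre of mass x/y, hull vertices, equivalent
  ellipse centre/axes/angle/eccentricity).
* **Colour** — per-degree hue histograms, normalized by mask size; the
  colour-stress index is the trapezoidal area under the histogram in the
  yellow (0–60°) and green (61–120°) bands,
  `AUC = Σ_d (f(d) + f(d+1)) / 2`, tracked per group over days.
* **QC** — Cook's distance on the genotype × treatment × day cell-means
  model, removing records with influence > 4 × mean influence; MAD-based
  replicate filtering (|x − median| / MAD > 6.2) for the ionome.
* **Responder timing** — per (genotype, day) one-way ANOVA between
  treatments, one global Benjamini–Hochberg FDR correction, −log10(q)
  profiles clustered by Canberra distance + Ward's minimum variance, k = 2
  cut → early vs late responding genotypes.
* **Variance partitioning** — mixed-model type III Wald chi-square ANOVA of
  area (fixed G, E, G×E, G×T, E×T, G×E×T; per-plant random intercept +
  slope over day), per-element type III SS / total SS fractions
  (genotype / treatment / interaction / residual), and PCAs with 95%
  treatment ellipses.
* **Synthetic experiments** — a seeded generator producing trait tables,
  hue histograms, rendered images and ionome tables with known ground truth
  (logistic growth with treatment onset days, two-peak hue mixtures,
  exact ionomic variance fractions, injected outliers).

## Worked example

```r
library(phenokinetics)

cfg <- experiment_config(seed = 1)      # 30 genotypes, 9/9/6 reps, days 8-26
exp <- generate_experiment(cfg)

qc  <- flag_influence_outliers(exp$traits)
qm  <- qvalue_matrix(qc$traits, pair = c("100/100", "10/10"))
lab <- split_early_late(ward_dendrogram(canberra_matrix(qm$neglog_q)), qm)
table(lab$label)
auc <- auc_time_series(exp$histograms)
subset(auc$series, group == "10/10")[which.max(
  subset(auc$series, group == "10/10")$yellow_auc), c("day", "yellow_auc")]
```

Running the numbered pipeline scripts reproduces the whole analysis and
prints, with seed 1:

```
influence filter: removed 640 of 13680 records (4.68%)
early/late classification: 15 early, 15 late; accuracy vs ground truth 1.00
10/10 yellow AUC peaks on day 13 (0.573)
ionome partitions: max |fraction - configured| = 0.041 over 18 elements
most genotype-driven elements: Mo, Co, Zn
most treatment-driven elements: P, Mg, Rb
```

i.e. the QC rule removes ~5% of image records; the q-value dendrogram
recovers the generator's 15 early and 15 late responders exactly; leaf
yellowing under severe nitrogen deprivation peaks mid-experiment (day 13);
and the ionomic partition returns the configured variance structure, with
trace metals genotype-driven and phosphorus the most treatment-responsive
element.

## Analysis workflow

The `analysis/` scripts are thin drivers over the package, writing their
tables under `results/`:

| script | stage |
|---|---|
| `analysis/01_simulate.R` | generate the synthetic experiment (tables, images, ground truth) |
| `analysis/02_extract_features.R` | segment rendered images; 16 shape features + hue histograms |
| `analysis/03_qc_outliers.R` | influence filter on traits; MAD filter on the ionome |
| `analysis/04_color_kinetics.R` | mean histograms, yellow/green AUC series, difference histograms, daily Welch tests |
| `analysis/05_response_timing.R` | q-value matrix, dendrogram, early/late labels, growth rates, end-size stars |
| `analysis/06_variance_partition.R` | mixed-model Wald ANOVA, per-element partitions, PCAs |

`run_pipeline(run_config(seed = 1))` runs the same chain in one call and
writes a JSON manifest (row counts, removal fractions, file hashes).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end to end on a fresh synthetic experiment
(simulate → QC → colour → timing → variance), writes every stage's tables
and manifest under `results/`, and emits the JSON report at `--out`.

## Layout

```
R/                  implementation (one file per module)
analysis/           numbered workflow scripts
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
```
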