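---
title: "Methods: temporal G-by-E analysis of plant stress phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal G-by-E analysis of plant stress phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-throughput phenotyping platforms photograph every plant of a genotype
panel daily while the plants grow under contrasting environments — here a
nitrogen-deprivation design with three ammonium/nitrate treatments
("100/100", "50/10", "10/10") applied to a 30-genotype panel with 9/9/6
replicate plants per genotype, imaged on days 8–26 after planting. The
analysis has to answer genotype-by-environment (G×E) questions from three
readouts: plant size (projected area as a biomass proxy), leaf colour (the
hue distribution of the plant mask), and the leaf ionome (element
concentrations in ppm) sampled at the end of the experiment.

`phenokinetics` implements the full chain: image parameterization, influence
-based quality control, colour stress kinetics, responder-timing
classification, and variance partitioning, plus a synthetic-experiment
generator with known ground truth so that every stage can be validated
without the (multi-gigabyte) raw image set.

# Image parameterization

`extract_shape_features()` reduces a binary plant mask to the 16 standard
shape descriptors: area, hull area, solidity, perimeter, width, height,
longest axis, centre of mass (x, y), hull vertex count, and the
moment-equivalent ellipse (centre, major/minor axis, angle, eccentricity).
Conventions that fix the numbers exactly:

* Coordinates are 0-based pixel centres, origin top-left, x rightward,
  y downward.
* The convex hull is taken over the four *corner* points of every foreground
  pixel. With a pixel-centre hull a filled convex region would have hull area
  smaller than its pixel count (a 10×10 square: 81 vs 100), breaking the
  defining property solidity = area / hull area ≤ 1; corner-point hulls give
  solidity exactly 1 for filled convex shapes and hull_area ≥ area always.
* Perimeter is the crack perimeter — the number of unit pixel edges between
  foreground and background — which is deterministic and exactly preserved
  under 90° rotation.
* The longest axis is the maximum pairwise distance between hull vertices.
* The equivalent ellipse comes from the second central moments of the pixel
  centres; the angle is the major-axis orientation in [0°, 180°).

`extract_hue_histogram()` counts foreground pixels per hue degree (0–359).
Hue is the angular coordinate of HSV colour space: red 0°, yellow 60°, green
120°. Although 8-bit imagery stores hue as 0–255 codes, the analysis is
defined on degrees; storage codes must be converted explicitly. Pixels with
zero saturation or zero value have no defined hue: they are excluded from
the bins but kept in the mask-pixel count, so after
`normalize_histogram()` the bins are fractions *of the whole mask* and sum
to at most 1. `rebin_hue()` sums the 360 bins into 2° bins (180 dimensions)
for colour PCA; mass is conserved exactly.

# Quality control

**Influence filter.** Image failures (dropped leaves, occlusions, tracking
errors) corrupt single records. Each record's Cook's distance is computed
under a cell-means linear model whose only term is the genotype × treatment
× day interaction; under that coding the leverage of a record in a cell of
n replicates is 1/n and the influence has a closed form identical to the
leave-one-out definition (tested against a brute-force refit oracle to
1e-8). Records above 4× the mean influence are removed. Records alone in
their cell have leverage 1 (undefined influence); they are reported as
singletons and excluded from the mean.

The influence model is fitted to log(area) by default. Plant areas are
positive and their noise is multiplicative, so raw-scale residual variance
is dominated by the largest (late-day) plants; a pooled-variance influence
measure is then blind to gross corruption of small plants (measured
sensitivity ~0.35 for 5× corruption). On the log scale the model is
homoscedastic and the same rule detects ~99.7% of 5× corruptions with a
~0.2% false-flag rate on clean records. `log_scale = FALSE` restores the
raw-scale behaviour. On clean synthetic data the rule removes ~4.7% of
records — the same order as the ~5.8% reported for the real platform.

**Replicate filter (ionome).** Within every genotype × treatment replicate
set, a measurement is excluded when |x − median| / MAD > 6.2, with the raw
MAD = median(|x − median|) and no 1.4826 consistency constant (the cutoff is
calibrated for the raw statistic). When the MAD is zero, values off the
median are flagged. With 6–9 replicates the MAD is a noisy spread estimate,
so a 1–3% flag rate on clean data is expected and harmless for the
variance partitioning that follows.

# Colour stress kinetics

Nitrogen starvation shifts leaf hue from green toward yellow. Normalized
histograms of replicate plants are averaged per degree with t-based 95%
confidence intervals (6–9 replicates make normal intervals too narrow), and
the mean histogram is integrated by the trapezoidal rule on the integer
degree grid over two bands: yellow 0–60° and green 61–120°. The conventional
band definitions are kept verbatim, including the un-integrated [60°, 61°]
sliver between them; the band limits are arguments if a user prefers
contiguous bands. Per-plant band areas tracked over days give the stress
kinetics; groups are compared day by day with Welch's t-test (group sizes
and variances differ between early and late responder sets), and
control-minus-stress difference histograms show which hue bands gain or
lose mass under treatment.

The standard-error bands of the group time series are computed over plants
(not over genotype means); the grouping column is an argument, so genotype-
level summaries can be passed in instead.

# Responder timing

For every genotype and day, the areas of the control ("100/100") and severe
("10/10") treatments are compared with a one-way ANOVA (the F statistic of
the treatment source of variation). The raw p-values of the whole genotype
× day matrix receive a single Benjamini–Hochberg FDR correction — one
correction over the whole matrix, not per genotype row, so the FDR is
controlled across all cells jointly (per-genotype correction is available
as an option).
q-values are displayed as −log10(q) (base 10; the heat-map convention),
each genotype giving a significance profile over days. Profiles are
compared with the Canberra distance, which weights coordinates by their
magnitude and therefore distinguishes *when* significance starts rather
than just its cumulative amount, and clustered with Ward's minimum-variance
method via the Lance–Williams update on the provided dissimilarities
(hclust method "ward.D"). Cutting the tree at k = 2 yields the early and
late responder groups; the cluster whose genotypes reach q < 0.05 sooner is
labelled "early". The onset threshold (q < 0.05), k, and the treatment pair
are arguments; ties between clusters are broken by leaf order.

Two ranking views complement the classification: day-26 mean area per
genotype in the 10/10 group, each genotype Welch-tested against the pooled
rest and starred at BH q < 0.01; and the growth rate as the per-plant
least-squares slope of area over days 10–22, averaged over replicates with
a t-based 95% CI. The regression slope equals the mean daily change for
complete series but stays well-defined when QC removed individual days.

# Variance partitioning

**Area time series.** A linear mixed model of the trait carries the six
fixed effects G, E, G×E, G×T, E×T, G×E×T (day as a categorical time factor;
no T main effect, whose span is absorbed by the G×T coding) and a per-plant
random intercept and slope over centred numeric day for the repeated
measures. Each effect is tested with a type III Wald chi-square on its
coefficient block under sum-to-zero contrasts. Wald chi-squares ignore the
uncertainty of the variance estimates and are mildly anti-conservative in
small designs; with ~150 plants the treatment test is calibrated (measured
type I error 0.05 at nominal 0.05 over 200 null simulations). If the mixed
fit fails, a fixed-effects model is used and flagged. The full 30-genotype
× 19-day factorial with categorical day is beyond desk-scale mixed-model
fitting (thousands of fixed-effect columns); the analysis scripts run it on
a sub-panel.

**Ionome.** Every element is partitioned into genotype, treatment,
interaction and residual fractions as type III (partial) SS divided by the
total SS — the "percent variance explained" reading of partial effects.
For balanced designs this equals the sequential decomposition (asserted in
the tests); with QC-induced imbalance each term is adjusted for the others.
Sub-detection values are kept as reported; no imputation.

**PCA.** Shape features and elements are centred and scaled to unit
variance (heterogeneous units); hue-bin matrices are centred only (bins
share a unit). Per-group 95% ellipses come from the group score covariance
at the chi-square(2 df) 0.95 quantile. Hue bins beyond 120° are all zero in
plant imagery and are dropped (with a warning) as constant columns before
the decomposition — numerically equivalent to keeping them, since constant
columns carry no variance.

# The synthetic generator

`generate_experiment()` emulates the platform's outputs with known truth:

* **Growth**: per-genotype logistic curves (asymptote ~50,000 px, rate
  0.35–0.55/day, inflection days 16–20) with multiplicative lognormal noise
  at CV 0.2 — areas are positive and their spread grows with size, matching
  the fan-shaped replicate spread of real area trajectories. From the
  genotype's onset day the low-nitrogen curves are scaled by the treatment
  penalty (default 1 / 0.7 / 0.5); before it, treatments coincide. Early
  genotypes get onset days 10–12, late ones 19–21, so the two classes are
  separated by ≥ 7 days.
* **Colour**: two-component hue mixtures (yellow mode 45°, green mode 100°,
  SD 8°, truncated to their bands) with the yellow weight following a
  Gaussian pulse peaking on day 13, stronger under nitrogen deprivation,
  plus a step increase after onset in stressed treatments and extra pulse
  amplitude for late genotypes in the control group. The pixel split
  between components is exact, so band masses match the configured
  fraction to rounding.
* **Ionome**: per element, additive genotype + treatment + interaction
  effects plus residual, each component rescaled so the realized variance
  fractions equal the configured ones exactly (the generator's contract is
  the partition itself, not just its expectation). Defaults make Mo and Co
  genotype-dominated and P treatment-dominated.
* **Images**: a compact connected blob of exactly the requested pixel count
  with the requested yellow/green hue split, on a uniform hue-240°
  background so the threshold segmenter is exact — segmentation quality is
  deliberately not the thing under test.
* **Outliers**: records corrupted independently with the configured rate by
  multiplying or dividing area by the magnitude; flags are returned.

What the generator does *not* emulate: real segmentation errors, camera
zoom or view calibration, germination-date variation (size differences
predating treatment), watering-volume dynamics, element detection limits,
and any genetic structure among genotypes. A green test therefore
establishes correctness of the analysis chain on its stated model, not
robustness to platform artefacts.

# Numerical and design choices

* Degree grid for AUC: integer degrees, unit spacing, endpoints inclusive;
  a constant c over [0°, 60°] integrates to 60c.
* BH correction is applied once over the full q-value matrix; single-cell
  matrices reduce to q = p.
* Cook's rule: zero residual variance gives all-zero influence (nothing
  flagged); singleton cells are excluded from the mean influence.
* MAD = 0 flags any value off the median; all-equal sets flag nothing.
* Welch tests with zero variance in both groups return p = 1 when means
  agree; one-way ANOVA with zero within-variance and unequal means reports
  the p → 0 limit and a degenerate flag.
* Ties in the early/late cluster labelling are broken by dendrogram leaf
  order.
* Seeds: every generator call derives all randomness from the config seed
  and restores the caller's RNG state.

# Known limitations

* The influence filter assumes a single QC pass; it is not iterated, so
  masked outliers (several corruptions in one small cell) can survive.
* Wald chi-squares (not F with adjusted denominator df) are used for the
  mixed model, the method standard for this model class; in designs much smaller than
  ~100 plants they run anti-conservative.
* The q-value onset rule inherits the FDR's false positives: a genotype can
  show a spuriously early significant day; clustering on whole profiles is
  what keeps the classification stable.
* Type III fractions need not sum exactly to 1 under imbalance.
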