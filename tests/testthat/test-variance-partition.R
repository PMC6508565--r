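test_that("type III partition matches limits, oracles and invariances", {
  # genotype-only signal with zero noise: genotype fraction -> 1
  d <- data.frame(genotype = rep(sprintf("g%d", 1:4), each = 6),
                  treatment = rep(c("A", "B"), 12),
                  y = rep(c(1, 5, 9, 13), each = 6))
  d$y <- d$y + rnorm(24, 0, 1e-8)  # avoid an exactly singular fit
  vp <- suppressWarnings(type3_variance_partition(d, "y"))  # near-perfect fit
  expect_equal(unname(vp$fractions["genotype"]), 1.0, tolerance = 1e-6)
  expect_lt(vp$fractions["residual"], 1e-6)

  # balanced design: type III equals sequential (type I) SS
  set.seed(41)
  db <- expand.grid(genotype = sprintf("g%d", 1:4),
                    treatment = c("A", "B", "C"), rep = 1:5)
  db$y <- rnorm(nrow(db), as.integer(db$genotype) + 2 * as.integer(db$treatment))
  vp2 <- type3_variance_partition(db, "y")
  seq_ss <- anova(lm(y ~ genotype * treatment, data = db))
  expect_equal(unname(vp2$ss["genotype"]), seq_ss["genotype", "Sum Sq"])
  expect_equal(unname(vp2$ss["treatment"]), seq_ss["treatment", "Sum Sq"])
  expect_equal(unname(vp2$ss["genotype:treatment"]),
               seq_ss["genotype:treatment", "Sum Sq"])
  expect_equal(sum(vp2$fractions), 1, tolerance = 1e-10)

  # fractions invariant to rescaling the response
  db$y2 <- db$y * 1000
  vp3 <- type3_variance_partition(db, "y2")
  expect_equal(vp3$fractions, vp2$fractions, tolerance = 1e-10)

  expect_error(type3_variance_partition(db[db$rep == 1, ], "y"), "replicates")
})

test_that("generator variance fractions are recovered per element", {
  cfg <- balanced_config(seed = 47, reps = 30)
  e <- generate_experiment(cfg, with_histograms = FALSE)
  parts <- partition_ionome(e$ionome, elements = cfg$elements)
  truth <- cfg$ionome_fractions
  m <- merge(parts, truth, by = "element", suffixes = c("", "_true"))
  expect_lt(max(abs(m$genotype - m$genotype_true)), 0.05)
  expect_lt(max(abs(m$treatment - m$treatment_true)), 0.05)
  expect_lt(max(abs(m$interaction - m$interaction_true)), 0.05)
})

test_that("mixed-model Wald ANOVA reports the six fixed effects", {
  cfg <- experiment_config(seed = 53, n_genotypes = 3,
                           reps_per_treatment = c(4L, 4L, 4L),
                           days = seq(8L, 26L, by = 6L))
  e <- generate_experiment(cfg, with_histograms = FALSE, with_ionome = FALSE)
  w <- mixed_model_wald(e$traits)
  expect_equal(w$tests$effect, c("G", "E", "GxE", "GxT", "ExT", "GxExT"))
  expect_true(all(w$tests$chisq >= 0))
  expect_true(all(w$tests$df > 0))
  # the generator's strong treatment effect is detected
  expect_lt(w$tests$p[w$tests$effect == "E"], 0.01)

  # constant response: degenerate-variance error
  flat <- data.table::copy(e$traits)[, area := 1]
  expect_error(mixed_model_wald(flat), "constant")
})

test_that("Wald falls back to a fixed-effects model when the mixed fit is impossible", {
  # one observation per plant: per-plant random slope+intercept unidentifiable
  set.seed(13)
  d <- data.table::data.table(
    plant_id = sprintf("p%d", 1:36),
    genotype = rep(c("g1", "g2"), each = 18),
    treatment = rep(rep(c("A", "B", "C"), each = 6), 2),
    day = rep(c(8L, 26L), 18))
  d[, area := 100 + 50 * (treatment == "C") + rnorm(.N, 0, 5)]
  w <- mixed_model_wald(d)
  expect_true(w$fallback)
  expect_lt(w$tests$p[w$tests$effect == "E"], 0.01)
})

test_that("PCA explains variance correctly and draws calibrated ellipses", {
  # perfectly collinear 2-D data: PC1 explains 100%
  x <- cbind(1:50, 2 * (1:50))
  p <- pca_with_ellipses(x, scale. = FALSE)
  expect_equal(p$var_explained[1], 100)
  expect_true(all(diff(p$var_explained) <= 1e-9))

  # reconstruction: scores %*% t(loadings) + center reproduces the input
  set.seed(3)
  m <- matrix(rnorm(200), 40, 5)
  pr <- pca_with_ellipses(m, scale. = FALSE)
  rec <- pr$scores %*% t(pr$loadings) + matrix(pr$center, 40, 5, byrow = TRUE)
  expect_equal(rec, m, ignore_attr = TRUE)
  # loadings orthonormal
  expect_equal(crossprod(pr$loadings), diag(5), ignore_attr = TRUE)

  # duplicating every sample leaves loadings unchanged
  pr2 <- pca_with_ellipses(rbind(m, m), scale. = FALSE)
  expect_equal(abs(pr2$loadings), abs(pr$loadings), tolerance = 1e-8)

  # isotropic Gaussian: 95% ellipse is a near-circle holding ~95% of points
  set.seed(8)
  g <- matrix(rnorm(4000), 2000, 2)
  pg <- pca_with_ellipses(g, groups = rep("all", 2000), scale. = FALSE)
  el <- pg$ellipses$all
  expect_equal(el$axes[1] / el$axes[2], 1, tolerance = 0.2)
  z <- sweep(pg$scores[, 1:2], 2, el$center)
  inside <- mean(rowSums((z / rep(el$axes, each = 2000))^2) <= 1)
  expect_equal(inside, 0.95, tolerance = 0.02)

  # constant columns dropped with a warning
  expect_warning(pca_with_ellipses(cbind(m, 7)), "constant")
})
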