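test_that("growth_curve obeys onset and no-effect semantics", {
  days <- 8:26
  # no treatment effect: identical curves whatever the onset
  expect_equal(growth_curve(5e4, 0.4, 17, days, 1.0, onset_day = 12),
               growth_curve(5e4, 0.4, 17, days, 1.0, onset_day = Inf))
  # before onset all treatments coincide; from onset the low-N curve is scaled
  full <- growth_curve(5e4, 0.4, 17, days, 1.0, onset_day = 14)
  low <- growth_curve(5e4, 0.4, 17, days, 0.5, onset_day = 14)
  expect_equal(low[days < 14], full[days < 14])
  expect_equal(low[days >= 14], 0.5 * full[days >= 14])
  # closed-form logistic: within 1% of the asymptote by inflection + 5/rate
  A <- 5e4; r <- 0.4
  expect_gt(growth_curve(A, r, 17, 17 + 5 / r), 0.99 * A)
  expect_error(growth_curve(-1, 0.4, 17, 10), "asymptote")
  expect_error(growth_curve(100, 0, 17, 10), "rate")
})

test_that("generate_experiment is seed-deterministic and unbiased", {
  cfg <- small_config(seed = 11)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$traits, e2$traits)
  expect_identical(e1$histograms, e2$histograms)
  expect_identical(e1$ionome, e2$ionome)
  expect_false(any(e1$truth$outliers$flagged))  # outlier_rate 0

  # different seed changes the data
  e3 <- generate_experiment(small_config(seed = 12), with_histograms = FALSE)
  expect_false(identical(e1$traits$area, e3$traits$area))

  # Monte-Carlo: cell means of area within 3 SE of the deterministic curve
  cfg50 <- experiment_config(seed = 5, n_genotypes = 2,
                             reps_per_treatment = c(50L, 50L, 50L),
                             days = c(10L, 18L, 26L))
  e50 <- generate_experiment(cfg50, with_histograms = FALSE, with_ionome = FALSE)
  gp <- cfg50$growth
  checks <- e50$traits[, .(m = mean(area), se = sd(area) / sqrt(.N)),
                       by = .(genotype, treatment, day)]
  i <- match(checks$genotype, gp$genotype)
  mu <- growth_curve(gp$asymptote[i], gp$rate[i], gp$inflection[i], checks$day,
                     unname(cfg50$treatment_effect[checks$treatment]),
                     gp$onset_day[i])
  expect_lt(max(abs(checks$m - mu) / checks$se), 3 + 1e-9)
})

test_that("hue histograms match the configured yellow fraction", {
  cfg <- small_config(seed = 3)
  e <- generate_experiment(cfg)
  H <- as.matrix(e$histograms[, hue_cols, with = FALSE])
  yellow_mass <- rowSums(H[, 1:61]) / rowSums(H)
  expect_lt(max(abs(yellow_mass - e$truth$yellow$yellow_fraction)), 0.02)
  # histogram totals equal the rounded area (all pixels have defined hue)
  expect_equal(rowSums(H), pmax(1, round(e$traits$area)))
})

test_that("ionome generator hits configured variance fractions at 30 reps/cell", {
  cfg <- balanced_config(seed = 21, reps = 30)
  e <- generate_experiment(cfg, with_histograms = FALSE)
  for (el in c("Mo", "P", "K")) {
    vp <- type3_variance_partition(e$ionome, el)
    truth <- cfg$ionome_fractions[cfg$ionome_fractions$element == el, ]
    expect_lt(abs(vp$fractions[["genotype"]] - truth$genotype), 0.05)
    expect_lt(abs(vp$fractions[["treatment"]] - truth$treatment), 0.05)
    expect_lt(abs(vp$fractions[["interaction"]] - truth$interaction), 0.05)
  }
})

test_that("inject_outliers flags and corrupts at the requested rate", {
  cfg <- small_config(seed = 8, days = 8:26)
  e <- generate_experiment(cfg, with_histograms = FALSE, with_ionome = FALSE)
  tr <- e$traits[1:1000]

  none <- inject_outliers(tr, rate = 0, magnitude = 5, seed = 1)
  expect_identical(none$traits$area, tr$area)
  expect_false(any(none$flags))

  out <- inject_outliers(tr, rate = 0.05, magnitude = 5, seed = 2)
  n_fl <- sum(out$flags)
  expect_gt(n_fl, qbinom(0.0005, 1000, 0.05))   # ~50 expected
  expect_lt(n_fl, qbinom(0.9995, 1000, 0.05))
  ratio <- out$traits$area[out$flags] / tr$area[out$flags]
  expect_true(all(abs(ratio - 5) < 1e-9 | abs(ratio - 0.2) < 1e-9))
  expect_identical(out$traits$area[!out$flags], tr$area[!out$flags])

  ident <- inject_outliers(tr, rate = 0.05, magnitude = 1, seed = 3)
  expect_identical(ident$traits$area, tr$area)  # magnitude 1: values unchanged
  expect_gt(sum(ident$flags), 0)                # but flags still set
})

test_that("render_plant_image draws the requested area and hue mix", {
  r <- render_plant_image(5000, 0.3, canvas_size = c(100, 100), seed = 9)
  expect_true(sum(r$mask) >= 4900 && sum(r$mask) <= 5100)  # exact by design
  expect_equal(sum(r$mask), 5000)
  expect_equal(dim(r$image), c(100, 100, 3))

  # recover hues of foreground pixels and check the band split
  fg <- which(r$mask)
  hw <- 100 * 100
  hsv <- grDevices::rgb2hsv(rbind(r$image[fg], r$image[fg + hw],
                                  r$image[fg + 2 * hw]), maxColorValue = 255)
  deg <- hsv[1, ] * 360
  expect_equal(mean(deg <= 60), 0.3, tolerance = 0.02)

  allg <- render_plant_image(800, 0, canvas_size = c(50, 50), seed = 10)
  fg <- which(allg$mask)
  hsv <- grDevices::rgb2hsv(rbind(allg$image[fg], allg$image[fg + 2500],
                                  allg$image[fg + 5000]), maxColorValue = 255)
  expect_true(all(hsv[1, ] * 360 > 60 & hsv[1, ] * 360 <= 120.5))

  empty <- render_plant_image(0, 0.5, canvas_size = c(20, 20), seed = 1)
  expect_equal(sum(empty$mask), 0)
  expect_error(extract_shape_features(empty$mask), "no plant")
  expect_error(render_plant_image(1e6, 0.5, canvas_size = c(50, 50)), "canvas")
})
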