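test_that("one-way ANOVA F matches the hand decomposition", {
  r <- one_way_anova_F(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$F, 13.5)            # SSB 13.5, MSW 1
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  expect_equal(r$ss_between, 13.5)
  expect_equal(r$p, pf(13.5, 1, 4, lower.tail = FALSE))
  # cross-check against the reference implementation
  y <- c(1, 2, 3, 4, 5, 6); gr <- factor(rep(1:2, each = 3))
  ref <- anova(lm(y ~ gr))
  expect_equal(r$F, ref$`F value`[1])
  expect_equal(r$p, ref$`Pr(>F)`[1])

  same <- one_way_anova_F(list(c(2, 2), c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  degen <- one_way_anova_F(list(c(1, 1), c(2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)

  # permutation null: p uniform
  set.seed(71)
  ps <- replicate(2000, {
    x <- rnorm(12)
    one_way_anova_F(list(x[1:6], x[7:12]))$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("BH q-values match the step-up closed form", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(17)
  for (m in c(1, 5, 50, 570)) {
    p <- runif(m)^2
    expect_equal(p.adjust(p, "BH"), step_up(p))
  }
})

test_that("q-value matrix finds treatment divergence from the onset day", {
  cfg <- small_config(seed = 23, days = 8:26)
  e <- generate_experiment(cfg, with_histograms = FALSE, with_ionome = FALSE)
  qm <- qvalue_matrix(e$traits)
  expect_equal(dim(qm$q), c(6, length(cfg$days)))
  expect_true(all(qm$q >= qm$p, na.rm = TRUE))           # BH never decreases p
  expect_true(all(qm$neglog_q >= 0, na.rm = TRUE))

  # cells become significant after the genotype's onset day and mostly not before
  post <- pre <- numeric(0)
  for (g in cfg$genotypes) {
    onset <- cfg$growth$onset_day[cfg$growth$genotype == g]
    post <- c(post, qm$q[g, as.character(qm$days[qm$days >= onset + 3])])
    pre <- c(pre, qm$q[g, as.character(qm$days[qm$days < onset])])
  }
  expect_gt(mean(post < 0.05), 0.8)
  expect_gt(mean(pre > 0.05), 0.8)

  # single-cell matrix: q equals p (BH with m = 1)
  one <- e$traits[genotype == "G01" & day == 26]
  qm1 <- qvalue_matrix(one)
  expect_equal(qm1$q[1, 1], qm1$p[1, 1])
})

test_that("Canberra distance satisfies its definition and metric axioms", {
  expect_equal(canberra_distance(c(1, 2), c(3, 2)), 0.5)
  expect_equal(canberra_distance(c(0, 0, 1), c(0, 0, 1)), 0)
  # zero-zero coordinates contribute nothing
  expect_equal(canberra_distance(c(0, 1), c(0, 3)), 0.5)
  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(10); v <- rnorm(10)
    expect_gte(canberra_distance(u, v), 0)
    expect_equal(canberra_distance(u, v), canberra_distance(v, u))
    expect_equal(canberra_distance(u, u), 0)
  }
  # cross-check against the reference implementation on positive vectors
  m <- matrix(abs(rnorm(40)), 4)
  expect_equal(as.vector(canberra_matrix(m)),
               as.vector(dist(m, method = "canberra")))
})

test_that("Ward clustering follows the Lance-Williams update", {
  # first merge is always the closest pair
  d3 <- matrix(c(0, 0.1, 5, 0.1, 0, 5, 5, 5, 0), 3)
  hc3 <- ward_dendrogram(d3)
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))

  # hand-computed 4-point Lance-Williams heights:
  # points {1,2} at distance 1, {3,4} at distance 1, cross distances 10
  d4 <- matrix(10, 4, 4); diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- 1
  d4[3, 4] <- d4[4, 3] <- 1
  hc4 <- ward_dendrogram(as.dist(d4))
  # merge 1: {1,2} at 1; merge 2: {3,4} at 1
  expect_equal(sort(hc4$height[1:2]), c(1, 1))
  # Ward LW for {1,2} vs {3,4}: after {1,2}: d({12},3) = (2*10+2*10-1*1)/3 = 13
  # likewise d({12},4) = 13; then d({12},{34}) = (3*13+3*13-2*1)/4 = 19
  expect_equal(hc4$height[3], 19)
  expect_true(all(diff(hc4$height) >= 0))
  expect_equal(nrow(hc4$merge), 3)

  # two well-separated blobs are recovered by the k = 2 cut
  set.seed(9)
  pts <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 8), ncol = 2))
  cl <- cutree(ward_dendrogram(dist(pts)), 2)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[11])
})

test_that("early/late split recovers ground truth and is label-invariant", {
  cfg <- small_config(seed = 29, days = 8:26)
  e <- generate_experiment(cfg, with_histograms = FALSE, with_ionome = FALSE)
  qm <- qvalue_matrix(e$traits)
  hc <- ward_dendrogram(canberra_matrix(qm$neglog_q))
  lab <- split_early_late(hc, qm)
  truth <- cfg$growth
  m <- merge(lab, truth, by = "genotype")
  expect_equal(mean(m$label.x == m$label.y), 1)
  expect_setequal(unique(lab$label), c("early", "late"))
  # estimated onsets separate the groups on average
  expect_lt(mean(lab$onset_day[lab$label == "early"]),
            mean(lab$onset_day[lab$label == "late"]))

  # permuting genotype names permutes but preserves the partition
  perm <- rev(qm$genotypes)
  tr2 <- data.table::copy(e$traits)
  tr2[, genotype := perm[match(genotype, qm$genotypes)]]
  qm2 <- qvalue_matrix(tr2)
  lab2 <- split_early_late(ward_dendrogram(canberra_matrix(qm2$neglog_q)), qm2)
  relabelled <- lab2$label[match(perm[match(lab$genotype, qm$genotypes)],
                                 lab2$genotype)]
  expect_identical(relabelled, lab$label)
})

test_that("growth rate recovers known slopes", {
  dt <- data.table::data.table(
    plant_id = rep(c("p1", "p2"), each = 13),
    genotype = "G", treatment = "T",
    day = rep(10:22, 2),
    area = c(5 * (10:22), rep(100, 13))
  )
  r <- growth_rate(dt)
  expect_equal(r$rate, (5 + 0) / 2)  # exact slope 5 and constant slope 0 averaged
  r1 <- growth_rate(dt[plant_id == "p1"])
  expect_equal(r1$rate, 5)

  # CI coverage for a noisy linear truth
  set.seed(61)
  cover <- mean(replicate(300, {
    d <- data.table::data.table(
      plant_id = rep(sprintf("p%d", 1:8), each = 13),
      genotype = "G", treatment = "T", day = rep(10:22, 8))
    d[, area := 100 + 7 * day + rnorm(.N, 0, 20)]
    ci <- growth_rate(d)
    ci$ci_lo <= 7 && 7 <= ci$ci_hi
  }))
  expect_gt(cover, 0.9)
})

test_that("end-size outperformers are detected and controlled", {
  cfg <- small_config(seed = 37)
  e <- generate_experiment(cfg, with_histograms = FALSE, with_ionome = FALSE)
  # shift one genotype's final-day areas far above the rest
  tr <- data.table::copy(e$traits)
  tr[genotype == "G03" & day == 26 & treatment == "10/10",
     area := area + 5 * sd(tr[day == 26 & treatment == "10/10", area])]
  res <- end_size_outperformers(tr)
  expect_true(res$starred[res$genotype == "G03"])
  expect_gt(res$effect[res$genotype == "G03"], 0)

  # exchangeable genotypes: stars at q < 0.01 are rare
  set.seed(77)
  n_star <- replicate(30, {
    d <- data.table::data.table(
      plant_id = sprintf("p%d", 1:60),
      genotype = rep(sprintf("g%d", 1:10), each = 6),
      treatment = "10/10", day = 26, area = rnorm(60, 1000, 50))
    sum(end_size_outperformers(d)$starred)
  })
  expect_lt(mean(n_star), 0.3)

  single <- e$traits[genotype == "G01" & day == 26 & treatment == "10/10"]
  expect_error(end_size_outperformers(single), "two genotypes")
})
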