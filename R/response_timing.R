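#' One-way ANOVA F-test
#'
#' Classic between/within sum-of-squares decomposition for k groups: the
#' p-value comes from the F statistic of the treatment source of variation.
#' When the within-group variance is exactly zero but the group means differ,
#' the F statistic is infinite and the p-value 0 (flagged degenerate).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `F`, `p`, `df1`, `df2`, `ss_between`, `ss_within` and
#'   `degenerate` (TRUE when the zero-within-variance limit was hit).
#' @export
one_way_anova_F <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  ni <- lengths(groups)
  if (any(ni < 2)) stop("each group needs at least 2 values")
  k <- length(groups)
  n <- sum(ni)
  gm <- sum(vapply(groups, sum, 0)) / n
  mi <- vapply(groups, mean, 0)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(F = 0, p = 1, df1 = df1, df2 = df2,
                  ss_between = 0, ss_within = 0, degenerate = FALSE))
    }
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2,
                ss_between = ssb, ss_within = 0, degenerate = TRUE))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_between = ssb, ss_within = ssw,
       degenerate = FALSE)
}

#' Genotype x day treatment-significance matrix
#'
#' For every genotype and day, tests whether the trait differs between two
#' treatments (one-way ANOVA on the replicate plants), then applies a single
#' Benjamini-Hochberg FDR correction globally across all genotype x day
#' cells and stores the -log10 transform of the q-values for heat-map
#' display.
#'
#' @param traits trait table (`genotype`, `treatment`, `day`, trait column).
#' @param trait trait column name (default "area").
#' @param pair character vector of the two treatments to compare.
#' @param bh_scope "global" (one correction over the whole matrix, the
#'   default) or "by_genotype" (correction within each genotype row).
#' @return object of class `qmatrix`: list with genotype x day matrices `p`,
#'   `q` and `neglog_q`, plus `genotypes`, `days` and the treatment pair.
#' @export
qvalue_matrix <- function(traits, trait = "area",
                          pair = c("100/100", "10/10"),
                          bh_scope = c("global", "by_genotype")) {
  bh_scope <- match.arg(bh_scope)
  traits <- data.table::as.data.table(traits)
  stopifnot(all(c("genotype", "treatment", "day", trait) %in% names(traits)),
            length(pair) == 2, all(pair %in% traits$treatment))
  dt <- traits[treatment %in% pair]
  pv <- dt[, .(
    p = {
      a <- get(trait)[treatment == pair[1]]
      b <- get(trait)[treatment == pair[2]]
      if (length(a) >= 2 && length(b) >= 2) one_way_anova_F(list(a, b))$p
      else NA_real_
    }
  ), by = .(genotype, day)]
  genotypes <- sort(unique(pv$genotype))
  days <- sort(unique(pv$day))
  P <- matrix(NA_real_, length(genotypes), length(days),
              dimnames = list(genotypes, days))
  P[cbind(match(pv$genotype, genotypes), match(pv$day, days))] <- pv$p
  Q <- P
  if (bh_scope == "global") {
    Q[] <- p.adjust(as.vector(P), method = "BH")
  } else {
    for (i in seq_along(genotypes)) Q[i, ] <- p.adjust(P[i, ], method = "BH")
  }
  structure(list(p = P, q = Q, neglog_q = -log10(Q),
                 genotypes = genotypes, days = days, pair = pair),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("q-value matrix: %d genotypes x %d days, %s vs %s\n",
              length(x$genotypes), length(x$days), x$pair[1], x$pair[2]))
  cat(sprintf("  cells with q < 0.05: %d / %d\n",
              sum(x$q < 0.05, na.rm = TRUE), sum(!is.na(x$q))))
  invisible(x)
}

#' Canberra distance between two vectors
#'
#' `sum_i |u_i - v_i| / (|u_i| + |v_i|)`, with coordinates where both entries
#' are zero contributing nothing. Sensitive to proportional differences in
#' small-magnitude coordinates, which is why it suits -log10(q) significance
#' profiles. Coordinates that are NA in either vector (e.g. genotype x day
#' cells that lost replication during QC) are skipped.
#'
#' @param u,v numeric vectors of equal length.
#' @return the Canberra distance.
#' @export
canberra_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  den <- abs(u) + abs(v)
  keep <- !is.na(den) & den > 0
  sum(abs(u - v)[keep] / den[keep])
}

#' Pairwise Canberra distances between matrix rows
#'
#' @param m numeric matrix; distances are computed between rows.
#' @return a `dist` object.
#' @export
canberra_matrix <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- canberra_distance(m[i, ], m[j, ])
    }
  }
  as.dist(d)
}

#' Ward's minimum-variance dendrogram
#'
#' Agglomerative clustering of a dissimilarity matrix by Ward's
#' minimum-variance criterion, using the Lance-Williams update on the
#' provided dissimilarities (hclust method "ward.D").
#'
#' @param d a `dist` object (or symmetric matrix with zero diagonal).
#' @return an `hclust` tree.
#' @export
ward_dendrogram <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
    d <- as.dist(d)
  }
  hclust(d, method = "ward.D")
}

#' Split genotypes into early and late responders
#'
#' Cuts the q-value dendrogram into `k = 2` clusters and labels the cluster
#' whose members reach treatment significance sooner as "early". A
#' genotype's onset day is its first day with `q < alpha`; genotypes that
#' never reach significance get an onset one day past the experiment end.
#' Ties between clusters are broken by leaf order (the cluster containing
#' the first leaf is labelled early).
#'
#' @param dendrogram `hclust` tree over the genotypes of `qm`.
#' @param qm a [qvalue_matrix()] result.
#' @param k number of clusters (default 2).
#' @param alpha q-value threshold defining onset (default 0.05).
#' @return data.frame with `genotype`, `cluster`, `onset_day` and `label`
#'   ("early"/"late"; clusters beyond the first two, if `k > 2`, are labelled
#'   "cluster<i>").
#' @export
split_early_late <- function(dendrogram, qm, k = 2, alpha = 0.05) {
  stopifnot(inherits(dendrogram, "hclust"), inherits(qm, "qmatrix"))
  cl <- cutree(dendrogram, k = k)
  genotypes <- dendrogram$labels %||% qm$genotypes
  stopifnot(length(cl) == length(qm$genotypes))
  onset <- apply(qm$q[genotypes, , drop = FALSE] < alpha, 1, function(sig) {
    hit <- which(sig)
    if (length(hit)) qm$days[hit[1]] else max(qm$days) + 1
  })
  mean_onset <- tapply(onset, cl, mean)
  ord <- order(mean_onset, match(names(mean_onset), cl[dendrogram$order]))
  lab_for_cluster <- setNames(rep(sprintf("cluster%d", seq_len(k)), length.out = k),
                              names(mean_onset)[ord])
  lab_for_cluster[1] <- "early"
  if (k >= 2) lab_for_cluster[2] <- "late"
  data.frame(genotype = genotypes,
             cluster = unname(cl),
             onset_day = unname(onset),
             label = unname(lab_for_cluster[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' Per-genotype growth rate
#'
#' Average change in area per day within a day window: a least-squares slope
#' of area against day is fitted per plant, then summarised per genotype as
#' the replicate mean with a t-based 95% confidence interval. The regression
#' slope equals the mean daily change for complete series but tolerates
#' missing days after outlier removal.
#'
#' @param traits trait table (`plant_id`, `genotype`, `treatment`, `day`,
#'   `area`).
#' @param window inclusive day window (default days 10--22).
#' @param treatment optional treatment to restrict to (default: all, rates
#'   reported per genotype x treatment).
#' @return data.table with `genotype`, `treatment`, `rate` (px/day),
#'   `ci_lo`, `ci_hi`, `n_plants`.
#' @export
growth_rate <- function(traits, window = c(10, 22), treatment = NULL) {
  traits <- data.table::as.data.table(traits)
  dt <- traits[day >= window[1] & day <= window[2]]
  if (!is.null(treatment)) {
    keep <- treatment
    dt <- dt[treatment %in% keep]
  }
  slopes <- dt[, .(slope = {
    if (.N >= 2 && var(day) > 0) cov(day, area) / var(day) else NA_real_
  }), by = .(plant_id, genotype, treatment)]
  slopes[!is.na(slope), .(
    rate = mean(slope),
    ci_lo = mean(slope) - qt(0.975, max(.N - 1, 1)) * sd(slope) / sqrt(.N),
    ci_hi = mean(slope) + qt(0.975, max(.N - 1, 1)) * sd(slope) / sqrt(.N),
    n_plants = .N
  ), by = .(genotype, treatment)][order(genotype, treatment)]
}

#' End-of-experiment size outperformers
#'
#' For one treatment on one day (default the final-day low-nitrogen group),
#' tests every genotype's replicate areas against the pooled areas of all
#' other genotypes (Welch t-test), corrects across genotypes with
#' Benjamini-Hochberg, and stars genotypes at `q < star_q`. The signed
#' `effect` column (genotype mean minus rest mean) separates out- from
#' under-performers.
#'
#' @param traits trait table.
#' @param day day to evaluate (default 26).
#' @param treatment treatment group (default "10/10").
#' @param star_q q-value threshold for the star (default 0.01).
#' @return data.table with `genotype`, `mean_area`, `effect`, `p`, `q`,
#'   `starred`, `n`.
#' @export
end_size_outperformers <- function(traits, day = 26, treatment = "10/10",
                                   star_q = 0.01) {
  traits <- data.table::as.data.table(traits)
  d <- day; tr <- treatment
  dt <- traits[day == d & treatment == tr]
  if (nrow(dt) == 0) stop("no records for the requested day and treatment")
  if (length(unique(dt$genotype)) < 2) {
    stop("need at least two genotypes to compare against the rest")
  }
  res <- dt[, {
    own <- area
    rest <- dt$area[dt$genotype != .BY$genotype]
    tt <- t.test(own, rest)
    .(mean_area = mean(own), effect = mean(own) - mean(rest),
      p = tt$p.value, n = .N)
  }, by = genotype]
  res[, q := p.adjust(p, method = "BH")]
  res[, starred := q < star_q]
  res[order(-mean_area)]
}
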