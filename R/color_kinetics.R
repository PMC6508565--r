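#' Per-degree mean histogram with 95% confidence intervals
#'
#' Averages a set of normalized hue histograms (replicate plants of one
#' group/day) degree by degree and attaches a t-based 95% confidence
#' half-width per degree, appropriate for the small replicate counts (6--9)
#' typical of phenotyping designs.
#'
#' @param hists numeric matrix, one row per replicate, one column per degree
#'   bin (normalized fractions).
#' @param conf confidence level (default 0.95).
#' @return list of class `mean_histogram`: `mean`, `ci_halfwidth` (both per
#'   degree) and `n` (replicates).
#' @export
mean_histogram_with_ci <- function(hists, conf = 0.95) {
  hists <- as.matrix(hists)
  n <- nrow(hists)
  if (n < 2) stop("need at least 2 replicate histograms")
  mu <- colMeans(hists)
  se <- apply(hists, 2, sd) / sqrt(n)
  structure(list(mean = mu, ci_halfwidth = qt(1 - (1 - conf) / 2, n - 1) * se,
                 n = n),
            class = "mean_histogram")
}

#' Trapezoidal area under a hue histogram band
#'
#' Integrates a per-degree histogram over the degree band `[lo_deg, hi_deg]`
#' (endpoints inclusive) by the trapezoidal rule on the unit-spaced integer
#' degree grid: `sum_{d = lo}^{hi - 1} (f[d] + f[d + 1]) / 2`. The canonical
#' stress bands are yellow `[0, 60]` and green `[61, 120]` degrees.
#'
#' @param hist numeric per-degree vector (index 1 = degree 0), or a
#'   `mean_histogram` (its mean is used).
#' @param lo_deg,hi_deg integer degree band limits, `0 <= lo < hi <= 359`.
#' @return the trapezoidal area (same units as the bin values times degrees).
#' @export
hist_auc <- function(hist, lo_deg, hi_deg) {
  f <- if (inherits(hist, "mean_histogram")) hist$mean else hist
  stopifnot(lo_deg >= 0, hi_deg > lo_deg, hi_deg <= length(f) - 1,
            lo_deg == round(lo_deg), hi_deg == round(hi_deg))
  i <- (lo_deg + 1):hi_deg  # 1-based left endpoints of each trapezoid
  sum((f[i] + f[i + 1]) / 2)
}

#' Yellow/green AUC time series per group
#'
#' For every plant and day, computes the trapezoidal area under its
#' normalized hue histogram within the yellow and green bands, then
#' summarises per group and day as mean and standard error over plants.
#'
#' @param hists data.table/data.frame with columns `plant_id`, `day`, a group
#'   column and the 360 per-degree bins `hue_000`..`hue_359` (raw counts or
#'   fractions; raw counts are normalized by their row sum first when
#'   `normalize = TRUE`).
#' @param group_col name of the grouping column (e.g. "treatment" or a
#'   responder label).
#' @param yellow,green integer degree bands, endpoints inclusive.
#' @param normalize divide each row by its total count before integrating.
#' @return list with `per_plant` (plant_id, group, day, yellow_auc,
#'   green_auc) and `series` (group, day, mean and SE of each band, n).
#' @export
auc_time_series <- function(hists, group_col = "treatment",
                            yellow = c(0, 60), green = c(61, 120),
                            normalize = TRUE) {
  hists <- data.table::as.data.table(hists)
  hue_cols <- grep("^hue_", names(hists), value = TRUE)
  stopifnot(length(hue_cols) == 360, group_col %in% names(hists),
            all(c("plant_id", "day") %in% names(hists)))
  M <- as.matrix(hists[, hue_cols, with = FALSE])
  if (normalize) {
    tot <- rowSums(M)
    tot[tot == 0] <- 1
    M <- M / tot
  }
  band_auc <- function(band) {
    i <- (band[1] + 1):band[2]
    rowSums((M[, i, drop = FALSE] + M[, i + 1, drop = FALSE]) / 2)
  }
  per_plant <- hists[, c("plant_id", group_col, "day"), with = FALSE]
  data.table::setnames(per_plant, group_col, "group")
  per_plant[, `:=`(yellow_auc = band_auc(yellow), green_auc = band_auc(green))]
  series <- per_plant[, .(
    yellow_auc = mean(yellow_auc), yellow_se = sd(yellow_auc) / sqrt(.N),
    green_auc = mean(green_auc), green_se = sd(green_auc) / sqrt(.N),
    n = .N
  ), by = .(group, day)][order(group, day)]
  list(per_plant = per_plant[], series = series)
}

#' Difference between two mean histograms
#'
#' Per-degree difference `meanA - meanB`, e.g. control minus stress to show
#' which hue bands gain or lose mass under treatment.
#'
#' @param meanA,meanB `mean_histogram` objects or numeric per-degree vectors
#'   of equal length.
#' @return numeric per-degree difference vector.
#' @export
difference_histogram <- function(meanA, meanB) {
  a <- if (inherits(meanA, "mean_histogram")) meanA$mean else meanA
  b <- if (inherits(meanB, "mean_histogram")) meanB$mean else meanB
  stopifnot(length(a) == length(b))
  a - b
}

#' Daily two-group comparison of band AUCs
#'
#' Welch two-sample t-test per day on per-plant band AUCs, used to find the
#' day from which two groups (e.g. early vs late responders within one
#' treatment) diverge in a colour band.
#'
#' @param per_plant table with columns `group`, `day` and the AUC column;
#'   exactly two groups required.
#' @param value name of the AUC column (default "yellow_auc").
#' @param min_n minimum plants per group per day for a test.
#' @return data.table with `day`, `p`, group means and n per group; days with
#'   insufficient replication get NA.
#' @export
compare_auc_groups <- function(per_plant, value = "yellow_auc", min_n = 3) {
  per_plant <- data.table::as.data.table(per_plant)
  stopifnot(all(c("group", "day", value) %in% names(per_plant)))
  grps <- sort(unique(as.character(per_plant$group)))
  if (length(grps) != 2) stop("exactly two groups are required")
  per_plant[, .(
    p = {
      a <- get(value)[group == grps[1]]
      b <- get(value)[group == grps[2]]
      if (length(a) >= min_n && length(b) >= min_n &&
          (sd(a) > 0 || sd(b) > 0)) t.test(a, b)$p.value
      else if (length(a) >= min_n && length(b) >= min_n) 1
      else NA_real_
    },
    mean1 = mean(get(value)[group == grps[1]]),
    mean2 = mean(get(value)[group == grps[2]]),
    n1 = sum(group == grps[1]), n2 = sum(group == grps[2])
  ), by = day][order(day)]
}
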