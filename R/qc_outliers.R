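#' Cook's distance under a cell-means model
#'
#' Influence of every record on a linear model containing only the full
#' interaction of the design factors (genotype x treatment x day): a
#' cell-means model, for which the leverage of a record in a cell of size
#' `n_c` is `1 / n_c` and Cook's distance has the closed form
#' `D_i = r_i^2 h_ii / (p s^2 (1 - h_ii)^2)` with `p` the number of occupied
#' cells and `s^2` the residual mean square. This equals the classic
#' leave-one-out definition `sum_j (yhat_j - yhat_j(i))^2 / (p s^2)`.
#'
#' Records alone in their cell have leverage 1: their influence is undefined.
#' They are flagged as singletons and excluded from any mean-influence
#' summary. If the model fits perfectly (zero residual variance) every
#' defined influence is 0.
#'
#' @param cells factor (or vector coercible to one) giving each record's
#'   design cell.
#' @param response numeric response (e.g. plant area).
#' @return list with `D` (Cook's distance, NA for singletons), `singleton`
#'   (logical), `p` (number of cells) and `s2` (residual mean square).
#' @export
cooks_distance_cells <- function(cells, response) {
  stopifnot(length(cells) == length(response))
  cells <- factor(cells)
  n <- length(response)
  cell_n <- tabulate(cells)
  p <- sum(cell_n > 0)
  if (n <= p) stop("need replication: no residual degrees of freedom")
  cell_mean <- tapply(response, cells, mean)
  r <- response - cell_mean[as.integer(cells)]
  s2 <- sum(r^2) / (n - p)
  h <- 1 / cell_n[as.integer(cells)]
  singleton <- cell_n[as.integer(cells)] == 1
  D <- rep(NA_real_, n)
  ok <- !singleton
  if (s2 == 0) {
    D[ok] <- 0
  } else {
    D[ok] <- r[ok]^2 * h[ok] / (p * s2 * (1 - h[ok])^2)
  }
  list(D = unname(D), singleton = unname(singleton), p = p, s2 = s2)
}

#' Remove influential trait records
#'
#' Applies the influence rule used for image QC: Cook's distance is computed
#' on the genotype x treatment x day cell-means model of `response`, and a
#' record is an outlier when its influence exceeds `threshold_mult` (default
#' 4) times the mean influence over all non-singleton records. Flagged
#' records are removed and the removal fraction reported.
#'
#' By default the influence model is fitted to `log(response)`. Plant areas
#' are positive with noise that scales multiplicatively, so raw-scale
#' residual variance is dominated by the largest plants and corrupted records
#' on small plants are invisible to a pooled-variance influence measure; on
#' the log scale the cell-means model is homoscedastic and the rule detects
#' gross corruption at every plant size. Set `log_scale = FALSE` for the
#' raw-scale model.
#'
#' @param traits trait table with `genotype`, `treatment`, `day` and the
#'   response column.
#' @param response name of the response column (default "area").
#' @param threshold_mult multiple of the mean influence used as cutoff.
#' @param log_scale fit the influence model on the log of the response
#'   (requires positive values).
#' @return list with `traits` (filtered table), `influence` (per-record
#'   Cook's distance, mean influence, threshold, flags, singleton flags) and
#'   `removal_fraction`.
#' @export
flag_influence_outliers <- function(traits, response = "area", threshold_mult = 4,
                                    log_scale = TRUE) {
  traits <- data.table::as.data.table(traits)
  stopifnot(all(c("genotype", "treatment", "day", response) %in% names(traits)))
  y <- traits[[response]]
  if (log_scale) {
    if (any(y <= 0)) stop("log-scale influence model requires positive responses")
    y <- log(y)
  }
  cells <- interaction(traits$genotype, traits$treatment, traits$day, drop = TRUE)
  cd <- cooks_distance_cells(cells, y)
  D_bar <- mean(cd$D, na.rm = TRUE)
  threshold <- threshold_mult * D_bar
  flags <- !is.na(cd$D) & cd$D > threshold
  list(
    traits = traits[!flags],
    influence = list(D = cd$D, mean_influence = D_bar, threshold = threshold,
                     flags = flags, singleton = cd$singleton),
    removal_fraction = mean(flags)
  )
}

#' MAD-based replicate outlier flags
#'
#' Robust flagging of replicate measurements (e.g. element concentrations of
#' the replicate plants of one genotype in one treatment): a value is flagged
#' when its absolute deviation from the replicate median exceeds `cutoff`
#' times the median absolute deviation. The MAD here is the raw
#' `median(|x - median(x)|)` without a consistency constant; the default
#' cutoff 6.2 is calibrated for that raw statistic.
#'
#' Degenerate case: when the MAD is 0 (more than half the values identical),
#' any value different from the median is flagged; if all values equal the
#' median nothing is flagged.
#'
#' @param values numeric replicate measurements (>= 3 recommended).
#' @param cutoff robust-score threshold (default 6.2).
#' @return list with `flags`, `scores` (|x - median| / MAD; Inf under the
#'   degenerate rule), `median`, `mad` and `cutoff`.
#' @export
mad_flags <- function(values, cutoff = 6.2) {
  stopifnot(is.numeric(values), length(values) >= 1)
  med <- median(values)
  dev <- abs(values - med)
  m <- median(dev)
  if (m == 0) {
    scores <- ifelse(dev > 0, Inf, 0)
    flags <- dev > 0
  } else {
    scores <- dev / m
    flags <- scores > cutoff
  }
  list(flags = flags, scores = scores, median = med, mad = m, cutoff = cutoff)
}

#' Filter an ionome table by the MAD rule
#'
#' Applies [mad_flags()] within every genotype x treatment replicate group for
#' every element column, setting flagged measurements to NA and reporting the
#' flag counts per element.
#'
#' @param ionome table with `genotype`, `treatment` and one numeric column per
#'   element.
#' @param elements element column names; defaults to all numeric columns.
#' @param cutoff robust-score threshold (default 6.2).
#' @return list with `ionome` (filtered copy), `flags` (logical table of the
#'   same shape) and `n_flagged` (named per-element counts).
#' @export
mad_filter_ionome <- function(ionome, elements = NULL, cutoff = 6.2) {
  ionome <- data.table::as.data.table(ionome)
  if (is.null(elements)) {
    elements <- setdiff(names(ionome)[vapply(ionome, is.numeric, TRUE)],
                        c("day", "rep"))
  }
  out <- data.table::copy(ionome)
  flags <- out[, .(genotype, treatment)]
  for (el in elements) {
    out[, .flag. := mad_flags(get(el), cutoff)$flags, by = .(genotype, treatment)]
    flags[, (el) := out$.flag.]
    out[.flag. == TRUE, (el) := NA_real_]
  }
  out[, .flag. := NULL]
  list(ionome = out[], flags = flags,
       n_flagged = vapply(elements, function(e) sum(flags[[e]]), integer(1)))
}
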