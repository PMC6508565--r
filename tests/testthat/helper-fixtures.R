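# Small, fast experiment configurations used across test files.

small_config <- function(seed = 42L, days = seq(8L, 26L, by = 3L), ...) {
  experiment_config(
    seed = seed,
    n_genotypes = 6L,
    reps_per_treatment = c(5L, 5L, 4L),
    days = days,
    ...
  )
}

# balanced ionome-focused config: equal replication so type I and type III
# sums of squares coincide
balanced_config <- function(seed = 42L, reps = 30L, n_genotypes = 5L, ...) {
  experiment_config(
    seed = seed,
    n_genotypes = n_genotypes,
    reps_per_treatment = rep(reps, 3L),
    days = c(8L, 26L),
    ...
  )
}

hue_cols <- sprintf("hue_%03d", 0:359)

# independent gift-wrapping (Jarvis march) convex hull for oracle checks
gift_wrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      d_c <- sum((pts[cand, ] - pts[cur, ])^2)
      if (cand == cur || cr > 1e-12 || (abs(cr) <= 1e-12 && d_j > d_c)) cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# Brute-force leave-one-out Cook's distance: refit the cell-means model
# without observation i and measure the scaled shift of all fitted values.
loo_cooks <- function(cells, y) {
  cells <- factor(cells)
  n <- length(y)
  p <- nlevels(droplevels(cells))
  means <- tapply(y, cells, mean)
  fit <- means[as.integer(cells)]
  s2 <- sum((y - fit)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    if (sum(cells == cells[i]) == 1) return(NA_real_)
    means_i <- tapply(y[-i], droplevels(cells[-i]), mean)
    fit_i <- means_i[as.character(cells)]
    sum((fit - fit_i)^2) / (p * s2)
  }, 0)
}

shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
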