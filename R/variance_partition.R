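#' Mixed-model Wald ANOVA of a trait time series
#'
#' Fits a linear mixed model of the trait with the six fixed effects
#' G, E, GxE, GxT, ExT and GxExT (genotype, treatment, and day treated as a
#' categorical time factor) and a per-plant random intercept and slope over
#' (centred) numeric day for the repeated measures. Each fixed effect is
#' tested with a type III Wald chi-square on its coefficient block under
#' sum-to-zero contrasts, i.e. adjusting for all other effects.
#'
#' If the mixed fit fails or does not converge, a fixed-effects-only linear
#' model is used instead and flagged in the output.
#'
#' @param traits trait table (`plant_id`, `genotype`, `treatment`, `day` and
#'   the response column).
#' @param response response column name (default "area").
#' @return object of class `wald_anova`: data.frame `tests` with columns
#'   `effect` (G, E, GxE, GxT, ExT, GxExT), `chisq`, `df`, `p`; plus
#'   `fallback` (TRUE when the fixed-effects model was used) and `fit`.
#' @export
mixed_model_wald <- function(traits, response = "area") {
  traits <- data.table::as.data.table(traits)
  stopifnot(all(c("plant_id", "genotype", "treatment", "day", response)
                %in% names(traits)))
  y <- traits[[response]]
  if (var(y) == 0) stop("response is constant: no variance to partition")
  d <- data.frame(
    y = y,
    G = factor(traits$genotype),
    E = factor(traits$treatment),
    T_ = factor(traits$day),
    day_c = as.numeric(traits$day) - mean(as.numeric(traits$day)),
    plant_id = factor(traits$plant_id)
  )
  stopifnot(nlevels(d$G) >= 2, nlevels(d$E) >= 2, nlevels(d$T_) >= 2)
  ctr <- list(G = "contr.sum", E = "contr.sum", T_ = "contr.sum")
  fixed <- y ~ G + E + G:E + G:T_ + E:T_ + G:E:T_

  fit <- NULL
  fallback <- FALSE
  fit <- tryCatch({
    m <- lme4::lmer(y ~ G + E + G:E + G:T_ + E:T_ + G:E:T_ +
                      (1 + day_c | plant_id),
                    data = d, contrasts = ctr, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
    conv <- m@optinfo$conv$lme4
    if (!is.null(conv$code) && conv$code < 0) NULL else m
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- lm(fixed, data = d, contrasts = ctr)
  }

  if (fallback) {
    beta <- coef(fit)
    V <- vcov(fit)
    asgn <- attr(model.matrix(fit), "assign")
    labels <- attr(terms(fit), "term.labels")
  } else {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    X <- lme4::getME(fit, "X")
    asgn <- attr(X, "assign")
    labels <- attr(terms(fixed), "term.labels")
  }
  keep <- !is.na(beta)
  pretty <- c("G" = "G", "E" = "E", "G:E" = "GxE", "G:T_" = "GxT",
              "E:T_" = "ExT", "G:E:T_" = "GxExT")
  tests <- lapply(seq_along(labels), function(ti) {
    idx <- which(asgn == ti & keep)
    if (!length(idx)) {
      return(data.frame(effect = pretty[[labels[ti]]], chisq = NA_real_,
                        df = 0L, p = NA_real_))
    }
    b <- beta[idx]
    Vb <- V[idx, idx, drop = FALSE]
    chisq <- drop(crossprod(b, solve(Vb, b)))
    data.frame(effect = pretty[[labels[ti]]], chisq = chisq,
               df = length(idx),
               p = pchisq(chisq, length(idx), lower.tail = FALSE))
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(tests = tests, fallback = fallback, fit = fit),
            class = "wald_anova")
}

#' @export
print.wald_anova <- function(x, ...) {
  cat("Type III Wald chi-square tests",
      if (x$fallback) "(fixed-effects fallback)" else "(mixed model)", "\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Type III variance partition of one response
#'
#' Partitions the total sum of squares of a response into genotype,
#' treatment, genotype-by-treatment interaction and residual fractions using
#' type III (partial) sums of squares under sum-to-zero contrasts. For
#' balanced designs this coincides with the sequential (type I)
#' decomposition; for unbalanced data each term is adjusted for all others.
#'
#' @param data table with `genotype`, `treatment` and the response column.
#' @param response response column name (an element, e.g. "Mo").
#' @return object of class `variance_partition`: named `fractions` (genotype,
#'   treatment, interaction, residual), the raw `ss`, `ss_total` and the
#'   response name. Rows with NA response are dropped.
#' @export
type3_variance_partition <- function(data, response) {
  data <- data.table::as.data.table(data)
  stopifnot(all(c("genotype", "treatment", response) %in% names(data)))
  d <- data.frame(y = data[[response]],
                  genotype = factor(data$genotype),
                  treatment = factor(data$treatment))
  d <- d[complete.cases(d), ]
  if (min(table(d$genotype, d$treatment)) < 2) {
    stop("need at least 2 replicates per genotype x treatment cell")
  }
  fit <- lm(y ~ genotype * treatment, data = d,
            contrasts = list(genotype = "contr.sum", treatment = "contr.sum"))
  dr <- drop1(fit, . ~ ., test = "F")
  ss <- dr[["Sum of Sq"]][-1]
  names(ss) <- rownames(dr)[-1]
  ss_res <- sum(resid(fit)^2)
  ss_total <- sum((d$y - mean(d$y))^2)
  fractions <- c(
    genotype = unname(ss["genotype"]) / ss_total,
    treatment = unname(ss["treatment"]) / ss_total,
    interaction = unname(ss["genotype:treatment"]) / ss_total,
    residual = ss_res / ss_total
  )
  structure(list(response = response, fractions = fractions,
                 ss = c(ss, residual = ss_res), ss_total = ss_total),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition of %s (type III SS / total SS):\n", x$response))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Per-element variance partitions of an ionome table
#'
#' Runs [type3_variance_partition()] for every element column and stacks the
#' fractions into one table, the input for "percent variance explained"
#' summaries across the ionome.
#'
#' @param ionome table with `genotype`, `treatment` and element columns.
#' @param elements element column names; defaults to all numeric columns.
#' @return data.table with `element`, `genotype`, `treatment`, `interaction`,
#'   `residual` fractions.
#' @export
partition_ionome <- function(ionome, elements = NULL) {
  ionome <- data.table::as.data.table(ionome)
  if (is.null(elements)) {
    elements <- setdiff(names(ionome)[vapply(ionome, is.numeric, TRUE)],
                        c("day", "rep"))
  }
  data.table::rbindlist(lapply(elements, function(el) {
    vp <- type3_variance_partition(ionome, el)
    data.table::data.table(element = el, t(vp$fractions))
  }))
}

#' PCA with per-group 95% confidence ellipses
#'
#' Centred (optionally unit-variance) principal component analysis with, for
#' each group, a 95% confidence ellipse of the first two component scores
#' derived from the group score covariance at the chi-square (2 df) 0.95
#' quantile. Constant columns are dropped with a warning before the
#' decomposition.
#'
#' @param x numeric matrix or data.frame of samples x variables.
#' @param groups group label per sample (e.g. treatment).
#' @param scale. divide variables by their standard deviation (TRUE for
#'   heterogeneous units such as shape features or elements; FALSE for hue
#'   bins, which share a unit).
#' @return object of class `pca_result`: `scores`, `loadings` (orthonormal
#'   rotation), `var_explained` (percent per PC, non-increasing), `center`,
#'   `scale`, and `ellipses` (per group: center, semi-axis lengths, angle in
#'   degrees).
#' @export
pca_with_ellipses <- function(x, groups = NULL, scale. = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) > 2)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant column(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  ellipses <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(x))
    r2 <- qchisq(0.95, df = 2)
    ellipses <- lapply(split(seq_len(nrow(x)), groups), function(i) {
      s <- pc$x[i, 1:2, drop = FALSE]
      if (nrow(s) < 3) return(NULL)
      cv <- cov(s)
      e <- eigen(cv, symmetric = TRUE)
      list(center = colMeans(s),
           axes = sqrt(pmax(e$values, 0) * r2),
           angle = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi)
    })
  }
  structure(list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
                 center = pc$center, scale = pc$scale, ellipses = ellipses),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d PCs; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              x$var_explained[1],
              if (length(x$var_explained) > 1) x$var_explained[2] else 0))
  invisible(x)
}
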