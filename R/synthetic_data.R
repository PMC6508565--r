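#' Configure a synthetic phenotyping experiment
#'
#' Builds the full parameter set for a simulated nitrogen-deprivation
#' phenotyping run: a genotype panel with logistic growth parameters, ordered
#' treatments with multiplicative area penalties that switch on at a
#' genotype-specific onset day, yellowing (hue) kinetics peaking mid
#' experiment, and an end-of-experiment leaf ionome with configurable
#' genotype/treatment/interaction variance fractions per element.
#'
#' Defaults reproduce the design of the emulated experiment: 30 genotypes,
#' treatments "100/100", "50/10", "10/10" with 9/9/6 replicates, daily imaging
#' on days 8--26, multiplicative lognormal area noise with CV 0.2, and an even
#' split of early (onset days 10--12) versus late (onset days 19--21)
#' responding genotypes.
#'
#' @param seed integer seed; all per-genotype parameters are drawn from it.
#' @param n_genotypes number of genotypes in the panel.
#' @param treatments ordered treatment labels; the first is the control.
#' @param reps_per_treatment replicate plants per genotype for each treatment.
#' @param days integer vector of imaging days.
#' @param treatment_effect named multiplicative area penalty per treatment
#'   (1 = no penalty), applied from the genotype's onset day onward.
#' @param growth_cv coefficient of variation of the multiplicative lognormal
#'   area noise.
#' @param early_frac fraction of genotypes assigned an early onset day.
#' @param onset_early,onset_late candidate onset days for early/late genotypes.
#' @param yellow_base baseline yellow fraction of the hue mixture.
#' @param yellow_amp named per-treatment amplitude of the yellowing pulse.
#' @param yellow_peak_day,yellow_peak_width centre (day) and width (days, SD)
#'   of the Gaussian yellowing pulse.
#' @param yellow_stress_extra additional yellow fraction in non-control
#'   treatments once the genotype's onset day is reached.
#' @param yellow_late_control_extra additional amplitude of the yellowing
#'   pulse for late-responding genotypes in the control treatment (late lines
#'   yellow visibly even under full nitrogen while early lines stay green).
#' @param yellow_mode,green_mode,hue_sd hue mixture component modes and SD
#'   (degrees); yellow is truncated to [0, 60], green to [61, 120].
#' @param outlier_rate,outlier_magnitude fraction of trait records corrupted
#'   and the multiplicative factor applied to their area.
#' @param elements ionome element names.
#' @param ionome_fractions data.frame with columns `element`, `genotype`,
#'   `treatment`, `interaction`, `residual` (variance fractions, each in
#'   [0, 1], summing to at most 1 per element), or NULL for defaults.
#' @param ionome_cv total coefficient of variation of each element around its
#'   typical concentration.
#'
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              n_genotypes = 30L,
                              treatments = c("100/100", "50/10", "10/10"),
                              reps_per_treatment = c(9L, 9L, 6L),
                              days = 8:26,
                              treatment_effect = c("100/100" = 1, "50/10" = 0.7, "10/10" = 0.5),
                              growth_cv = 0.2,
                              early_frac = 0.5,
                              onset_early = 10:12,
                              onset_late = 19:21,
                              yellow_base = 0.15,
                              yellow_amp = c("100/100" = 0.10, "50/10" = 0.30, "10/10" = 0.40),
                              yellow_peak_day = 13,
                              yellow_peak_width = 3,
                              yellow_stress_extra = 0.05,
                              yellow_late_control_extra = 0.08,
                              yellow_mode = 45,
                              green_mode = 100,
                              hue_sd = 8,
                              outlier_rate = 0,
                              outlier_magnitude = 5,
                              elements = NULL,
                              ionome_fractions = NULL,
                              ionome_cv = 0.25) {
  stopifnot(n_genotypes >= 2, length(treatments) >= 2,
            length(reps_per_treatment) == length(treatments),
            all(reps_per_treatment >= 2),
            length(days) >= 2, growth_cv >= 0,
            outlier_rate >= 0, outlier_rate < 1, outlier_magnitude > 0)
  if (is.null(names(treatment_effect))) names(treatment_effect) <- treatments
  if (is.null(names(yellow_amp))) names(yellow_amp) <- treatments
  stopifnot(all(treatments %in% names(treatment_effect)),
            all(treatments %in% names(yellow_amp)))
  if (any(c(onset_early, onset_late) < min(days) |
          c(onset_early, onset_late) > max(days))) {
    stop("onset days must lie within the experiment day range")
  }

  genotypes <- sprintf("G%02d", seq_len(n_genotypes))
  n_early <- round(early_frac * n_genotypes)

  params <- with_seed(seed, {
    lab <- rep("late", n_genotypes)
    lab[sample.int(n_genotypes, n_early)] <- "early"
    data.frame(
      genotype   = genotypes,
      asymptote  = 50000 * exp(rnorm(n_genotypes, 0, 0.15)),
      rate       = runif(n_genotypes, 0.35, 0.55),
      inflection = runif(n_genotypes, 16, 20),
      onset_day  = ifelse(lab == "early",
                          sample(onset_early, n_genotypes, replace = TRUE),
                          sample(onset_late,  n_genotypes, replace = TRUE)),
      label      = lab,
      stringsAsFactors = FALSE
    )
  })

  if (is.null(elements)) {
    elements <- c("B", "Na", "Mg", "Al", "P", "S", "K", "Ca", "Mn", "Fe",
                  "Co", "Ni", "Cu", "Zn", "As", "Se", "Rb", "Mo")
  }
  baseline <- c(B = 15, Na = 120, Mg = 4000, Al = 40, P = 3000, S = 1500,
                K = 25000, Ca = 4500, Mn = 60, Fe = 100, Co = 0.3, Ni = 1.5,
                Cu = 8, Zn = 35, As = 0.1, Se = 0.5, Rb = 15, Mo = 1.2)
  base_ppm <- ifelse(elements %in% names(baseline), baseline[elements], 10)
  if (is.null(ionome_fractions)) {
    ionome_fractions <- data.frame(
      element = elements, genotype = 0.30, treatment = 0.30,
      interaction = 0.10, residual = 0.30, stringsAsFactors = FALSE
    )
    # genotype-dominated and treatment-dominated elements, mimicking panels
    # where trace metals track genotype and macronutrients track nitrogen
    ionome_fractions[ionome_fractions$element %in% c("Mo", "Co"),
                     c("genotype", "treatment", "interaction", "residual")] <-
      rep(c(0.55, 0.15, 0.05, 0.25), each = sum(elements %in% c("Mo", "Co")))
    ionome_fractions[ionome_fractions$element == "P",
                     c("genotype", "treatment", "interaction", "residual")] <-
      c(0.10, 0.55, 0.10, 0.25)
  }
  fr <- ionome_fractions[, c("genotype", "treatment", "interaction", "residual")]
  stopifnot(all(fr >= 0), all(fr <= 1), all(rowSums(fr) <= 1 + 1e-8))

  cfg <- list(
    seed = as.integer(seed),
    genotypes = genotypes, treatments = treatments,
    reps_per_treatment = setNames(as.integer(reps_per_treatment), treatments),
    days = as.integer(days),
    growth = params,
    treatment_effect = treatment_effect[treatments],
    growth_cv = growth_cv,
    yellow_base = yellow_base, yellow_amp = yellow_amp[treatments],
    yellow_peak_day = yellow_peak_day, yellow_peak_width = yellow_peak_width,
    yellow_stress_extra = yellow_stress_extra,
    yellow_late_control_extra = yellow_late_control_extra,
    yellow_mode = yellow_mode, green_mode = green_mode, hue_sd = hue_sd,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    elements = elements, base_ppm = setNames(base_ppm, elements),
    ionome_fractions = ionome_fractions, ionome_cv = ionome_cv
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Synthetic phenotyping experiment configuration\n")
  cat(sprintf("  %d genotypes x %d treatments (%s), reps %s\n",
              length(x$genotypes), length(x$treatments),
              paste(x$treatments, collapse = ", "),
              paste(x$reps_per_treatment, collapse = "/")))
  cat(sprintf("  days %d-%d, growth CV %.2f, outlier rate %.2f, seed %d\n",
              min(x$days), max(x$days), x$growth_cv, x$outlier_rate, x$seed))
  invisible(x)
}

#' Logistic growth curve with treatment onset
#'
#' Expected projected plant area (px) on a given day: a logistic curve
#' `A / (1 + exp(-r (day - t0)))` scaled by the treatment's multiplicative
#' penalty from the genotype's onset day onward. Before the onset day all
#' treatments coincide; a `treatment_effect` of 1 leaves the curve untouched.
#'
#' @param asymptote logistic asymptote A (px), positive.
#' @param rate logistic growth rate r (per day), positive.
#' @param inflection day of the inflection point t0.
#' @param day day(s) at which to evaluate the curve.
#' @param treatment_effect multiplicative penalty in (0, 1] applied from
#'   `onset_day` onward.
#' @param onset_day first day on which the treatment penalty acts.
#' @return expected area in pixels, vectorised over `day`.
#' @export
growth_curve <- function(asymptote, rate, inflection, day,
                         treatment_effect = 1, onset_day = Inf) {
  if (any(asymptote <= 0)) stop("asymptote must be positive")
  if (any(rate <= 0)) stop("rate must be positive")
  base <- asymptote / (1 + exp(-rate * (day - inflection)))
  base * ifelse(day >= onset_day, treatment_effect, 1)
}

#' Yellow fraction of the hue mixture for given conditions
#'
#' The ground-truth fraction of foreground pixels belonging to the yellow hue
#' component: a baseline plus a Gaussian pulse centred mid experiment whose
#' amplitude depends on treatment, plus a stress increment in non-control
#' treatments once the genotype's onset day has passed. Clamped to [0, 1].
#'
#' @param config an [experiment_config()].
#' @param genotype,treatment,day vectors (recycled) identifying the condition.
#' @return yellow mixture weight(s) in [0, 1].
#' @export
yellow_fraction_curve <- function(config, genotype, treatment, day) {
  gi <- match(genotype, config$growth$genotype)
  onset <- config$growth$onset_day[gi]
  is_late <- config$growth$label[gi] == "late"
  pulse <- exp(-0.5 * ((day - config$yellow_peak_day) / config$yellow_peak_width)^2)
  extra <- (config$yellow_late_control_extra %||% 0) *
    (is_late & treatment == config$treatments[1])
  yf <- config$yellow_base +
    (unname(config$yellow_amp[treatment]) + extra) * pulse +
    config$yellow_stress_extra * (treatment != config$treatments[1] & day >= onset)
  pmin(pmax(yf, 0), 1)
}

# Hue mixture component densities over integer degrees 0..359: truncated
# normals so that the yellow component lives entirely in [0, 60] degrees and
# the green component in [61, 120].
hue_component_densities <- function(config) {
  deg <- 0:359
  dy <- stats::dnorm(deg, config$yellow_mode, config$hue_sd)
  dy[deg > 60] <- 0
  dg <- stats::dnorm(deg, config$green_mode, config$hue_sd)
  dg[deg < 61 | deg > 120] <- 0
  list(yellow = dy / sum(dy), green = dg / sum(dg))
}

#' Generate a complete synthetic experiment
#'
#' Simulates trait records (one plant per day), per-plant hue histograms and
#' an end-of-experiment leaf ionome, with full ground truth. Areas follow
#' [growth_curve()] with multiplicative lognormal noise; hue histograms are
#' multinomial draws from a two-component (yellow/green) mixture with the
#' weight given by [yellow_fraction_curve()]; element concentrations follow an
#' additive genotype + treatment + interaction model whose effect vectors are
#' rescaled to hit the configured variance fractions exactly. If
#' `config$outlier_rate > 0` gross area outliers are injected and flagged in
#' the ground truth.
#'
#' The same config (and therefore seed) always reproduces identical tables.
#'
#' @param config an [experiment_config()].
#' @param with_histograms,with_ionome generate the hue histogram / ionome
#'   tables (switch off for speed when only trait records are needed).
#' @return a list of class `pheno_experiment` with elements `traits`
#'   (data.table: plant_id, genotype, treatment, day, 16 shape columns),
#'   `histograms` (data.table: plant_id, genotype, treatment, day,
#'   hue_000..hue_359 raw counts), `ionome` (data.table: plant_id, genotype,
#'   treatment, one ppm column per element) and `truth` (outlier flags,
#'   early/late labels with onset days, per-record yellow fractions, element
#'   variance fractions).
#' @export
generate_experiment <- function(config, with_histograms = TRUE, with_ionome = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  with_seed(config$seed, {
    plants <- data.table::CJ(genotype = config$genotypes,
                             treatment = config$treatments, sorted = FALSE)
    plants <- plants[rep(seq_len(nrow(plants)),
                         config$reps_per_treatment[plants$treatment])]
    plants[, rep := seq_len(.N), by = .(genotype, treatment)]
    plants[, plant_id := sprintf("%s_%s_r%02d", genotype,
                                 gsub("/", "-", treatment), rep)]

    traits <- plants[rep(seq_len(nrow(plants)), each = length(config$days))]
    traits[, day := rep(config$days, nrow(plants))]

    gp <- config$growth[match(traits$genotype, config$growth$genotype), ]
    mu <- growth_curve(gp$asymptote, gp$rate, gp$inflection, traits$day,
                       unname(config$treatment_effect[traits$treatment]),
                       gp$onset_day)
    sdlog <- sqrt(log(1 + config$growth_cv^2))
    traits[, area := mu * exp(rnorm(.N, -sdlog^2 / 2, sdlog))]

    # correlated companion shape features so shape PCA has a full 16-column
    # input; all derived from area with independent noise
    n <- nrow(traits)
    r_eq <- sqrt(traits$area / pi)
    solidity <- 1 / (1 + exp(-rnorm(n, 0.62, 0.25)))
    traits[, `:=`(
      hull_area = area / solidity,
      solidity = solidity,
      perimeter = 2 * pi * r_eq / solidity * exp(rnorm(n, 0, 0.05)),
      width = 2 * r_eq * exp(rnorm(n, 0.18, 0.08)),
      height = 2 * r_eq * exp(rnorm(n, 0.18, 0.08))
    )]
    traits[, `:=`(
      longest_axis = pmax(width, height) * exp(rnorm(n, 0.05, 0.03)),
      com_x = rnorm(n, 250, 8),
      com_y = rnorm(n, 300, 8) - r_eq / 4,
      hull_vertices = 3 + rpois(n, 15)
    )]
    traits[, `:=`(
      ellipse_cx = com_x + rnorm(n, 0, 2),
      ellipse_cy = com_y + rnorm(n, 0, 2),
      ellipse_major = longest_axis * exp(rnorm(n, -0.05, 0.03)),
      ellipse_minor = pmin(width, height) * exp(rnorm(n, -0.05, 0.03)),
      ellipse_angle = runif(n, 0, 180)
    )]
    traits[, ellipse_eccentricity :=
             sqrt(pmax(0, 1 - (pmin(ellipse_minor, ellipse_major) /
                               pmax(ellipse_minor, ellipse_major))^2))]
    traits[, c("rep") := NULL]
    data.table::setcolorder(traits, c("plant_id", "genotype", "treatment", "day"))

    yf <- yellow_fraction_curve(config, traits$genotype, traits$treatment, traits$day)
    truth_yellow <- traits[, .(plant_id, day)][, yellow_fraction := yf]

    histograms <- NULL
    if (with_histograms) {
      comp <- hue_component_densities(config)
      npix <- pmax(1L, as.integer(round(traits$area)))
      # exact split between components so the yellow-band mass matches the
      # configured fraction to within rounding, then multinomial within each
      n_yellow <- as.integer(round(yf * npix))
      counts <- matrix(0L, n, 360L)
      for (i in seq_len(n)) {
        cy <- if (n_yellow[i] > 0) {
          rmultinom(1L, n_yellow[i], comp$yellow)
        } else 0L
        cg <- if (npix[i] - n_yellow[i] > 0) {
          rmultinom(1L, npix[i] - n_yellow[i], comp$green)
        } else 0L
        counts[i, ] <- cy + cg
      }
      colnames(counts) <- sprintf("hue_%03d", 0:359)
      histograms <- cbind(traits[, .(plant_id, genotype, treatment, day)],
                          data.table::as.data.table(counts))
    }

    ionome <- NULL
    if (with_ionome) {
      ionome <- plants[, .(plant_id, genotype, treatment)]
      frs <- config$ionome_fractions
      for (el in config$elements) {
        mu_e <- config$base_ppm[[el]]
        V <- (config$ionome_cv * mu_e)^2
        f <- frs[frs$element == el, ]
        g <- scale_to_var(rnorm(length(config$genotypes)), f$genotype * V)
        t_ <- scale_to_var(rnorm(length(config$treatments)), f$treatment * V)
        gt <- matrix(rnorm(length(g) * length(t_)), length(g))
        gt <- gt - rowMeans(gt)
        gt <- sweep(gt, 2, colMeans(gt))
        gt <- scale_to_var(gt, f$interaction * V)
        gi <- match(ionome$genotype, config$genotypes)
        ti <- match(ionome$treatment, config$treatments)
        # residuals are centred within each genotype x treatment cell and
        # rescaled, so the realized variance components equal the configured
        # fractions exactly (the generator's contract) rather than only in
        # expectation
        eps <- rnorm(nrow(ionome))
        cell <- interaction(gi, ti)
        eps <- eps - stats::ave(eps, cell)
        eps <- scale_to_var(eps, f$residual * V)
        ionome[, (el) := mu_e + g[gi] + t_[ti] + gt[cbind(gi, ti)] + eps]
      }
    }

    outlier_flags <- rep(FALSE, n)
    if (config$outlier_rate > 0) {
      inj <- inject_outliers(traits, config$outlier_rate,
                             config$outlier_magnitude, seed = NULL)
      traits <- inj$traits
      outlier_flags <- inj$flags
    }

    truth <- list(
      outliers = traits[, .(plant_id, day)][, flagged := outlier_flags],
      labels = data.frame(genotype = config$growth$genotype,
                          onset_day = config$growth$onset_day,
                          label = config$growth$label,
                          stringsAsFactors = FALSE),
      yellow = truth_yellow,
      ionome_fractions = config$ionome_fractions
    )
    out <- list(traits = traits[], histograms = histograms,
                ionome = ionome, truth = truth, config = config)
    class(out) <- "pheno_experiment"
    out
  })
}

# Centre a numeric vector/matrix and rescale so its population variance
# (denominator n) equals `v` exactly; all-zero input stays zero when v is 0.
scale_to_var <- function(x, v) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (v == 0) return(x * 0)
  if (s2 == 0) stop("cannot scale a constant vector to positive variance")
  x * sqrt(v / s2)
}

#' @export
print.pheno_experiment <- function(x, ...) {
  cat(sprintf("Synthetic phenotyping experiment: %d trait records, %d plants\n",
              nrow(x$traits), length(unique(x$traits$plant_id))))
  cat(sprintf("  histograms: %s; ionome: %s; seed %d\n",
              if (is.null(x$histograms)) "no" else "yes",
              if (is.null(x$ionome)) "no" else "yes", x$config$seed))
  invisible(x)
}

#' Inject gross area outliers into a trait table
#'
#' Each record is independently corrupted with probability `rate`: its area is
#' multiplied or divided (coin flip) by `magnitude`. Returns the corrupted
#' table together with the ground-truth flags; these are the positives the
#' influence filter is expected to recover.
#'
#' @param traits trait table with an `area` column.
#' @param rate corruption probability in [0, 1).
#' @param magnitude multiplicative corruption factor (1 leaves values
#'   unchanged but still flags the selected records).
#' @param seed optional seed; NULL draws from the current RNG stream.
#' @return list with `traits` (copy) and logical `flags`.
#' @export
inject_outliers <- function(traits, rate, magnitude, seed = NULL) {
  stopifnot(rate >= 0, rate < 1, magnitude > 0)
  with_seed(seed, {
    traits <- data.table::as.data.table(traits)[]
    traits <- data.table::copy(traits)
    flags <- runif(nrow(traits)) < rate
    if (any(flags)) {
      updown <- sample(c(TRUE, FALSE), sum(flags), replace = TRUE)
      fac <- ifelse(updown, magnitude, 1 / magnitude)
      traits[flags, area := area * fac]
    }
    list(traits = traits, flags = flags)
  })
}

#' Render a synthetic plant image and its mask
#'
#' Draws a single connected blob of exactly `area_px` foreground pixels
#' (pixels nearest the canvas centre under a jittered distance, so the outline
#' is irregular but compact) on a uniform background colour whose hue lies
#' outside the plant range. Foreground pixel hues are drawn from the
#' yellow/green mixture: exactly `round(yellow_fraction * area_px)` pixels get
#' yellow hues in [0, 60] degrees and the rest green hues in [61, 120].
#'
#' @param area_px number of foreground pixels to draw.
#' @param yellow_fraction fraction of foreground pixels with yellow hue.
#' @param canvas_size `c(height, width)` in pixels.
#' @param seed optional seed; NULL draws from the current RNG stream.
#' @param background_rgb background colour, RGB in 0--255 (default a blue,
#'   hue 240 degrees, far from the plant hues).
#' @return list with `image` (height x width x 3 array, 0--255) and `mask`
#'   (logical matrix).
#' @export
render_plant_image <- function(area_px, yellow_fraction, canvas_size = c(100L, 100L),
                               seed = NULL, background_rgb = c(30, 30, 180)) {
  stopifnot(length(canvas_size) == 2, area_px >= 0,
            yellow_fraction >= 0, yellow_fraction <= 1)
  h <- canvas_size[1]; w <- canvas_size[2]
  if (area_px > h * w) stop("requested area exceeds canvas size")
  with_seed(seed, {
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- background_rgb[1]
    img[, , 2] <- background_rgb[2]
    img[, , 3] <- background_rgb[3]
    mask <- matrix(FALSE, h, w)
    if (area_px > 0) {
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      d <- sqrt((yy - (h + 1) / 2)^2 + (xx - (w + 1) / 2)^2) +
        runif(h * w, 0, 0.45)
      sel <- order(d)[seq_len(area_px)]
      mask[sel] <- TRUE
      n_yellow <- round(yellow_fraction * area_px)
      hues <- c(pmin(pmax(rnorm(n_yellow, 45, 8), 0), 60),
                pmin(pmax(rnorm(area_px - n_yellow, 100, 8), 61), 120))
      hues <- sample(hues)
      rgb <- col2rgb(hsv(hues / 360, s = 0.85, v = 0.8))
      fg <- which(mask)
      img[fg] <- rgb[1, ]
      img[fg + h * w] <- rgb[2, ]
      img[fg + 2 * h * w] <- rgb[3, ]
    }
    list(image = img, mask = mask)
  })
}
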