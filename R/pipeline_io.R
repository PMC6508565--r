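#' Pipeline run configuration
#'
#' Bundles every stage's parameters with explicit defaults that reproduce the
#' standard analysis settings: influence cutoff 4x the mean Cook's distance,
#' MAD cutoff 6.2, yellow band 0--60 and green band 61--120 degrees, global
#' BH correction with onset threshold q < 0.05, dendrogram cut at k = 2,
#' growth-rate window days 10--22 and end-size evaluation on day 26 in the
#' "10/10" treatment with stars at q < 0.01.
#'
#' @param seed master seed; the synthetic experiment uses it directly.
#' @param experiment an [experiment_config()]; built from `seed` if NULL.
#' @param outdir output directory for stage tables and the manifest.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "color", "timing", "variance")`.
#' @param influence_mult,mad_cutoff,q_alpha,star_q,k thresholds (see above).
#' @param yellow_band,green_band integer degree bands.
#' @param bh_scope "global" or "by_genotype" BH correction scope.
#' @param pair treatment pair for the q-value matrix.
#' @param growth_window,end_day growth-rate day window and end-size day.
#' @param mixed_model run the mixed-model Wald ANOVA stage (slow for large
#'   panels; the type III ionome partition always runs in "variance").
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       experiment = NULL,
                       outdir = "results/pipeline",
                       stages = c("simulate", "qc", "color", "timing", "variance"),
                       influence_mult = 4,
                       mad_cutoff = 6.2,
                       q_alpha = 0.05,
                       star_q = 0.01,
                       k = 2,
                       yellow_band = c(0, 60),
                       green_band = c(61, 120),
                       bh_scope = "global",
                       pair = c("100/100", "10/10"),
                       growth_window = c(10, 22),
                       end_day = 26,
                       mixed_model = FALSE) {
  if (is.null(experiment)) experiment <- experiment_config(seed = seed)
  cfg <- list(seed = as.integer(seed), experiment = experiment, outdir = outdir,
              stages = stages, influence_mult = influence_mult,
              mad_cutoff = mad_cutoff, q_alpha = q_alpha, star_q = star_q,
              k = k, yellow_band = yellow_band, green_band = green_band,
              bh_scope = bh_scope, pair = pair,
              growth_window = growth_window, end_day = end_day,
              mixed_model = mixed_model)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes `simulate -> qc -> color -> timing -> variance` with the settings
#' in a [run_config()], writes every stage's tables as plain CSV plus a JSON
#' manifest (seeds, row counts, removal fractions, md5 hashes) and returns
#' the in-memory results. Re-running with the same config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  manifest <- list(seed = config$seed, stages = list())
  out <- list(config = config)

  if (!("simulate" %in% config$stages) &&
      !file.exists(file.path(config$outdir, "traits.csv"))) {
    stop(sprintf("stage %s: input trait table not found at %s (enable the simulate stage or provide traits.csv)",
                 config$stages[1], file.path(config$outdir, "traits.csv")))
  }

  if ("simulate" %in% config$stages) {
    say("simulate: generating synthetic experiment (seed %d)", config$experiment$seed)
    exp <- generate_experiment(config$experiment)
    out$experiment <- exp
    paths$traits <- file.path(config$outdir, "traits.csv")
    write_trait_table(exp$traits, paths$traits)
    paths$histograms <- file.path(config$outdir, "hues.csv")
    data.table::fwrite(exp$histograms, paths$histograms)
    paths$ionome <- file.path(config$outdir, "ionome.csv")
    data.table::fwrite(exp$ionome, paths$ionome)
    paths$truth <- file.path(config$outdir, "ground_truth.json")
    jsonlite::write_json(list(labels = exp$truth$labels,
                              n_outliers = sum(exp$truth$outliers$flagged),
                              ionome_fractions = exp$truth$ionome_fractions),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    manifest$stages$simulate <- list(
      n_trait_records = nrow(exp$traits),
      n_plants = length(unique(exp$traits$plant_id)),
      n_outliers_injected = sum(exp$truth$outliers$flagged))
  } else {
    exp <- list(traits = read_trait_table(file.path(config$outdir, "traits.csv")),
                histograms = data.table::fread(file.path(config$outdir, "hues.csv")),
                ionome = data.table::fread(file.path(config$outdir, "ionome.csv")))
    out$experiment <- exp
  }

  traits_qc <- exp$traits
  if ("qc" %in% config$stages) {
    qc <- flag_influence_outliers(exp$traits, threshold_mult = config$influence_mult)
    traits_qc <- qc$traits
    say("qc: removed %.2f%% of trait records (threshold %.3g)",
        100 * qc$removal_fraction, qc$influence$threshold)
    ion <- mad_filter_ionome(exp$ionome, cutoff = config$mad_cutoff)
    out$qc <- qc
    out$ionome_qc <- ion
    paths$traits_filtered <- file.path(config$outdir, "traits_filtered.csv")
    write_trait_table(traits_qc, paths$traits_filtered)
    manifest$stages$qc <- list(
      removal_fraction = qc$removal_fraction,
      n_removed = sum(qc$influence$flags),
      ionome_flags = as.list(ion$n_flagged))
  }

  if ("timing" %in% config$stages) {
    qm <- qvalue_matrix(traits_qc, pair = config$pair, bh_scope = config$bh_scope)
    hc <- ward_dendrogram(canberra_matrix(qm$neglog_q))
    labels <- split_early_late(hc, qm, k = config$k, alpha = config$q_alpha)
    rates <- growth_rate(traits_qc, window = config$growth_window)
    enders <- end_size_outperformers(traits_qc, day = config$end_day,
                                     star_q = config$star_q)
    say("timing: %d early / %d late responders; %d genotypes starred at q < %.2g",
        sum(labels$label == "early"), sum(labels$label == "late"),
        sum(enders$starred), config$star_q)
    out$timing <- list(qmatrix = qm, dendrogram = hc, labels = labels,
                       growth_rates = rates, end_size = enders)
    paths$qmatrix <- file.path(config$outdir, "qmatrix.csv")
    data.table::fwrite(data.table::data.table(genotype = qm$genotypes, qm$q),
                       paths$qmatrix)
    paths$labels <- file.path(config$outdir, "responder_labels.csv")
    data.table::fwrite(labels, paths$labels)
    paths$growth_rates <- file.path(config$outdir, "growth_rates.csv")
    data.table::fwrite(rates, paths$growth_rates)
    paths$end_size <- file.path(config$outdir, "end_size.csv")
    data.table::fwrite(enders, paths$end_size)
    manifest$stages$timing <- list(
      n_early = sum(labels$label == "early"),
      n_late = sum(labels$label == "late"),
      n_starred = sum(enders$starred))
  }

  if ("color" %in% config$stages) {
    hists <- exp$histograms
    if (!is.null(out$timing)) {
      # early/late responder kinetics within each treatment group
      lab <- out$timing$labels
      hists <- data.table::as.data.table(hists)
      hists[, responder := paste(lab$label[match(genotype, lab$genotype)],
                                 treatment)]
      grp_col <- "responder"
    } else {
      grp_col <- "treatment"
    }
    auc <- auc_time_series(hists, group_col = grp_col,
                           yellow = config$yellow_band, green = config$green_band)
    say("color: AUC series for %d group x day cells", nrow(auc$series))
    out$color <- auc
    paths$auc_series <- file.path(config$outdir, "auc_series.csv")
    data.table::fwrite(auc$series, paths$auc_series)
    manifest$stages$color <- list(n_series_rows = nrow(auc$series))
  }

  if ("variance" %in% config$stages) {
    parts <- partition_ionome(exp$ionome,
                              elements = config$experiment$elements)
    out$variance <- list(ionome_partitions = parts)
    if (config$mixed_model) {
      out$variance$wald <- mixed_model_wald(traits_qc)
    }
    shape_cols <- c("area", "hull_area", "solidity", "perimeter", "width",
                    "height", "longest_axis", "com_x", "com_y", "hull_vertices",
                    "ellipse_cx", "ellipse_cy", "ellipse_major", "ellipse_minor",
                    "ellipse_angle", "ellipse_eccentricity")
    end_traits <- data.table::as.data.table(traits_qc)[day == max(day)]
    out$variance$shape_pca <- pca_with_ellipses(
      end_traits[, shape_cols, with = FALSE],
      groups = end_traits$treatment, scale. = TRUE)
    ion_cols <- config$experiment$elements
    out$variance$ionome_pca <- pca_with_ellipses(
      as.matrix(data.table::as.data.table(exp$ionome)[, ion_cols, with = FALSE]),
      groups = exp$ionome$treatment, scale. = TRUE)
    say("variance: partitioned %d elements; shape PC1 %.1f%%",
        nrow(parts), out$variance$shape_pca$var_explained[1])
    paths$partitions <- file.path(config$outdir, "ionome_partitions.csv")
    data.table::fwrite(parts, paths$partitions)
    manifest$stages$variance <- list(n_elements = nrow(parts))
  }

  manifest$files <- lapply(paths, function(p)
    list(path = p, md5 = unname(tools::md5sum(p)), bytes = file.size(p)))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  out$manifest_path <- manifest_path
  invisible(out)
}

trait_id_cols <- c("plant_id", "genotype", "treatment", "day")

#' Read / write long-format trait tables
#'
#' Plain-CSV round trip for the long trait schema (`plant_id`, `genotype`,
#' `treatment`, `day`, trait columns). Reading validates the schema and
#' reports offending row numbers for malformed day values.
#'
#' @param path file path.
#' @return `read_trait_table`: a data.table.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  dt <- data.table::fread(path)
  missing <- setdiff(c(trait_id_cols, "area"), names(dt))
  if (length(missing)) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "))
  }
  day_num <- suppressWarnings(as.numeric(dt$day))
  bad <- which(is.na(day_num) | day_num != round(day_num))
  if (length(bad)) {
    stop("malformed day value at row(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  dt[, day := as.integer(day_num)]
  dt[]
}

#' @rdname read_trait_table
#' @param table trait table to write.
#' @export
write_trait_table <- function(table, path) {
  table <- data.table::as.data.table(table)
  missing <- setdiff(c(trait_id_cols, "area"), names(table))
  if (length(missing)) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "))
  }
  data.table::fwrite(table, path)
  invisible(path)
}

#' Read / write plain-text PNM images
#'
#' Minimal ASCII PNM support used to persist synthetic images and masks as
#' text: P3 (RGB) for images, P2 (greyscale; masks as 0/1) for masks.
#'
#' @param path file path.
#' @return `read_pnm`: a height x width x 3 array (P3) or matrix (P2).
#' @export
read_pnm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- tok[1]
  if (!magic %in% c("P2", "P3")) stop("unsupported PNM magic: ", magic)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (magic == "P2") {
    matrix(vals, h, w, byrow = TRUE)
  } else {
    px <- matrix(vals, ncol = 3, byrow = TRUE)
    arr <- array(0, c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- matrix(px[, ch], h, w, byrow = TRUE)
    arr
  }
}

#' @rdname read_pnm
#' @param x image array (h x w x 3) or matrix (mask / greyscale).
#' @param maxval maximum sample value declared in the header.
#' @export
write_pnm <- function(x, path, maxval = 255) {
  if (is.matrix(x)) {
    header <- c("P2", paste(ncol(x), nrow(x)), as.character(maxval))
    body <- apply(round(x), 1, paste, collapse = " ")
  } else {
    stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
    header <- c("P3", paste(dim(x)[2], dim(x)[1]), as.character(maxval))
    flat <- matrix(aperm(round(x), c(3, 2, 1)), nrow = 3)
    body <- vapply(seq_len(dim(x)[1]), function(i) {
      cols <- seq.int((i - 1) * dim(x)[2] + 1, i * dim(x)[2])
      paste(flat[, cols], collapse = " ")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
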