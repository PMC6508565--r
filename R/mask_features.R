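#' Segment a plant from a uniform background
#'
#' Minimal colour-threshold segmenter: a pixel is foreground when its
#' Euclidean RGB distance from the background colour exceeds `tolerance`.
#' Designed for scenes with a fixed, distinct background colour (as produced
#' by [render_plant_image()]); an image with no foreground returns an
#' all-FALSE mask rather than an error.
#'
#' @param image height x width x 3 array, channels 0--255.
#' @param background_color RGB triplet of the background, 0--255.
#' @param tolerance distance threshold; 0 marks every pixel that differs from
#'   the background at all.
#' @return logical matrix of the same height/width.
#' @export
segment_plant <- function(image, background_color = c(30, 30, 180), tolerance = 30) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, length(background_color) == 3)
  d2 <- (image[, , 1] - background_color[1])^2 +
        (image[, , 2] - background_color[2])^2 +
        (image[, , 3] - background_color[3])^2
  d2 > tolerance^2
}

#' Extract the 16 shape features of a binary plant mask
#'
#' Computes the standard parameterization of a segmented plant: area, hull
#' area, solidity, perimeter, width, height, longest axis, centre of mass
#' (x, y), hull vertex count, and the moment-equivalent ellipse (centre,
#' major/minor axis, angle, eccentricity) -- 16 features in total.
#'
#' Conventions: image coordinates with the origin at the top-left pixel
#' centre, x rightward, y downward, 0-based. Area is the foreground pixel
#' count. The convex hull is taken over the four corner points of every
#' foreground pixel (centres offset by half a pixel), so a filled convex
#' region has solidity exactly 1 and hull_area is never smaller than area.
#' Perimeter is the crack perimeter: the number of unit pixel edges between
#' foreground and background. The longest axis is the maximal pairwise
#' distance between hull vertices. The ellipse derives from the second
#' central moments of the pixel centres; its angle is the major-axis
#' orientation in degrees within [0, 180).
#'
#' Masks with fewer than 3 foreground pixels yield NA for the hull- and
#' ellipse-derived fields (flagged partial result); an empty mask is an error.
#'
#' @param mask logical matrix, TRUE = plant.
#' @return one-row data.frame with exactly 16 numeric columns.
#' @export
extract_shape_features <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("no plant: mask has no foreground pixels")
  x <- idx[, 2] - 1  # 0-based pixel centres
  y <- idx[, 1] - 1

  area <- n
  width <- diff(range(x)) + 1
  height <- diff(range(y)) + 1
  com_x <- mean(x)
  com_y <- mean(y)

  # crack perimeter: foreground pixel edges adjacent to background/border
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
  perimeter <- sum(core & !m[1:nrow(mask), 2:(ncol(mask) + 1)]) +
               sum(core & !m[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)]) +
               sum(core & !m[2:(nrow(mask) + 1), 1:ncol(mask)]) +
               sum(core & !m[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)])

  hull_area <- solidity <- longest_axis <- hull_vertices <- NA_real_
  ellipse <- rep(NA_real_, 6)
  if (n >= 3) {
    corners <- cbind(c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
                     c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
    hi <- chull(corners)
    hv <- corners[hi, , drop = FALSE]
    hull_vertices <- nrow(hv)
    hull_area <- polygon_area(hv)
    solidity <- area / hull_area
    longest_axis <- max_pairwise_distance(hv)

    mxx <- mean((x - com_x)^2)
    myy <- mean((y - com_y)^2)
    mxy <- mean((x - com_x) * (y - com_y))
    common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    l1 <- (mxx + myy + common) / 2
    l2 <- (mxx + myy - common) / 2
    ang <- (atan2(2 * mxy, mxx - myy) / 2) * 180 / pi
    ellipse <- c(com_x, com_y, 4 * sqrt(l1), 4 * sqrt(pmax(l2, 0)),
                 (ang + 180) %% 180,
                 if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0)
  }

  data.frame(area = area, hull_area = hull_area, solidity = solidity,
             perimeter = perimeter, width = width, height = height,
             longest_axis = longest_axis, com_x = com_x, com_y = com_y,
             hull_vertices = hull_vertices,
             ellipse_cx = ellipse[1], ellipse_cy = ellipse[2],
             ellipse_major = ellipse[3], ellipse_minor = ellipse[4],
             ellipse_angle = ellipse[5], ellipse_eccentricity = ellipse[6])
}

# shoelace area of a polygon given as an n x 2 vertex matrix
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

max_pairwise_distance <- function(v) {
  if (nrow(v) < 2) return(0)
  max(dist(v))
}

#' Per-degree hue histogram of masked pixels
#'
#' Counts foreground pixels at each of the 360 hue degrees. Hue is the
#' angular (0--360 degree) coordinate of HSV space; pixels with zero
#' saturation or zero value have no defined hue and are excluded from the
#' bins but still counted in `n_mask_pixels` (so normalized bins are
#' fractions of the whole mask).
#'
#' @param image height x width x 3 RGB array, 0--255.
#' @param mask logical matrix of the same height/width.
#' @return object of class `hue_histogram`: list with `bins` (named counts
#'   hue_000..hue_359), `n_mask_pixels`, `normalized = FALSE`.
#' @export
extract_hue_histogram <- function(image, mask) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(mask) == dim(image)[1:2]))
  fg <- which(mask)
  if (length(fg) == 0) stop("empty mask: no pixels to histogram")
  hw <- prod(dim(image)[1:2])
  rgb <- rbind(image[fg], image[fg + hw], image[fg + 2 * hw])
  hsv <- rgb2hsv(rgb, maxColorValue = 255)
  defined <- hsv[2, ] > 0 & hsv[3, ] > 0
  deg <- floor(hsv[1, defined] * 360) %% 360
  bins <- tabulate(deg + 1L, nbins = 360L)
  names(bins) <- sprintf("hue_%03d", 0:359)
  structure(list(bins = bins, n_mask_pixels = length(fg), normalized = FALSE),
            class = "hue_histogram")
}

#' Normalize a hue histogram by mask size
#'
#' Divides each bin by the total number of mask pixels, turning counts into
#' the fraction of the mask taking each hue value. Because undefined-hue
#' pixels stay in the denominator, the normalized bins sum to at most 1.
#'
#' @param hist a raw `hue_histogram`.
#' @return the histogram with fractional bins and `normalized = TRUE`.
#' @export
normalize_histogram <- function(hist) {
  stopifnot(inherits(hist, "hue_histogram"))
  if (hist$normalized) return(hist)
  if (hist$n_mask_pixels <= 0) stop("cannot normalize: mask has no pixels")
  hist$bins <- hist$bins / hist$n_mask_pixels
  hist$normalized <- TRUE
  hist
}

#' Re-bin a 360-degree hue histogram to wider bins
#'
#' Sums consecutive degree bins into bins of `width_deg` degrees (default 2
#' degrees, giving the 180-dimensional colour representation used for colour
#' PCA). Mass is conserved exactly.
#'
#' @param hist a `hue_histogram` or a numeric vector of length 360.
#' @param width_deg bin width in degrees; must divide 360.
#' @return numeric vector of `360 / width_deg` summed bins, named by the
#'   left edge of each bin.
#' @export
rebin_hue <- function(hist, width_deg = 2) {
  v <- if (inherits(hist, "hue_histogram")) hist$bins else hist
  stopifnot(length(v) == 360)
  if (360 %% width_deg != 0) stop("width_deg must divide 360")
  k <- 360 %/% width_deg
  out <- colSums(matrix(v, nrow = width_deg, ncol = k))
  names(out) <- sprintf("hue_%03d", seq(0, 359, by = width_deg))
  out
}

#' @export
print.hue_histogram <- function(x, ...) {
  cat(sprintf("Hue histogram: %d bins, %d mask pixels, %s\n",
              length(x$bins), x$n_mask_pixels,
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}
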