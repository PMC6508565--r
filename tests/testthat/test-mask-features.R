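test_that("segment_plant recovers the rendered mask and handles edge cases", {
  r <- render_plant_image(2000, 0.4, canvas_size = c(80, 80), seed = 4)
  expect_identical(segment_plant(r$image), r$mask)

  bg <- array(0, c(10, 10, 3))
  bg[, , 1] <- 30; bg[, , 2] <- 30; bg[, , 3] <- 180
  expect_false(any(segment_plant(bg)))           # uniform background -> empty
  bg[5, 5, ] <- c(31, 30, 180)
  expect_equal(sum(segment_plant(bg, tolerance = 0)), 1)  # any difference counts
})

test_that("shape features of a filled square match the closed form", {
  mask <- matrix(FALSE, 20, 20)
  mask[6:15, 4:13] <- TRUE  # 10x10 square
  f <- extract_shape_features(mask)
  expect_equal(ncol(f), 16)
  expect_equal(f$area, 100)
  expect_equal(f$width, 10)
  expect_equal(f$height, 10)
  expect_equal(f$hull_area, 100)
  expect_equal(f$solidity, 1.0)
  expect_equal(f$hull_vertices, 4)
  expect_equal(f$perimeter, 40)
  # centroid of the pixel-centre grid (0-based: cols 4:13 -> x 3..12)
  expect_equal(f$com_x, 7.5)
  expect_equal(f$com_y, 9.5)
  expect_equal(f$ellipse_eccentricity, 0)
})

test_that("hull features agree with an independent gift-wrapping oracle", {
  set.seed(31)
  for (trial in 1:5) {
    r <- render_plant_image(500 + trial * 300, 0.5,
                            canvas_size = c(60, 60), seed = 100 + trial)
    f <- extract_shape_features(r$mask)
    idx <- which(r$mask, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1
    corners <- cbind(c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
                     c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
    oracle <- shoelace(gift_wrap_hull(corners))
    expect_equal(f$hull_area, oracle, tolerance = 1e-9)
    expect_gte(f$hull_area, f$area)
    expect_equal(f$solidity, f$area / f$hull_area)
    expect_true(f$ellipse_eccentricity >= 0 && f$ellipse_eccentricity < 1)
  }
})

test_that("90-degree rotation swaps width/height and preserves size features", {
  r <- render_plant_image(1200, 0.2, canvas_size = c(70, 50), seed = 77)
  mask <- r$mask
  rot <- t(mask)[, nrow(mask):1]  # 90-degree rotation
  f0 <- extract_shape_features(mask)
  f1 <- extract_shape_features(rot)
  expect_equal(f1$area, f0$area)
  expect_equal(f1$width, f0$height)
  expect_equal(f1$height, f0$width)
  expect_equal(f1$hull_area, f0$hull_area)
  expect_equal(f1$solidity, f0$solidity)
  expect_equal(f1$perimeter, f0$perimeter)
  expect_equal(f1$longest_axis, f0$longest_axis)
})

test_that("hue histogram bins primary colours at their HSV degrees", {
  mk <- function(rgb) {
    img <- array(0, c(4, 4, 3))
    img[, , 1] <- rgb[1]; img[, , 2] <- rgb[2]; img[, , 3] <- rgb[3]
    img
  }
  mask <- matrix(TRUE, 4, 4)
  expect_equal(unname(extract_hue_histogram(mk(c(0, 255, 0)), mask)$bins[121]), 16)  # green 120
  expect_equal(unname(extract_hue_histogram(mk(c(255, 0, 0)), mask)$bins[1]), 16)    # red 0
  expect_equal(unname(extract_hue_histogram(mk(c(255, 255, 0)), mask)$bins[61]), 16) # yellow 60
  expect_error(extract_hue_histogram(mk(c(255, 0, 0)), matrix(FALSE, 4, 4)), "empty")
})

test_that("normalization divides by mask pixels, keeping undefined hue in the denominator", {
  img <- array(0, c(2, 4, 3))
  img[, 1:2, 1] <- 255            # half red
  img[, 3:4, ] <- 128             # half gray: saturation 0, undefined hue
  mask <- matrix(TRUE, 2, 4)
  h <- extract_hue_histogram(img, mask)
  expect_equal(h$n_mask_pixels, 8)
  expect_equal(sum(h$bins), 4)    # only defined-hue pixels binned
  n <- normalize_histogram(h)
  expect_equal(sum(n$bins), 0.5)  # gray stays in the denominator

  # all-red image: every pixel has defined hue, normalized mass 1
  img2 <- array(0, c(2, 4, 3)); img2[, , 1] <- 255
  n2 <- normalize_histogram(extract_hue_histogram(img2, mask))
  expect_equal(sum(n2$bins), 1.0)

  degenerate <- structure(list(bins = rep(0, 360), n_mask_pixels = 0,
                               normalized = FALSE), class = "hue_histogram")
  expect_error(normalize_histogram(degenerate), "no pixels")
})

test_that("rebinning conserves mass and matches brute-force partial sums", {
  expect_equal(unname(rebin_hue(rep(1, 360), 2)), rep(2, 180))
  expect_equal(unname(rebin_hue(rep(1, 360), 360)), 360)
  set.seed(12)
  v <- runif(360)
  for (w in c(2, 5, 90)) {
    got <- rebin_hue(v, w)
    brute <- vapply(seq_len(360 / w), function(j) sum(v[((j - 1) * w + 1):(j * w)]), 0)
    expect_equal(unname(got), brute)
    expect_equal(sum(got), sum(v))
  }
  expect_error(rebin_hue(v, 7), "divide")
})
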