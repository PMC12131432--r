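# Colour-channel statistics inside finger regions and the ARTIX score.
#
# The per-finger redness score is computed from quartile statistics of the
# Gaussian-smoothed red channel. The default formula is
#   redness = median_R + (Q1_R + Q3_R) / 2,
# i.e. median plus midhinge of the smoothed red channel, bounded in
# [0, 510]. The green and blue channels are always computed and reported;
# they carry zero weight in the default score but can be weighted in via
# `score_weights()`. The per-timepoint ARTIX value is the arithmetic mean
# of the per-finger redness over all non-thumb regions.

.formula_version <- "median+midhinge-v1"

#' Weights of the redness formula
#'
#' @param median_r Weight of the red-channel median.
#' @param midhinge_r Weight of the red-channel midhinge `(Q1 + Q3) / 2`.
#' @param gb_penalty Weight of a green/blue robustness penalty,
#'   `gb_penalty * (midhinge_G + midhinge_B) / 2`, subtracted from the
#'   score; 0 by default.
#' @return A named list of weights.
#' @export
score_weights <- function(median_r = 1, midhinge_r = 1, gb_penalty = 0) {
  list(median_r = median_r, midhinge_r = midhinge_r, gb_penalty = gb_penalty)
}

#' Masked Gaussian smoothing of an image over one region
#'
#' Smooths each colour channel with a Gaussian kernel normalized over the
#' region mask: pixels outside the region carry zero weight, so values near
#' the region border are averages of region pixels only and background
#' never bleeds into the statistics. `sigma = 0` is the identity.
#'
#' @param image H x W x 3 array, intensities in \[0, 255\].
#' @param region A `finger_region` (or any object with a `$mask`), or a
#'   bare binary mask.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return A list with matrices `R`, `G`, `B` of smoothed values (only
#'   entries inside the region are meaningful; outside entries are `NA`)
#'   and the logical `mask`.
#' @export
masked_gaussian_smooth <- function(image, region, sigma = 2) {
  assert_rgb_image(image)
  mask <- if (is.list(region)) region$mask else region
  mask <- as_binary_mask(mask)
  if (!identical(dim(mask), dim(image)[1:2])) {
    artix_error("artix_shape_mismatch", "region mask must match the image grid")
  }
  if (!any(mask)) {
    artix_error("artix_empty_region", "region is empty")
  }
  if (sigma < 0) artix_error("artix_bad_input", "sigma must be >= 0")
  m <- mask * 1
  chans <- lapply(1:3, function(c) {
    ch <- image[, , c]
    if (sigma == 0) {
      out <- ch
    } else {
      num <- EBImage::gblur(ch * m, sigma = sigma)
      den <- EBImage::gblur(m, sigma = sigma)
      out <- num / pmax(den, 1e-12)
    }
    out[!mask] <- NA_real_
    out
  })
  list(R = chans[[1]], G = chans[[2]], B = chans[[3]], mask = mask)
}

#' Per-channel quartile statistics of a smoothed region
#'
#' Median, first and third quartile of each colour channel over the region
#' pixels, using linear-interpolation (type 7) quantiles.
#'
#' @param smoothed Output of [masked_gaussian_smooth()].
#' @param region Optional region (defaults to the mask recorded in
#'   `smoothed`).
#' @param min_pixels Minimum region size; smaller regions raise a
#'   `"region too small"` error (condition class `artix_region_too_small`).
#' @return An object of class `channel_stats`: a list with `stats` (a 3-row
#'   data frame: channel, median, q1, q3) and `n_pixels`.
#' @export
channel_stats <- function(smoothed, region = NULL, min_pixels = 25L) {
  mask <- if (is.null(region)) smoothed$mask else
    as_binary_mask(if (is.list(region)) region$mask else region)
  n <- sum(mask)
  if (n == 0L) artix_error("artix_empty_region", "region is empty")
  if (n < min_pixels) {
    artix_error("artix_region_too_small",
                sprintf("region too small: %d px < %d px minimum", n, min_pixels))
  }
  rows <- lapply(c("R", "G", "B"), function(ch) {
    v <- smoothed[[ch]][mask]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(channel = ch, median = q[2], q1 = q[1], q3 = q[3])
  })
  structure(list(stats = do.call(rbind, rows), n_pixels = n),
            class = "channel_stats")
}

#' Redness score of one finger region
#'
#' Default formula: red-channel median plus red-channel midhinge
#' `(Q1 + Q3) / 2`, computed on the smoothed values, giving scores in
#' \[0, 510\]. Weights, including an optional green/blue penalty, come from
#' [score_weights()].
#'
#' @param stats A `channel_stats` object.
#' @param weights See [score_weights()].
#' @return Numeric score (arbitrary units).
#' @export
redness_score <- function(stats, weights = score_weights()) {
  stopifnot(inherits(stats, "channel_stats"))
  s <- stats$stats
  r <- s[s$channel == "R", ]
  g <- s[s$channel == "G", ]
  b <- s[s$channel == "B", ]
  val <- weights$median_r * r$median +
    weights$midhinge_r * (r$q1 + r$q3) / 2
  if (weights$gb_penalty != 0) {
    val <- val - weights$gb_penalty *
      ((g$q1 + g$q3) / 2 + (b$q1 + b$q3) / 2) / 2
  }
  unname(val)
}

#' ARTIX score of one assessment frame
#'
#' Computes the per-finger redness of every non-thumb region and averages
#' them into the single per-timepoint score. Regions smaller than
#' `min_pixels` are dropped with a warning as long as at least three
#' quarters of the scoring regions remain (6 of 8 for a two-hand frame);
#' fewer remaining regions raise an error.
#'
#' @param image H x W x 3 array (the frame the regions were extracted from).
#' @param regions List of `finger_region` objects; thumbs are excluded
#'   automatically.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param weights See [score_weights()].
#' @param min_pixels Minimum pixels per scored region.
#' @param timepoint_label Optional label stored in the result.
#' @return An object of class `artix_score`: list with `value`,
#'   `per_finger` (named numeric), `n_regions`, `timepoint_label`,
#'   `formula_version` and `weights`.
#' @export
artix_score <- function(image, regions, sigma = 2, weights = score_weights(),
                        min_pixels = 25L, timepoint_label = NULL) {
  scoring <- scoring_regions(regions)
  vals <- numeric(0)
  dropped <- character(0)
  for (reg in scoring) {
    label <- paste0(if (!is.null(reg$hand) && !is.na(reg$hand))
      paste0(reg$hand, "_") else "", reg$finger)
    res <- tryCatch({
      sm <- masked_gaussian_smooth(image, reg, sigma = sigma)
      st <- channel_stats(sm, min_pixels = min_pixels)
      redness_score(st, weights)
    }, artix_region_too_small = function(e) NULL)
    if (is.null(res)) dropped <- c(dropped, label)
    else vals[label] <- res
  }
  n_total <- length(scoring)
  if (length(vals) < ceiling(0.75 * n_total)) {
    artix_error("artix_too_few_regions",
                sprintf("only %d of %d scoring regions usable", length(vals), n_total))
  }
  if (length(dropped) > 0L) {
    artix_warn("artix_dropped_regions",
               paste("regions dropped as too small:", paste(dropped, collapse = ", ")))
  }
  structure(list(value = mean(vals), per_finger = vals,
                 n_regions = length(vals),
                 timepoint_label = timepoint_label,
                 formula_version = .formula_version, weights = weights),
            class = "artix_score")
}

#' @export
print.artix_score <- function(x, ...) {
  cat(sprintf("ARTIX %.1f (%d fingers, formula %s)\n",
              x$value, x$n_regions, x$formula_version))
  invisible(x)
}
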