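# Hand segmentation: square resize, a deterministic classical segmenter
# (background-palette distance thresholding), a small trainable per-pixel
# probabilistic segmenter, and mask overlap (IoU) evaluation.
#
# Masks share the pixel grid of their (resized) source image. Cleanup is the
# same for both segmenters: morphological closing with a disc, then keeping
# the at most two largest connected components (one or two hands per frame).

#' Resize an image to a square frame
#'
#' Bilinear resize to `side` x `side`. The per-axis scale factors needed to
#' map landmark coordinates between the original and resized grids are
#' attached as attributes: `scale = c(x = side/W, y = side/H)` where the
#' input is H rows by W columns (x = column, y = row), plus
#' `source_shape = c(H, W)`.
#'
#' @param image H x W x 3 numeric array, intensities in \[0, 255\].
#' @param side Target side length in pixels (>= 64).
#' @return A `side` x `side` x 3 array with `scale` and `source_shape`
#'   attributes.
#' @export
resize_square <- function(image, side) {
  assert_rgb_image(image)
  side <- as.integer(side)
  if (side < 64L) {
    artix_error("artix_bad_size", "target side must be at least 64 px")
  }
  d <- dim(image)
  if (d[1] == side && d[2] == side) {
    out <- image
  } else {
    # EBImage works on [0,1]; resize is bilinear by default
    out <- EBImage::imageData(EBImage::resize(EBImage::Image(image / 255,
                                                             colormode = "Color"),
                                              w = side, h = side)) * 255
    out <- clamp(out, 0, 255)
    dim(out) <- c(side, side, 3L)
  }
  attr(out, "scale") <- c(x = side / d[2], y = side / d[1])
  attr(out, "source_shape") <- c(d[1], d[2])
  out
}

# closing + keep the <=2 largest components; returns logical matrix.
# The structuring element scales with resolution: disc radius 3 at the
# 512 px reference frame, so narrow interdigital gaps are not bridged at
# small working resolutions.
.cleanup_mask <- function(mask, brush_size = NULL, max_components = 2L) {
  if (is.null(brush_size)) {
    r <- max(1L, as.integer(round(3 * min(dim(mask)) / 512)))
    brush_size <- 2L * r + 1L
  }
  m <- EBImage::closing(mask * 1, EBImage::makeBrush(brush_size, "disc"))
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0], n)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(max_components, n))]
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Classical hand segmentation by background-palette distance
#'
#' Deterministic fallback segmenter: estimates the background colour from
#' the image border, marks pixels whose Euclidean RGB distance from that
#' palette exceeds a threshold, then applies morphological closing and keeps
#' the at most two largest connected components. Works whenever the
#' background palette is far from the skin palette (e.g. hands on a dark
#' insulated surface).
#'
#' @param image H x W x 3 array, intensities in \[0, 255\].
#' @param threshold RGB distance above which a pixel is considered hand.
#' @param border Width in pixels of the frame border used to estimate the
#'   background palette.
#' @return H x W logical mask.
#' @export
segment_hand_classical <- function(image, threshold = 45, border = 4L) {
  assert_rgb_image(image)
  d <- dim(image)
  ri <- c(seq_len(border), d[1] - seq_len(border) + 1L)
  ci <- c(seq_len(border), d[2] - seq_len(border) + 1L)
  bg <- vapply(1:3, function(c) {
    ch <- image[, , c]
    stats::median(c(ch[ri, ], ch[-ri, ci]))
  }, numeric(1))
  dist2 <- (image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
    (image[, , 3] - bg[3])^2
  mask <- .cleanup_mask(dist2 > threshold^2)
  if (!any(mask)) {
    artix_error("artix_no_hand", "no hand found: mask empty after cleanup")
  }
  mask
}

# Logistic regression by iteratively reweighted least squares with a small
# L2 penalty, which keeps the solution finite when hand and background
# pixels are perfectly separable in feature space.
.ridge_logistic <- function(x, y, maxit = 25L, lambda = 1e-3, tol = 1e-6) {
  p <- ncol(x)
  beta <- numeric(p)
  pen <- diag(lambda, p); pen[1, 1] <- 0  # do not penalize the intercept
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(x, x * w) + pen, crossprod(x, w * z))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coef = beta, converged = converged)
}

# per-pixel feature stack: raw channels, Gaussian-smoothed channels and a
# coarse smoothed luminance; returns an n_pixels x 7 matrix
.pixel_features <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  lum <- (r + g + b) / 3
  cbind(c(r), c(g), c(b),
        c(EBImage::gblur(r, sigma = 2)),
        c(EBImage::gblur(g, sigma = 2)),
        c(EBImage::gblur(b, sigma = 2)),
        c(EBImage::gblur(lum, sigma = 5)))
}

#' Train the per-pixel hand segmenter
#'
#' Fits a logistic per-pixel classifier on raw and Gaussian-smoothed colour
#' features, producing hand probabilities that are thresholded at 0.5 and
#' cleaned up like the classical segmenter. Training pixels are subsampled
#' from each image, stratified between hand and background. The fitted model
#' is evaluated on the held-out validation set and carries the mean
#' intersection-over-union achieved there.
#'
#' @param train_set,val_set Lists of `list(image=, mask=)` pairs (a
#'   `synthetic_hand` works as-is). The two sets must be disjoint.
#' @param epochs Maximum number of iteratively reweighted least squares
#'   passes for the logistic fit.
#' @param seed Integer seed for the pixel subsampling.
#' @param pixels_per_image Training pixels sampled from each image.
#' @return An object of class `artix_segmenter` with elements `coef`,
#'   `val_iou` (mean held-out IoU), `val_iou_per_image` and `converged`.
#' @export
train_segmenter <- function(train_set, val_set, epochs = 25L, seed = 1L,
                            pixels_per_image = 400L) {
  if (length(val_set) == 0L) {
    artix_error("artix_bad_input", "validation set must be nonempty")
  }
  if (length(train_set) == 0L) {
    artix_error("artix_bad_input", "training set must be nonempty")
  }
  samp <- with_seed(seed, {
    xs <- vector("list", length(train_set))
    ys <- vector("list", length(train_set))
    for (i in seq_along(train_set)) {
      item <- train_set[[i]]
      feats <- .pixel_features(item$image)
      lab <- c(as_binary_mask(item$mask))
      n_half <- pixels_per_image %/% 2L
      pos <- which(lab); neg <- which(!lab)
      take <- c(sample(pos, min(n_half, length(pos))),
                sample(neg, min(n_half, length(neg))))
      xs[[i]] <- feats[take, , drop = FALSE]
      ys[[i]] <- lab[take]
    }
    list(x = do.call(rbind, xs), y = unlist(ys))
  })
  x <- cbind(1, samp$x / 255)
  fit <- .ridge_logistic(x, as.numeric(samp$y), maxit = as.integer(epochs))
  if (!fit$converged) {
    artix_warn("artix_not_converged",
               "segmenter training did not converge; metrics reported anyway")
  }
  model <- structure(list(coef = fit$coef, converged = fit$converged),
                     class = "artix_segmenter")
  ious <- vapply(val_set, function(item) {
    pred <- segment_hand_model(model, item$image)
    mask_overlap(pred, as_binary_mask(item$mask))
  }, numeric(1))
  model$val_iou_per_image <- ious
  model$val_iou <- mean(ious)
  model
}

#' Segment a hand with a trained segmenter
#'
#' @param model An `artix_segmenter` from [train_segmenter()].
#' @param image H x W x 3 array, intensities in \[0, 255\].
#' @return H x W logical mask (per-pixel probability thresholded at 0.5,
#'   then morphological cleanup).
#' @export
segment_hand_model <- function(model, image) {
  stopifnot(inherits(model, "artix_segmenter"))
  assert_rgb_image(image)
  x <- cbind(1, .pixel_features(image) / 255)
  eta <- drop(x %*% model$coef)
  prob <- matrix(stats::plogis(eta), dim(image)[1], dim(image)[2])
  mask <- .cleanup_mask(prob > 0.5)
  if (!any(mask)) {
    artix_error("artix_no_hand", "no hand found: mask empty after cleanup")
  }
  mask
}

#' Overlap between two masks (intersection-over-union)
#'
#' @param pred,truth Binary masks on the same pixel grid.
#' @return IoU in \[0, 1\]; 1 iff the masks are identical (two empty masks
#'   count as identical).
#' @export
mask_overlap <- function(pred, truth) {
  pred <- as_binary_mask(pred); truth <- as_binary_mask(truth)
  if (!identical(dim(pred), dim(truth))) {
    artix_error("artix_shape_mismatch", "masks must share the same shape")
  }
  u <- sum(pred | truth)
  if (u == 0L) return(1)
  sum(pred & truth) / u
}
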