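# Per-finger mask extraction from hand landmarks.
#
# Landmarks follow the 21-point convention (wrist = 0; four joints per
# digit, CMC/MCP/IP/TIP for the thumb and MCP/PIP/DIP/TIP for the fingers),
# as produced by common hand-landmark detectors. The landmark provider is
# pluggable: the synthetic generator supplies ground-truth sets, and
# precomputed sets can be loaded from CSV; the package never calls an
# external detector directly.

# landmark row indices (1-based into the 21-row table) of each digit chain
# used as the skeleton, thumb first. The thumb skeleton starts at its MCP.
.digit_chains <- list(
  thumb = c(3L, 4L, 5L),
  index = c(6L, 7L, 8L, 9L),
  middle = c(10L, 11L, 12L, 13L),
  ring = c(14L, 15L, 16L, 17L),
  pinky = c(18L, 19L, 20L, 21L)
)
.mcp_rows <- c(thumb = 3L, index = 6L, middle = 10L, ring = 14L, pinky = 18L)

assert_landmarks <- function(lms) {
  if (!is.data.frame(lms) || nrow(lms) != 21L ||
      !all(c("point_index", "x", "y", "normalized") %in% names(lms))) {
    artix_error("artix_bad_landmarks",
                "landmark set must be a 21-row data frame with point_index, x, y, normalized")
  }
  lms <- lms[order(lms$point_index), ]
  invisible(lms)
}

#' Rescale a landmark set onto a mask pixel grid
#'
#' Normalized coordinates in \[0, 1\] are mapped to pixel-centre coordinates
#' as `x_px = x * (W - 1)`, `y_px = y * (H - 1)`. Pixel coordinates from a
#' different source frame are multiplied by the per-axis shape ratio
#' (`W_mask / W_source` in x, `H_mask / H_source` in y). Rescaling an
#' already-aligned pixel set with identical shapes is the identity.
#'
#' @param lms A 21-row landmark data frame (columns `point_index`,
#'   `point_name`, `x`, `y`, `normalized`, and optionally `hand`).
#' @param mask_shape Target grid as `c(H, W)`.
#' @param source_shape For pixel-coordinate inputs, the source grid
#'   `c(H, W)`; ignored for normalized inputs. Defaults to `mask_shape`.
#' @return The landmark data frame in pixel coordinates on the mask grid
#'   (`normalized = FALSE`).
#' @export
rescale_landmarks <- function(lms, mask_shape, source_shape = NULL) {
  lms <- assert_landmarks(lms)
  stopifnot(length(mask_shape) == 2L, all(mask_shape > 0))
  H <- mask_shape[1]; W <- mask_shape[2]
  if (isTRUE(all(lms$normalized))) {
    if (any(lms$x < 0 | lms$x > 1 | lms$y < 0 | lms$y > 1)) {
      artix_error("artix_bad_landmarks",
                  "normalized landmark coordinates must lie in [0, 1]")
    }
    lms$x <- lms$x * (W - 1)
    lms$y <- lms$y * (H - 1)
  } else {
    src <- source_shape %||% mask_shape
    stopifnot(length(src) == 2L, all(src > 0))
    lms$x <- lms$x * (W / src[2])
    lms$y <- lms$y * (H / src[1])
  }
  lms$normalized <- FALSE
  class(lms) <- c("hand_landmarks", "data.frame")
  lms
}

# distance from points (px, py) to a polyline given as a k x 2 matrix
.polyline_dist <- function(px, py, pts) {
  d2 <- rep(Inf, length(px))
  for (s in seq_len(nrow(pts) - 1L)) {
    A <- pts[s, ]; B <- pts[s + 1L, ]
    vx <- B[1] - A[1]; vy <- B[2] - A[2]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      clamp(((px - A[1]) * vx + (py - A[2]) * vy) / len2, 0, 1)
    dx <- px - (A[1] + t * vx); dy <- py - (A[2] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Extract per-finger masks from a hand mask and its landmarks
#'
#' For each digit the MCP-to-tip landmark chain forms a skeleton polyline. A
#' hand-mask pixel joins digit *d* when (a) its projection onto the digit's
#' proximal axis (MCP towards the next joint) lies distal to the MCP and
#' (b) its distance to the skeleton is at most the digit's half-width
#' estimate `r_d = halfwidth_factor * min(distance to adjacent MCPs)`.
#' Pixels eligible for several digits go to the nearest skeleton, with ties
#' broken towards the lower digit index (thumb < index < ... < pinky).
#'
#' @param mask H x W binary hand mask.
#' @param lms Landmark set; normalized coordinates are rescaled onto the
#'   mask grid automatically.
#' @param halfwidth_factor Multiplier on the minimum adjacent-MCP distance
#'   giving the digit capture radius.
#' @return A list of 5 `finger_region` objects (thumb, index, middle, ring,
#'   pinky), each with elements `finger`, `hand`, `mask` (H x W logical) and
#'   `skeleton` (joint coordinates, one row per landmark).
#' @export
segment_fingers <- function(mask, lms, halfwidth_factor = 0.5) {
  mask <- as_binary_mask(mask)
  lms <- assert_landmarks(lms)
  if (isTRUE(all(lms$normalized))) {
    lms <- rescale_landmarks(lms, dim(mask))
  }
  H <- nrow(mask); W <- ncol(mask)
  ix <- clamp(round(lms$x) + 1L, 1L, W)
  iy <- clamp(round(lms$y) + 1L, 1L, H)
  if (!any(mask[cbind(iy, ix)])) {
    artix_error("artix_landmark_misalignment",
                "landmark/mask misalignment: all landmarks fall outside the mask")
  }

  pts <- as.matrix(lms[, c("x", "y")])
  mcp <- pts[.mcp_rows, , drop = FALSE]
  # digit capture radius from adjacent MCP spacing (hand order)
  adj <- sqrt(rowSums((mcp[-1, , drop = FALSE] - mcp[-5, , drop = FALSE])^2))
  r_d <- halfwidth_factor * pmin(c(adj[1], adj), c(adj, adj[4]))

  on <- which(mask)
  px <- (col(mask)[on]) - 1
  py <- (row(mask)[on]) - 1

  dist_mat <- matrix(Inf, length(on), 5L)
  for (i in 1:5) {
    chain <- pts[.digit_chains[[i]], , drop = FALSE]
    dir <- chain[2, ] - chain[1, ]
    dir <- dir / sqrt(sum(dir^2))
    distal <- (px - chain[1, 1]) * dir[1] + (py - chain[1, 2]) * dir[2] >= 0
    d <- .polyline_dist(px, py, chain)
    eligible <- distal & d <= r_d[i]
    dist_mat[eligible, i] <- d[eligible]
  }
  best <- max.col(-dist_mat, ties.method = "first")  # ties -> lower index
  assigned <- ifelse(is.finite(dist_mat[cbind(seq_along(best), best)]), best, 0L)

  hand_label <- if ("hand" %in% names(lms)) lms$hand[1] else NA_character_
  lapply(1:5, function(i) {
    m <- matrix(FALSE, H, W)
    m[on[assigned == i]] <- TRUE
    structure(list(finger = .finger_order[i], hand = hand_label, mask = m,
                   skeleton = pts[.digit_chains[[i]], , drop = FALSE]),
              class = "finger_region")
  })
}

#' Keep only the regions that enter the redness score
#'
#' Drops thumb regions: the score is computed over the second to fifth
#' digits of each hand (8 regions for a two-hand frame, 4 for one hand).
#'
#' @param regions List of `finger_region` objects (one or two hands).
#' @return The non-thumb regions.
#' @export
scoring_regions <- function(regions) {
  stopifnot(length(regions) >= 1L)
  keep <- vapply(regions, function(r) !identical(r$finger, "thumb"), logical(1))
  if (!any(keep)) {
    artix_error("artix_no_scoring_regions",
                "no non-thumb regions available for scoring")
  }
  regions[keep]
}

#' Read a landmark set from CSV
#'
#' Expected columns: `subject_id`, `timepoint_label`, `hand`, `point_index`
#' (0--20), `point_name`, `x`, `y`, `normalized_flag`. Returns one landmark
#' data frame per (subject, timepoint, hand) combination.
#'
#' @param path CSV file path.
#' @return A list of landmark data frames.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint_label", "hand", "point_index",
            "point_name", "x", "y", "normalized_flag")
  if (!all(need %in% names(df))) {
    artix_error("artix_bad_landmarks",
                paste("landmark CSV must contain columns:",
                      paste(need, collapse = ", ")))
  }
  key <- interaction(df$subject_id, df$timepoint_label, df$hand, drop = TRUE)
  lapply(split(df, key), function(g) {
    out <- data.frame(hand = g$hand, point_index = g$point_index,
                      point_name = g$point_name, x = g$x, y = g$y,
                      normalized = as.logical(g$normalized_flag),
                      stringsAsFactors = FALSE)
    out <- out[order(out$point_index), ]
    class(out) <- c("hand_landmarks", "data.frame")
    out
  })
}
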