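# Synthetic hand and cold-challenge generators.
#
# Hands are drawn as a filled palm ellipse plus five capsule-shaped digits,
# which gives pixel-exact ground truth for the mask, the per-digit partition
# and the 21-point landmark set. All geometry is parameterised relative to a
# 512 px frame and rescaled, so the same spec renders at any resolution.

# Digit layout constants at the 512 px reference frame, in order
# thumb, index, middle, ring, pinky. Angles are degrees clockwise from
# vertical (up); base angles position the digit root on the palm ellipse.
.finger_order <- c("thumb", "index", "middle", "ring", "pinky")
.base_angle_deg <- c(-80, -36, -12, 12, 36)
.dir_angle_deg <- c(-70, -20, -2, 13, 32)
.default_lengths <- c(95, 150, 168, 152, 112)
.default_widths <- c(32, 32, 33, 32, 27)
# joint positions as fractions of digit length beyond the palm boundary;
# thumb row uses the CMC/MCP/IP/TIP convention, others MCP/PIP/DIP/TIP
.joint_fracs_thumb <- c(-0.10, 0, 0.52, 0.94)
.joint_fracs_finger <- c(0, 0.42, 0.72, 0.94)
# capsules start slightly inside the palm so the digit joins it seamlessly
.capsule_root_frac <- -0.12

landmark_names <- function() {
  c("wrist",
    "thumb_cmc", "thumb_mcp", "thumb_ip", "thumb_tip",
    "index_mcp", "index_pip", "index_dip", "index_tip",
    "middle_mcp", "middle_pip", "middle_dip", "middle_tip",
    "ring_mcp", "ring_pip", "ring_dip", "ring_tip",
    "pinky_mcp", "pinky_pip", "pinky_dip", "pinky_tip")
}

#' Specification of a synthetic hand image
#'
#' Collects the geometry and colour parameters used by
#' [generate_synthetic_hand()]. Lengths are in pixels of the output frame;
#' colours are RGB triples on the 0--255 scale. Defaults draw a plausible
#' right-hand dorsum filling most of a square frame, on a dark background
#' emulating the insulated surface hands rest on during a cold challenge.
#'
#' @param image_size Side of the square output frame in pixels (>= 128).
#' @param handedness `"left"` or `"right"`; left hands are mirrored in x.
#' @param palm_center Pixel coordinates (x, y) of the palm ellipse centre;
#'   default is centred horizontally, slightly below the frame midline.
#' @param palm_radius Semi-minor (horizontal) palm radius in pixels; the
#'   vertical semi-axis is 1.12 times this.
#' @param finger_lengths,finger_widths Numeric length-5 vectors (thumb,
#'   index, middle, ring, pinky) in pixels.
#' @param base_rgb Skin colour of palm and digits, RGB in \[0, 255\].
#' @param finger_rgb Optional 5 x 3 matrix of per-digit colours (rows in
#'   thumb..pinky order); `NULL` uses `base_rgb` everywhere.
#' @param background_rgb Background colour, RGB in \[0, 255\].
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise added
#'   to every channel (intensity units).
#' @param seed Integer seed controlling the noise; fixed seed gives
#'   bit-identical renders.
#' @return An object of class `hand_spec`.
#' @export
hand_spec <- function(image_size = 512L,
                      handedness = c("right", "left"),
                      palm_center = NULL,
                      palm_radius = NULL,
                      finger_lengths = NULL,
                      finger_widths = NULL,
                      base_rgb = c(200, 140, 130),
                      finger_rgb = NULL,
                      background_rgb = c(18, 18, 20),
                      noise_sd = 5,
                      seed = 1L) {
  handedness <- match.arg(handedness)
  image_size <- as.integer(image_size)
  if (image_size < 128L) {
    artix_error("artix_geometry_error", "image_size must be at least 128 px")
  }
  s <- image_size / 512
  spec <- structure(list(
    image_size = image_size,
    handedness = handedness,
    palm_center = palm_center %||% c(0.5 * image_size, 0.63 * image_size),
    palm_radius = palm_radius %||% (88 * s),
    finger_lengths = finger_lengths %||% (.default_lengths * s),
    finger_widths = finger_widths %||% (.default_widths * s),
    base_rgb = base_rgb,
    finger_rgb = finger_rgb,
    background_rgb = background_rgb,
    noise_sd = noise_sd,
    seed = seed
  ), class = "hand_spec")
  stopifnot(length(spec$finger_lengths) == 5L, length(spec$finger_widths) == 5L)
  spec
}

#' Randomly jittered hand specification
#'
#' Draws a [hand_spec()] with palm size, digit lengths/widths, skin tone and
#' frame placement jittered around the defaults, for building varied
#' train/validation image sets.
#'
#' @param seed Integer seed; drives both the jitter and the render noise.
#' @param image_size Side of the square frame in pixels.
#' @param noise_sd Pixel noise standard deviation.
#' @return A `hand_spec`.
#' @export
random_hand_spec <- function(seed, image_size = 512L, noise_sd = 5) {
  with_seed(seed, {
    handed <- sample(c("left", "right"), 1L)
    s <- image_size / 512
    hand_spec(
      image_size = image_size,
      handedness = handed,
      palm_center = c(image_size * (0.5 + runif(1, -0.03, 0.03)),
                      image_size * (0.63 + runif(1, -0.02, 0.02))),
      palm_radius = 88 * s * runif(1, 0.95, 1.1),
      finger_lengths = .default_lengths * s * runif(5, 0.94, 1.06),
      finger_widths = .default_widths * s * runif(5, 0.88, 1.0),
      base_rgb = clamp(c(200, 140, 130) + rnorm(3, 0, 12), 60, 255),
      background_rgb = clamp(c(18, 18, 20) + rnorm(3, 0, 4), 0, 60),
      noise_sd = noise_sd,
      seed = child_seed(seed, 101L)
    )
  })
}

# Geometry shared by the renderer and the ground-truth labelling:
# palm ellipse parameters, digit root/tip segments and landmark positions.
hand_geometry <- function(spec) {
  size <- spec$image_size
  cx <- spec$palm_center[1]; cy <- spec$palm_center[2]
  a <- spec$palm_radius; b <- 1.12 * spec$palm_radius
  mirror <- spec$handedness == "left"
  rad <- pi / 180
  base_ang <- .base_angle_deg * rad
  dir_ang <- .dir_angle_deg * rad
  if (mirror) { base_ang <- -base_ang; dir_ang <- -dir_ang }

  roots <- cbind(cx + a * sin(base_ang), cy - b * cos(base_ang))
  dirs <- cbind(sin(dir_ang), -cos(dir_ang))
  L <- spec$finger_lengths

  # capsule runs from slightly inside the palm to the digit tip
  cap_a <- roots + .capsule_root_frac * L * dirs
  cap_b <- roots + L * dirs

  lms <- matrix(NA_real_, 21L, 2L)
  lms[1, ] <- c(cx, cy + 0.80 * b)
  for (i in 1:5) {
    fr <- if (i == 1L) .joint_fracs_thumb else .joint_fracs_finger
    idx <- 2L + (i - 1L) * 4L
    for (j in 1:4) {
      lms[idx + j - 1L, ] <- roots[i, ] + fr[j] * L[i] * dirs[i, ]
    }
  }

  # frame-fit check: capsule extremes plus half-width margin
  half_w <- spec$finger_widths / 2
  ext <- rbind(cap_a - half_w, cap_a + half_w, cap_b - half_w, cap_b + half_w,
               c(cx - a, cy - b), c(cx + a, cy + b))
  if (any(ext < 1) || any(ext > size - 2)) {
    artix_error("artix_geometry_error",
                "hand geometry does not fit inside the image frame")
  }
  list(size = size, cx = cx, cy = cy, a = a, b = b,
       roots = roots, dirs = dirs, cap_a = cap_a, cap_b = cap_b,
       half_w = half_w, landmarks = lms)
}

# squared distance from every pixel centre to the segment A-B
.seg_dist2 <- function(X, Y, A, B) {
  vx <- B[1] - A[1]; vy <- B[2] - A[2]
  len2 <- vx * vx + vy * vy
  t <- ((X - A[1]) * vx + (Y - A[2]) * vy) / len2
  t <- clamp(t, 0, 1)
  dx <- X - (A[1] + t * vx); dy <- Y - (A[2] + t * vy)
  dx * dx + dy * dy
}

#' Generate a synthetic hand image with exact ground truth
#'
#' Renders an RGB photograph-like frame of a single hand on a dark
#' background, together with the pixel-exact hand mask, a per-digit ground
#' truth labelling (1 = thumb ... 5 = pinky; 0 elsewhere) and the 21-point
#' landmark set (wrist plus four joints per digit) in pixel coordinates
#' (0-based, x = column, y = row).
#'
#' @param spec A [hand_spec()].
#' @return A list of class `synthetic_hand` with elements `image`
#'   (H x W x 3 array, 0--255), `mask` (H x W logical), `digit_truth`
#'   (H x W integer), `landmarks` (a landmark data frame, see
#'   [rescale_landmarks()]) and `spec`.
#' @examples
#' h <- generate_synthetic_hand(hand_spec(image_size = 160, noise_sd = 0))
#' sum(h$mask) > 0
#' @export
generate_synthetic_hand <- function(spec) {
  stopifnot(inherits(spec, "hand_spec"))
  g <- hand_geometry(spec)
  size <- g$size
  # pixel-centre coordinate grids (0-based)
  X <- matrix(rep(0:(size - 1L), each = size), nrow = size)   # column index
  Y <- matrix(rep(0:(size - 1L), times = size), nrow = size)  # row index

  palm <- ((X - g$cx) / g$a)^2 + ((Y - g$cy) / g$b)^2 <= 1

  digit <- matrix(0L, size, size)
  caps <- vector("list", 5L)
  for (i in 1:5) {
    caps[[i]] <- .seg_dist2(X, Y, g$cap_a[i, ], g$cap_b[i, ]) <= g$half_w[i]^2
  }
  # ground-truth digit area = capsule minus palm; assert the digit areas
  # are pairwise disjoint (the palm may absorb converging capsule roots)
  for (i in 1:5) {
    di <- caps[[i]] & !palm
    if (any(digit[di] != 0L)) {
      artix_error("artix_geometry_error",
                  "digit capsules overlap outside the palm; adjust the hand geometry")
    }
    digit[di] <- i
  }
  mask <- palm | Reduce(`|`, caps)

  img <- array(0, dim = c(size, size, 3L))
  frgb <- spec$finger_rgb
  for (c in 1:3) {
    ch <- matrix(spec$background_rgb[c], size, size)
    ch[mask] <- spec$base_rgb[c]
    if (!is.null(frgb)) {
      for (i in 1:5) ch[digit == i] <- frgb[i, c]
    }
    img[, , c] <- ch
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, rnorm(length(img), 0, spec$noise_sd))
    img <- clamp(img + array(noise, dim = dim(img)), 0, 255)
  }

  lms <- data.frame(
    hand = spec$handedness,
    point_index = 0:20,
    point_name = landmark_names(),
    x = g$landmarks[, 1],
    y = g$landmarks[, 2],
    normalized = FALSE,
    stringsAsFactors = FALSE
  )
  class(lms) <- c("hand_landmarks", "data.frame")

  structure(list(image = img, mask = mask, digit_truth = digit,
                 landmarks = lms, spec = spec),
            class = "synthetic_hand")
}
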