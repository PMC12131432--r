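# Shared fixtures: small synthetic hands, hand-built regions/landmarks and
# an independent quantile oracle.

tiny_hand <- function(seed = 1L, size = 160L, noise_sd = 0, ...) {
  generate_synthetic_hand(hand_spec(image_size = size, noise_sd = noise_sd,
                                    seed = seed, ...))
}

# finger_region stand-in from a bare mask
make_region <- function(mask, finger = "index", hand = "right") {
  structure(list(finger = finger, hand = hand, mask = mask, skeleton = NULL),
            class = "finger_region")
}

# rectangular region inside an image of the given size
rect_region <- function(size, rows, cols, finger = "index", hand = "right") {
  m <- matrix(FALSE, size, size)
  m[rows, cols] <- TRUE
  make_region(m, finger, hand)
}

# regions recovered from the generator's exact digit partition
truth_regions <- function(hand) {
  fingers <- c("thumb", "index", "middle", "ring", "pinky")
  lapply(1:5, function(i)
    make_region(hand$digit_truth == i, fingers[i], hand$spec$handedness))
}

# uniform-colour image with given rgb everywhere
flat_image <- function(size, rgb) {
  img <- array(0, dim = c(size, size, 3L))
  for (c in 1:3) img[, , c] <- rgb[c]
  img
}

# independent brute-force type-7 quantile: sort + linear interpolation
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# hand-built 21-point landmark table from a list of 5 digit chains, each a
# 4 x 2 matrix of (x, y) joints (thumb first); wrist given separately
manual_landmarks <- function(wrist, chains, hand = "right") {
  pts <- rbind(wrist, do.call(rbind, chains))
  df <- data.frame(hand = hand, point_index = 0:20,
                   point_name = artix:::landmark_names(),
                   x = pts[, 1], y = pts[, 2], normalized = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("hand_landmarks", "data.frame")
  df
}

# minimal session object for return-to-baseline tests
fake_session <- function(group, basal, ten, measure_basal_thermal = 30,
                         ten_thermal = 31, id = "S") {
  sched <- protocol_schedule()
  art <- c(basal = basal, `0min` = basal - 10, `2min` = basal - 8,
           `4min` = basal - 6, `6min` = basal - 4, `8min` = basal - 2,
           `10min` = ten)
  th <- c(basal = measure_basal_thermal, `0min` = 25, `2min` = 26,
          `4min` = 27, `6min` = 28, `8min` = 29, `10min` = ten_thermal)
  structure(list(subject_id = id, group = group, season = "MayJul",
                 covariates = list(), schedule = sched,
                 artix = art, thermal = th),
            class = "challenge_session")
}
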