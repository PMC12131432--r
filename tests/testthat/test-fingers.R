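test_that("landmark rescaling maps normalized and pixel coordinates", {
  h <- tiny_hand()
  lms <- h$landmarks
  # normalized (0.5, 0.5) lands on the centre of a 512-grid
  norm <- lms
  norm$x <- 0.5; norm$y <- 0.5; norm$normalized <- TRUE
  px <- rescale_landmarks(norm, c(512, 512))
  expect_equal(unique(px$x), 255.5)
  expect_equal(unique(px$y), 255.5)
  expect_false(any(px$normalized))

  # idempotent for already-aligned pixel coordinates
  once <- rescale_landmarks(lms, c(160, 160))
  twice <- rescale_landmarks(once, c(160, 160))
  expect_equal(once, twice)

  # frame-to-mask ratio, round trip within half a pixel
  big <- lms
  big$x <- lms$x * (4000 / 160); big$y <- lms$y * (3000 / 160)
  small <- rescale_landmarks(big, c(512, 512), source_shape = c(3000, 4000))
  expect_equal(small$x, big$x * (512 / 4000))
  back <- rescale_landmarks(small, c(3000, 4000), source_shape = c(512, 512))
  expect_lt(max(abs(back$x - big$x)), 0.5)
  expect_lt(max(abs(back$y - big$y)), 0.5)

  bad <- norm; bad$x <- 1.5
  expect_error(rescale_landmarks(bad, c(160, 160)),
               class = "artix_bad_landmarks")
})

test_that("finger extraction matches the generator's digit partition", {
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  worst <- sapply(1:20, function(s) {
    h <- generate_synthetic_hand(random_hand_spec(s, image_size = 192,
                                                  noise_sd = 0))
    regs <- segment_fingers(h$mask, h$landmarks)
    min(sapply(1:5, function(i) dice(regs[[i]]$mask, h$digit_truth == i)))
  })
  expect_true(all(worst >= 0.90))
})

test_that("regions are disjoint, inside the mask, and mirror-symmetric", {
  h <- tiny_hand(seed = 9)
  regs <- segment_fingers(h$mask, h$landmarks)
  un <- matrix(0L, nrow(h$mask), ncol(h$mask))
  for (r in regs) {
    expect_true(all(h$mask[r$mask]))       # containment
    un <- un + r$mask
  }
  expect_true(all(un <= 1L))               # pairwise disjoint

  # mirrored mask + mirrored landmarks give mirrored regions
  W <- ncol(h$mask)
  flip <- function(m) m[, W:1]
  lms_m <- h$landmarks
  lms_m$x <- (W - 1) - lms_m$x
  regs_m <- segment_fingers(flip(h$mask), lms_m)
  for (i in seq_along(regs)) {
    expect_identical(regs_m[[i]]$mask, flip(regs[[i]]$mask))
  }
})

test_that("equidistant pixels break ties towards the lower finger index", {
  size <- 120
  mask <- matrix(TRUE, size, size)
  chain <- function(x, y0 = 80) cbind(x, c(y0, y0 - 15, y0 - 30, y0 - 45))
  chains <- list(chain(5), chain(28), chain(32), chain(80), chain(100))
  lms <- manual_landmarks(c(55, 110), chains)
  regs <- segment_fingers(mask, lms)
  # pixels at x = 30 are equidistant to the index (x=28) and middle (x=32)
  # skeletons; the tie rule sends them to the lower index digit
  tie_rows <- 40:75
  expect_true(all(regs[[2]]$mask[tie_rows, 31]))
  expect_false(any(regs[[3]]$mask[tie_rows, 31]))
})

test_that("misaligned landmarks raise an error", {
  h <- tiny_hand()
  off <- h$landmarks
  off$x <- off$x * 0 + 2; off$y <- off$y * 0 + 2   # far corner, outside hand
  expect_error(segment_fingers(h$mask, off),
               class = "artix_landmark_misalignment")
})

test_that("scoring regions exclude thumbs with the 8-digit convention", {
  left <- truth_regions(tiny_hand(seed = 1, handedness = "left"))
  right <- truth_regions(tiny_hand(seed = 1, handedness = "right"))
  both <- c(left, right)
  sc <- scoring_regions(both)
  expect_length(sc, 8L)
  expect_false(any(vapply(sc, function(r) r$finger == "thumb", logical(1))))
  expect_length(scoring_regions(right), 4L)
  expect_error(scoring_regions(right[1]), class = "artix_no_scoring_regions")
})

test_that("landmark CSV round-trips through the file provider", {
  h <- tiny_hand()
  df <- data.frame(subject_id = "S1", timepoint_label = "basal",
                   hand = "right", point_index = h$landmarks$point_index,
                   point_name = h$landmarks$point_name,
                   x = h$landmarks$x, y = h$landmarks$y,
                   normalized_flag = FALSE)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(df, f, row.names = FALSE)
  sets <- read_landmarks_csv(f)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$x, h$landmarks$x)
  regs <- segment_fingers(h$mask, sets[[1]])
  expect_length(regs, 5L)
})
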