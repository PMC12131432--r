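test_that("masked smoothing preserves constants and damps outliers", {
  img <- flat_image(64, c(100, 100, 100))
  reg <- rect_region(64, 10:40, 10:40)
  for (sig in c(0, 1, 3)) {
    sm <- masked_gaussian_smooth(img, reg, sigma = sig)
    expect_equal(sm$R[reg$mask], rep(100, sum(reg$mask)), tolerance = 1e-8)
  }

  # sigma = 0 is the identity
  img2 <- flat_image(64, c(0, 0, 0))
  img2[, , 1] <- matrix(runif(64 * 64, 0, 255), 64, 64)
  sm0 <- masked_gaussian_smooth(img2, reg, sigma = 0)
  expect_identical(sm0$R[reg$mask], img2[, , 1][reg$mask])

  # single 255 outlier in a 100-valued region
  img3 <- flat_image(64, c(100, 100, 100))
  img3[25, 25, 1] <- 255
  sm3 <- masked_gaussian_smooth(img3, reg, sigma = 2)
  expect_lt(max(sm3$R[reg$mask]), 255)
  expect_equal(median(sm3$R[reg$mask]), 100, tolerance = 1e-6)

  expect_error(masked_gaussian_smooth(img, rect_region(64, 1, integer(0))),
               class = "artix_empty_region")
})

test_that("channel stats equal interpolated quartiles of region pixels", {
  img <- flat_image(32, c(0, 0, 0))
  img[1, 1:5, 1] <- c(10, 20, 30, 40, 50)
  reg <- rect_region(32, 1, 1:5)
  sm <- masked_gaussian_smooth(img, reg, sigma = 0)
  st <- channel_stats(sm, min_pixels = 1)
  r <- st$stats[st$stats$channel == "R", ]
  expect_equal(r$median, 30)
  expect_equal(r$q1, 20)
  expect_equal(r$q3, 40)

  cimg <- flat_image(32, c(128, 128, 128))
  creg <- rect_region(32, 5:12, 5:12)
  cst <- channel_stats(masked_gaussian_smooth(cimg, creg, 2))
  expect_true(all(cst$stats$median == 128 & cst$stats$q1 == 128 &
                    cst$stats$q3 == 128))

  small <- rect_region(32, 1:2, 1:5)   # 10 px < default 25 px minimum
  expect_error(channel_stats(masked_gaussian_smooth(cimg, small, 0)),
               class = "artix_region_too_small")
})

test_that("quantiles match an independent sort-based oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(25:400, 1)
    vals <- runif(n, 0, 255)
    img <- flat_image(32, c(0, 0, 0))
    reg_idx <- sample(32 * 32, n)
    m <- matrix(FALSE, 32, 32); m[reg_idx] <- TRUE
    ch <- img[, , 1]; ch[reg_idx] <- vals; img[, , 1] <- ch
    st <- channel_stats(masked_gaussian_smooth(img, make_region(m), 0))
    r <- st$stats[st$stats$channel == "R", ]
    expect_equal(r$q1, oracle_quantile(vals, 0.25), tolerance = 1e-9)
    expect_equal(r$median, oracle_quantile(vals, 0.5), tolerance = 1e-9)
    expect_equal(r$q3, oracle_quantile(vals, 0.75), tolerance = 1e-9)
  }
})

test_that("the redness formula is median plus midhinge of the red channel", {
  fake_stats <- function(med, q1, q3) {
    structure(list(stats = data.frame(channel = c("R", "G", "B"),
                                      median = c(med, 0, 0),
                                      q1 = c(q1, 0, 0), q3 = c(q3, 0, 0)),
                   n_pixels = 100L), class = "channel_stats")
  }
  expect_equal(redness_score(fake_stats(200, 180, 220)), 400)
  expect_equal(redness_score(fake_stats(255, 255, 255)), 510)
  expect_equal(redness_score(fake_stats(128, 128, 128)), 256)
})

test_that("ARTIX is the mean redness over non-thumb regions", {
  size <- 96
  img <- flat_image(size, c(0, 60, 60))
  regions <- list()
  reds <- c(150, 150, 150, 150, 200, 200, 200, 200)
  fingers <- rep(c("index", "middle", "ring", "pinky"), 2)
  hands <- rep(c("left", "right"), each = 4)
  for (i in 1:8) {
    rows <- (2 + (i - 1) * 11):(9 + (i - 1) * 11)
    regions[[i]] <- rect_region(size, rows, 10:20, fingers[i], hands[i])
    img[rows, 10:20, 1] <- reds[i]
  }
  sc <- artix_score(img, regions, sigma = 0)
  expect_equal(sc$value, mean(2 * reds))   # 4 at 300, 4 at 400 -> 350
  expect_equal(sc$value, 350)
  expect_equal(sc$n_regions, 8L)

  uni <- img
  for (i in 1:8) uni[regions[[i]]$mask] <- NA  # guard: masks disjoint
  expect_equal(sum(is.na(uni)), 3L * 8L * 8L * 11L)

  img400 <- img
  img400[, , 1][Reduce(`|`, lapply(regions, function(r) r$mask))] <- 200
  expect_equal(artix_score(img400, regions, sigma = 0)$value, 400)
})

test_that("thumb pixels never influence the score", {
  for (s in 1:3) {
    h <- tiny_hand(seed = s, noise_sd = 3)
    regs <- truth_regions(h)
    base <- artix_score(h$image, regs)
    recol <- h$image
    thumb <- h$digit_truth == 1
    recol[, , 1][thumb] <- 0
    recol[, , 2][thumb] <- 0
    recol[, , 3][thumb] <- 255
    expect_identical(artix_score(recol, regs)$value, base$value)
  }
})

test_that("raising red values in one finger never decreases the score", {
  h <- tiny_hand(seed = 4, noise_sd = 3)
  regs <- truth_regions(h)
  base <- artix_score(h$image, regs)$value
  for (delta in c(5, 20, 60)) {
    up <- h$image
    idx <- h$digit_truth == 3   # middle finger
    up[, , 1][idx] <- pmin(up[, , 1][idx] + delta, 255)
    expect_gte(artix_score(up, regs)$value, base)
  }
})

test_that("the score is invariant to region order", {
  h <- tiny_hand(seed = 6, noise_sd = 3)
  regs <- truth_regions(h)
  a <- artix_score(h$image, regs)$value
  b <- artix_score(h$image, rev(regs))$value
  expect_equal(a, b)
})

test_that("small regions are dropped with a warning, too many is an error", {
  size <- 96
  img <- flat_image(size, c(150, 60, 60))
  regions <- lapply(1:8, function(i)
    rect_region(size, (2 + (i - 1) * 11):(9 + (i - 1) * 11), 10:20,
                rep(c("index", "middle", "ring", "pinky"), 2)[i],
                rep(c("left", "right"), each = 4)[i]))
  # shrink two regions below the 25 px minimum: score still computed
  regions[[1]]$mask[] <- FALSE; regions[[1]]$mask[2, 10:13] <- TRUE
  regions[[2]]$mask[] <- FALSE; regions[[2]]$mask[13, 10:13] <- TRUE
  expect_warning(sc <- artix_score(img, regions, sigma = 0),
                 class = "artix_dropped_regions")
  expect_equal(sc$n_regions, 6L)
  expect_equal(sc$value, 300)
  # three dropped of eight -> fewer than 6 remain -> error
  regions[[3]]$mask[] <- FALSE; regions[[3]]$mask[24, 10:13] <- TRUE
  expect_error(suppressWarnings(artix_score(img, regions, sigma = 0)),
               class = "artix_too_few_regions")
})

test_that("sparse outliers barely move the smoothed redness", {
  img <- flat_image(96, c(120, 80, 80))
  reg <- rect_region(96, 10:80, 10:80, "index")
  n <- sum(reg$mask)
  set.seed(7)
  idx <- sample(which(reg$mask), ceiling(0.01 * n))
  ch <- img[, , 1]
  ch[idx] <- ifelse(runif(length(idx)) < 0.5, 0, 255)
  dirty <- img; dirty[, , 1] <- ch
  clean_score <- redness_score(channel_stats(masked_gaussian_smooth(img, reg, 2)))
  dirty_score <- redness_score(channel_stats(masked_gaussian_smooth(dirty, reg, 2)))
  expect_lt(abs(clean_score - dirty_score), 2)
})
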