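test_that("hsv_mask applies both saturation conditions strictly", {
  # one pixel per case: S/V > 0.2 & S > 0.19 must both hold
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- fruitmorph:::hsv_to_rgb(0, 0.30, 1.00)  # ratio .3, S .3
  img[1, 2, ] <- fruitmorph:::hsv_to_rgb(0, 0.15, 0.50)  # ratio .3, S .15
  img[1, 3, ] <- c(0, 0, 0)                              # V = 0
  m <- hsv_mask(img)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))
})

test_that("hsv_mask equals a per-pixel brute-force evaluation", {
  set.seed(42)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  m <- hsv_mask(img)
  oracle <- matrix(FALSE, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    hsv <- grDevices::rgb2hsv(matrix(img[i, j, ], 3), maxColorValue = 1)
    s <- hsv[2]; v <- hsv[3]
    oracle[i, j] <- v > 0 && s / v > 0.2 && s > 0.19
  }
  expect_identical(m, oracle)
})

test_that("otsu threshold matches the exhaustive between-class oracle", {
  set.seed(7)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 4,
                runif(1024),
                c(rnorm(500, 0.2, 0.05), rnorm(500, 0.7, 0.05)),
                rbeta(1024, 0.5, 0.5),
                sample(c(0.1, 0.9), 1024, replace = TRUE))
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
})

test_that("background difference segments a two-level disk exactly", {
  bg <- array(0.3, c(64, 64, 3))
  img <- bg
  d <- disk_mask(64, 20)
  for (ch in 1:3) { p <- img[, , ch]; p[d] <- 0.8; img[, , ch] <- p }
  m <- background_diff_mask(img, bg)
  expect_identical(m, d)
})

test_that("identical image and background give an empty mask with warning", {
  bg <- array(0.3, c(16, 16, 3))
  expect_warning(m <- background_diff_mask(bg, bg), "identical")
  expect_false(any(m))
  expect_true(attr(m, "constant_difference"))
})

test_that("background_diff_mask rejects shape mismatches", {
  expect_error(background_diff_mask(array(0, c(4, 4, 3)),
                                    array(0, c(5, 4, 3))), "dimensions")
})

test_that("difference path is invariant to a common additive shift", {
  set.seed(3)
  bg <- array(runif(32 * 32 * 3, 0.2, 0.4), c(32, 32, 3))
  img <- bg
  d <- disk_mask(32, 9)
  for (ch in 1:3) { p <- img[, , ch]; p[d] <- p[d] + 0.4; img[, , ch] <- p }
  m1 <- background_diff_mask(img, bg)
  m2 <- background_diff_mask(img + 0.1, bg + 0.1)
  expect_identical(m1, m2)
})

test_that("union identity: with an empty difference mask the result is m1", {
  # image == background, but both contain a saturated disk that m1 catches
  img <- flat_hsv_image(64, 64, 0.1, 0.05, 0.9)
  d <- disk_mask(64, 15)
  red <- fruitmorph:::hsv_to_rgb(0, 0.9, 0.8)
  for (ch in 1:3) { p <- img[, , ch]; p[d] <- red[ch]; img[, , ch] <- p }
  suppressWarnings(seg <- segment_fruit(img, img))
  expect_false(any(seg$m2))
  expect_identical(seg$mask, d)
  expect_identical(seg$area_px, sum(d))
})

test_that("largest-component rule removes a small bright speck", {
  rs <- quick_render()
  img <- rs$images[[1]]
  # paint a 3x3 saturated speck far from the fruit (< 1% of its area)
  red <- fruitmorph:::hsv_to_rgb(0.05, 0.95, 0.9)
  for (ch in 1:3) { p <- img[, , ch]; p[3:5, 3:5] <- red[ch]
    img[, , ch] <- p }
  seg <- segment_fruit(img, rs$backgrounds[[1]])
  expect_false(any(seg$mask[1:8, 1:8]))
  expect_true(any(seg$m1[3:5, 3:5] | seg$m2[3:5, 3:5]))
})

test_that("no fruit detected raises an error naming the image", {
  bg <- flat_hsv_image(32, 32, 0.1, 0.05, 0.9)
  suppressWarnings(
    expect_error(segment_fruit(bg, bg, image_id = "cam3_shot"), "cam3_shot"))
})

test_that("post-processing only selects and fills, never invents pixels", {
  rs <- quick_render(seed = 11)
  for (k in c(1, 5)) {
    seg <- segment_fruit(rs$images[[k]], rs$backgrounds[[k]])
    u <- seg$m1 | seg$m2
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(seg$mask * 1),
                                              EBImage::makeBrush(3, "box")))
    expect_true(all(dil[u] > 0.5))
    filled <- EBImage::imageData(
      EBImage::fillHull(EBImage::Image(u * 1))) > 0.5
    expect_true(all(filled[seg$mask]))
  }
})

test_that("segmentation recovers the renderer truth mask", {
  mixtures <- list(
    data.frame(h = 0.00, s = 0.85, v = 0.75, weight = 1),       # red
    data.frame(h = 0.15, s = 0.80, v = 0.90, weight = 1),       # yellow
    data.frame(h = c(0.33, 0.02), s = 0.8, v = 0.8,
               weight = c(0.6, 0.4)))                            # green/red
  for (i in seq_along(mixtures)) {
    rs <- quick_render(mixture = mixtures[[i]], seed = 20 + i)
    for (k in 1:5) {
      seg <- segment_fruit(rs$images[[k]], rs$backgrounds[[k]])
      expect_gt(band_excluded_iou(seg$mask, rs$truth_masks[[k]]), 0.99)
    }
  }
})
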