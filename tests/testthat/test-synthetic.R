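test_that("fruit_spec validates its invariants", {
  bad <- circle_profile(3); bad[10] <- -1
  expect_error(fruit_spec(bad, circle_profile(3)), "positive")
  expect_error(fruit_spec(circle_profile(3)[-1], circle_profile(3)), "360")
  expect_error(fruit_spec(circle_profile(3), circle_profile(3),
                          peel_hue_mixture = data.frame(h = 0, s = 0.9,
                                                        v = 0.8,
                                                        weight = 0.9)),
               "sum to 1")
})

test_that("a fruit larger than the frame is rejected", {
  spec <- fruit_spec(circle_profile(10), circle_profile(10))
  expect_error(render_fruit(spec, calibration = 0.01, width = 324,
                            height = 270), "larger than frame")
})

test_that("constant-radius spec renders pixel disks in all five views", {
  rs <- quick_render(side = circle_profile(3), top = circle_profile(3),
                     cm_per_px = 0.01, width = 700, height = 650)
  for (k in 1:5) {
    p <- to_polar(rs$truth_masks[[k]])
    expect_true(all(abs(p$radius_deg - 300) <= 1))
  }
})

test_that("a pure-red mixture renders fruit pixels at hue 0 after quantization", {
  rs <- quick_render(mixture = data.frame(h = 0, s = 0.9, v = 0.8,
                                          weight = 1), seed = 2)
  img <- rs$images[[1]]; m <- rs$truth_masks[[1]]
  # interior pixels only: the <= 1 px antialiasing band blends with the
  # background and is not part of the color contract
  interior <- EBImage::imageData(
    EBImage::erode(EBImage::Image(m * 1), EBImage::makeBrush(5, "box"))) > 0.5
  n <- prod(dim(m))
  sel <- which(interior)
  rgb <- rbind(img[sel], img[sel + n], img[sel + 2 * n])
  h <- grDevices::rgb2hsv(rgb, maxColorValue = 1)[1, ]
  h <- pmin(h, 1 - h)  # hue distance to 0, circular
  expect_true(all(h <= 0.5 / 64))
  expect_gt(length(sel), 0.8 * sum(m))
})

test_that("image and background differ only around the truth mask", {
  rs <- quick_render(seed = 17)
  for (k in c(2, 5)) {
    diffpx <- apply(abs(rs$images[[k]] - rs$backgrounds[[k]]), c(1, 2), max)
    dil <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(rs$truth_masks[[k]] * 1),
                      EBImage::makeBrush(5, "box"))) > 0.5
    expect_true(all(diffpx[!dil] == 0))
    expect_gt(sum(rs$truth_masks[[k]]), 0)
  }
})

test_that("rendered background defeats the HSV mask by construction", {
  rs <- quick_render(seed = 23)
  m1 <- hsv_mask(rs$backgrounds[[1]])
  expect_false(any(m1))
})

test_that("re-extraction recovers programmed geometry and color", {
  rs <- quick_render(side = ellipse_profile(3.5, 2.8),
                     top = circle_profile(3.0),
                     mixture = data.frame(h = c(0.05, 0.33), s = 0.85,
                                          v = 0.8, weight = c(0.6, 0.4)),
                     seed = 31, cm_per_px = 0.02, width = 648, height = 540)
  seg <- segment_fruit(rs$images[[1]], rs$backgrounds[[1]])
  d <- dimensions(seg$mask, 0.02)
  expect_equal(unname(d[["width_cm"]]), 7.0, tolerance = 0.01)
  expect_equal(unname(d[["height_cm"]]), 5.6, tolerance = 0.01)
  masks <- lapply(1:4, function(k)
    segment_fruit(rs$images[[k]], rs$backgrounds[[k]])$mask)
  h <- fruit_histogram(rs$images[1:4], masks)
  mass_near <- function(hue) {
    bin <- findInterval(hue, h$hue_breaks, rightmost.closed = TRUE)
    sum(h$hue_density[max(bin - 1, 1):min(bin + 1, 64)]) / 64
  }
  expect_equal(mass_near(0.05), 0.6, tolerance = 0.03 / 0.6)
  expect_equal(mass_near(0.33), 0.4, tolerance = 0.03 / 0.4)
})

test_that("extracted asymmetry is monotone in the programmed skew", {
  skews <- c(0, 0.03, 0.06, 0.09, 0.12)
  asym <- vapply(skews, function(sk) {
    rs <- quick_render(side = ovoid_profile_cm(), skew = sk, seed = 3)
    seg <- segment_fruit(rs$images[[1]], rs$backgrounds[[1]])
    symmetrize(seg$mask)$asymmetry
  }, numeric(1))
  expect_true(all(diff(asym) >= 0))
  expect_identical(asym[1], 0)
  expect_gt(asym[length(asym)], 0)
})

test_that("write_sample follows the directory dialect and round-trips", {
  rs <- quick_render(weight_g = 182.4, seed = 41, cm_per_px = 0.06,
                     width = 160, height = 140)
  root <- withr::local_tempdir()
  paths <- write_sample(rs, root, id = "T042", index = 7)
  expect_match(paths[3], "images/T042/cam3/T042_cam3_0007_[0-9]{8}_[0-9]{6}\\.tif")
  rb <- read_image_with_weight(paths[3])
  expect_identical(rb$image, rs$images[[3]])
  expect_identical(rb$weight_g, 182.4)
  expect_error(write_sample(rs, root, id = "T042", index = 7),
               "overwrite")
})

test_that("simulate_study programs per-cultivar trait means", {
  st <- simulate_study(n_cultivars = 4, n_fruit = 400, seed = 10)
  prog <- attr(st, "programmed")
  expect_identical(nrow(st), 1600L)
  for (i in 1:4) {
    sub <- st[st$cultivar == prog$cultivar[i], ]
    expect_equal(mean(sub$width_mean_cm), prog$width_mean_cm[i],
                 tolerance = 0.02)
    expect_equal(mean(sub$weight_g), prog$weight_g[i], tolerance = 0.05)
  }
  expect_identical(st, simulate_study(n_cultivars = 4, n_fruit = 400,
                                      seed = 10))
})
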