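test_that("polar profile of a disk is flat at the disk radius", {
  p <- to_polar(disk_mask(301, 100))
  expect_true(all(abs(p$radius_deg - 100) <= 0.6))
  expect_equal(unname(p$centroid), c(151, 151), tolerance = 1e-6)
})

test_that("polar profile of an ellipse matches the analytic form", {
  p <- to_polar(ellipse_mask(301, 301, 120, 80))
  th <- (0:359) * pi / 180
  analytic <- 120 * 80 / sqrt((80 * cos(th))^2 + (120 * sin(th))^2)
  expect_true(all(abs(p$radius_deg - analytic) < 1))
})

test_that("square diagonal radius is side/2 * sqrt(2)", {
  p <- to_polar(square_mask(201, 100))
  expect_equal(p$radius_deg[46], 50 * sqrt(2), tolerance = 1 / (50 * sqrt(2)))
  expect_equal(p$radius_deg[1], 50, tolerance = 1 / 50)
})

test_that("profile polygon area matches mask pixel area within 2%", {
  shapes <- list(disk_mask(301, 100), ellipse_mask(301, 301, 120, 80),
                 square_mask(201, 120), random_blob(seed = 4),
                 random_blob(seed = 9))
  for (m in shapes) {
    a <- polar_area(to_polar(m))
    expect_lt(abs(a - sum(m)) / sum(m), 0.02)
  }
})

test_that("to_polar rejects an empty mask", {
  expect_error(to_polar(matrix(FALSE, 5, 5)), "empty")
})

test_that("asymmetry of a centered odd-sized disk is exactly zero", {
  expect_identical(asymmetry_index(disk_mask(201, 80)), 0)
})

test_that("asymmetry agrees with the per-pixel XOR oracle on random blobs", {
  for (s in 1:10) {
    m <- random_blob(n = 101, r0 = 30, seed = s)
    a <- asymmetry_index(m)
    o <- oracle_mirror_asym(m)
    expect_equal(a, o, tolerance = 1e-12)
  }
})

test_that("right triangle is asymmetric and matches the oracle", {
  m <- outer(1:80, 1:80, function(i, j) i + j <= 70)
  expect_equal(asymmetry_index(m), oracle_mirror_asym(m), tolerance = 1e-12)
  expect_gt(asymmetry_index(m), 0)
})

test_that("asymmetry is invariant to horizontal translation and mirroring", {
  m <- random_blob(n = 121, r0 = 32, seed = 3)
  wide <- matrix(FALSE, nrow(m), ncol(m) + 40)
  wide[, 21:(20 + ncol(m))] <- m
  expect_equal(asymmetry_index(wide), asymmetry_index(m), tolerance = 1e-12)
  expect_equal(asymmetry_index(m[, rev(seq_len(ncol(m)))]),
               asymmetry_index(m), tolerance = 1e-12)
})

test_that("symmetrize recovers a known rotation of an ellipse", {
  m <- rotate_mask(ellipse_mask(241, 241, 90, 60), 5)
  s <- symmetrize(m)
  expect_lt(abs(s$symmetry_angle_deg - (-5)), 0.5)
  expect_lt(s$asymmetry, 0.01)
})

test_that("symmetrize of a symmetric disk returns angle 0, asymmetry 0", {
  s <- symmetrize(disk_mask(151, 60))
  expect_identical(s$symmetry_angle_deg, 0)
  expect_identical(s$asymmetry, 0)
})

test_that("symmetrize never increases asymmetry", {
  for (seed in c(2, 6, 8)) {
    m <- random_blob(n = 121, r0 = 32, seed = seed)
    s <- symmetrize(m)
    expect_lte(s$asymmetry, asymmetry_index(m))
  }
})

test_that("grid minimum is within one step of a 10x finer grid", {
  m <- rotate_mask(ellipse_mask(201, 201, 70, 45), 3.4)
  coarse <- symmetrize(m, range_deg = 5, step_deg = 0.25)
  fine <- symmetrize(m, range_deg = 5, step_deg = 0.025)
  expect_lte(abs(coarse$symmetry_angle_deg - fine$symmetry_angle_deg), 0.25)
})

test_that("dimensions scale linearly with the calibration", {
  d <- disk_mask(901, 300)
  dim1 <- dimensions(d, 0.01)
  expect_equal(unname(dim1), c(6.01, 6.01), tolerance = 0.02 / 6.01)
  dim2 <- dimensions(d, 0.02)
  expect_equal(unname(dim2), 2 * unname(dim1), tolerance = 1e-12)
})

test_that("top circles of a constant profile collapse to that radius", {
  tc <- top_circles(circle_profile(250))
  expect_equal(tc$radius_mean_px, 250)
  expect_equal(tc$radius_in_px, 250)
  expect_equal(tc$radius_circ_px, 250)
  expect_identical(tc$radius_std_nor, 0)
})

test_that("top circles of an ellipse recover the semi-axes", {
  p <- to_polar(ellipse_mask(301, 301, 120, 80), view = "top")
  tc <- top_circles(p)
  expect_lt(abs(tc$radius_in_px - 80), 1)
  expect_lt(abs(tc$radius_circ_px - 120), 1)
  # std_nor against direct computation on the analytic profile
  analytic <- ellipse_profile(120, 80)
  expect_equal(tc$radius_std_nor, sd(analytic / mean(analytic)),
               tolerance = 0.02)
})

test_that("incircle <= mean <= circumcircle on random profiles", {
  set.seed(5)
  for (i in 1:10) {
    r <- 100 * (1 + runif(360, -0.2, 0.2))
    tc <- top_circles(r)
    expect_lte(tc$radius_in_px, tc$radius_mean_px)
    expect_lte(tc$radius_mean_px, tc$radius_circ_px)
  }
})

test_that("profile export round-trips through text", {
  p <- to_polar(ellipse_mask(151, 151, 50, 35))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_profile(p, path, cm_per_px = 0.01)
  back <- read.delim(path)
  expect_equal(back$radius_px, signif(p$radius_deg, 6), tolerance = 1e-5)
  expect_equal(nrow(back), 360L)
})
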