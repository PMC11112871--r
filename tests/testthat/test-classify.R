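test_that("default side library has 13 distinguishable mean-1 outlines", {
  lib <- default_reference_library("side")
  expect_identical(lib$class_id, 1:13)
  expect_true(all(c("rectangular", "rectangular conical",
                    "flattened spherical") %in% lib$name))
  expect_true(all(abs(rowMeans(lib$profiles) - 1) < 1e-9))
  C <- cor(t(lib$profiles))
  diag(C) <- NA
  expect_lt(max(C, na.rm = TRUE), 0.995)
})

test_that("each reference outline self-classifies with correlation 1", {
  lib <- default_reference_library("side")
  for (i in 1:13) {
    cl <- classify_shape(lib$profiles[i, ], lib)
    expect_identical(cl$shape_class, i)
    expect_equal(cl$corr, 1, tolerance = 1e-12)
  }
})

test_that("classification is scale-free", {
  lib <- default_reference_library("side")
  cl <- classify_shape(lib$profiles[4L, ] * 2, lib)
  expect_identical(cl$shape_class, 4L)
  expect_equal(cl$corr, 1, tolerance = 1e-12)
})

test_that("classes are recovered under 3% multiplicative radial noise", {
  lib <- default_reference_library("side")
  set.seed(101)
  hits <- 0L; total <- 0L
  for (i in 1:13) for (rep in 1:100) {
    noisy <- lib$profiles[i, ] * (1 + rnorm(360, 0, 0.03))
    hits <- hits + (classify_shape(noisy, lib)$shape_class == i)
    total <- total + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("constant-profile corner cases are defined", {
  d <- (0:359) * pi / 180
  lib <- fruitmorph:::new_reference_library(
    1:2, c("flat", "wavy"), rbind(rep(1, 360), 1 + 0.1 * cos(2 * d)),
    "side")
  # constant candidate vs constant reference: equality -> 1, with warning
  expect_warning(cl <- classify_shape(rep(5, 360), lib), "constant")
  expect_identical(cl$shape_class, 1L)
  expect_equal(cl$corr, 1)
  # non-constant candidate vs constant reference: correlation 0
  cl2 <- classify_shape(1 + 0.2 * cos(2 * d), lib)
  expect_identical(unname(cl2$per_class_corr[1L]), 0)
  expect_identical(cl2$shape_class, 2L)
})

test_that("average shape is degenerate-safe and linear", {
  p <- ellipse_profile(3, 2.4)
  avg <- average_shape(rbind(p, p, p))
  expect_equal(avg$mean_radius_deg, p)
  expect_identical(avg$sd_radius_deg, rep(0, 360))
  expect_identical(average_shape(matrix(p, 1))$n_fruit, 1L)
  two <- average_shape(rbind(circle_profile(90), circle_profile(110)))
  expect_equal(two$mean_radius_deg, rep(100, 360))
  expect_equal(two$sd_radius_deg, rep(sd(c(90, 110)), 360))
  # mean of per-degree means equals mean of per-profile means
  set.seed(8)
  profs <- matrix(100 * (1 + runif(5 * 360, -0.1, 0.1)), 5)
  expect_equal(mean(average_shape(profs)$mean_radius_deg),
               mean(rowMeans(profs)))
})

test_that("average shape rejects mixed views", {
  a <- to_polar(disk_mask(61, 20), view = "side")
  b <- to_polar(disk_mask(61, 20), view = "top")
  expect_error(average_shape(list(a, b)), "mix")
})

test_that("k-means recovers well-separated shape families", {
  set.seed(12)
  fams <- rbind(
    t(replicate(15, circle_profile(1) * (1 + rnorm(360, 0, 0.01)))),
    t(replicate(15, ellipse_profile(1, 1.4) * (1 + rnorm(360, 0, 0.01)))),
    t(replicate(15, ellipse_profile(1.4, 1) * (1 + rnorm(360, 0, 0.01)))))
  truth <- rep(1:3, each = 15)
  cl <- cluster_shapes(fams, k = 3, seed = 2)
  expect_identical(length(unique(cl$labels)), 3L)
  # perfect recovery up to permutation: labels constant within families
  for (f in 1:3)
    expect_identical(length(unique(cl$labels[truth == f])), 1L)
  tab <- table(truth, cl$labels)
  expect_true(all(apply(tab, 1, max) == 15))
})

test_that("k = n puts every profile in its own cluster with zero SS", {
  profs <- rbind(circle_profile(1), ellipse_profile(1, 1.3),
                 ellipse_profile(1.3, 1), ellipse_profile(1, 1.6))
  cl <- cluster_shapes(profs, k = 4, seed = 3)
  expect_identical(sort(cl$labels), 1:4)
  expect_equal(cl$tot_withinss, 0)
})

test_that("canonical labels are invariant to profile order", {
  set.seed(30)
  fams <- rbind(
    t(replicate(10, circle_profile(1) * (1 + rnorm(360, 0, 0.01)))),
    t(replicate(10, ellipse_profile(1, 1.5) * (1 + rnorm(360, 0, 0.01)))))
  perm <- sample(nrow(fams))
  a <- cluster_shapes(fams, k = 2, seed = 4)
  b <- cluster_shapes(fams[perm, ], k = 2, seed = 4)
  expect_identical(a$labels[perm], b$labels)
})

test_that("within-cluster SS is non-increasing in k", {
  set.seed(44)
  profs <- t(replicate(40, ellipse_profile(1, runif(1, 0.8, 1.6)) *
                         (1 + rnorm(360, 0, 0.02))))
  ss <- vapply(3:8, function(k)
    cluster_shapes(profs, k = k, seed = 9, nstart = 10)$tot_withinss,
    numeric(1))
  expect_true(all(diff(ss) <= 1e-9))
})

test_that("library files round-trip and are validated", {
  lib <- default_reference_library("side")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_library(lib, path)
  back <- load_reference_library(path)
  expect_equal(back$profiles, lib$profiles, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_identical(back$class_id, lib$class_id)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("class_id", "name", sprintf("deg%03d", 0:358)),
                     collapse = "\t"),
               paste(c("1", "x", rep("1", 359)), collapse = "\t")), bad)
  expect_error(load_reference_library(bad), "362")

  tab <- read.delim(path)
  tab$class_id <- 1L
  dup <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_reference_library(dup), "duplicate")

  tab2 <- read.delim(path)
  tab2[2, 10] <- -1
  neg <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2, neg, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_reference_library(neg), "row 2")
})

test_that("lag registration finds a rotated match", {
  lib <- default_reference_library("side")
  shifted <- c(lib$profiles[9L, 31:360], lib$profiles[9L, 1:30])
  cl <- classify_shape(shifted, lib, register = "lag")
  expect_identical(cl$shape_class, 9L)
  expect_equal(cl$corr, 1, tolerance = 1e-9)
})
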