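test_that("thresholding produces the superlevel set", {
  z <- matrix(0, 8, 8)
  expect_true(all(threshold_map(z, 0.5) == 0))
  expect_error(threshold_map(z, 0), "> 0")

  blob <- generate_density_fixture(data.frame(x = 16L, y = 16L, class = 0L),
                                   c(32, 32), sigma = 3)[, , 1]
  bin <- threshold_map(blob, 0.5)
  expect_identical(sort(unique(as.vector(bin))), c(0L, 255L))
  expect_identical(sum(bin == 255L), sum(blob >= 0.5))  # direct enumeration
  expect_true(all(threshold_map(blob, max(blob) + 1) == 0))
})

test_that("distance transform gives Euclidean distance to background", {
  expect_true(all(distance_transform(matrix(0, 9, 9)) == 0))

  single <- matrix(0, 9, 9); single[5, 5] <- 1
  d <- distance_transform(single)
  expect_equal(d[5, 5], 1)
  expect_true(all(d[-5, ] == 0) && all(d[, -5][5, ] == 0))

  block <- matrix(0, 11, 11); block[3:9, 3:9] <- 255
  d2 <- distance_transform(block)
  bgpix <- which(block == 0, arr.ind = TRUE)
  brute <- min(sqrt((bgpix[, 1] - 6)^2 + (bgpix[, 2] - 6)^2))
  expect_equal(d2[6, 6], brute)
  expect_equal(d2[6, 6], 4)
})

test_that("watershed handles constants, ridges and masks", {
  expect_true(all(watershed_labels(matrix(5, 6, 6)) == 1L))

  ridge <- matrix(c(0, 1, 2, 3, 2, 1, 0), 1)
  lab <- watershed_labels(ridge)
  expect_identical(length(unique(as.vector(lab))), 2L)
  expect_identical(lab[1, 1], lab[1, 2])
  expect_identical(lab[1, 6], lab[1, 7])
  expect_false(lab[1, 1] == lab[1, 7])

  relief <- matrix(runif(64), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[2:4, 2:4] <- TRUE
  labm <- watershed_labels(relief, mask = mask)
  expect_true(all(labm[!mask] == 0L))
  expect_true(all(labm[mask] > 0L))
  expect_error(watershed_labels(matrix(c(1, NA), 1)), "finite")
})

test_that("priority-flood equals exhaustive level-by-level flooding", {
  withr::with_seed(2024, {
    for (i in 1:60) {
      H <- sample(2:8, 1); W <- sample(2:8, 1)
      relief <- matrix(sample.int(10000, H * W), H, W)  # all distinct
      conn <- sample(c(4L, 8L), 1)
      fast <- watershed_labels(relief, conn)
      slow <- oracle_watershed(relief, conn)
      expect_identical(canon_labels(fast), canon_labels(slow))
    }
  })
})

test_that("watershed output partitions the foreground into connected basins", {
  withr::with_seed(7, {
    for (i in 1:20) {
      relief <- matrix(sample.int(500, 49, replace = TRUE), 7, 7)
      lab <- watershed_labels(relief, 8)
      expect_true(all(lab > 0L))                     # covers every pixel
      K <- max(lab)
      expect_identical(sort(unique(as.vector(lab))), seq_len(K))
      for (k in seq_len(K))
        expect_true(is_connected_region(lab, k, 8))
    }
  })
})

test_that("extract_centers recovers well-separated planted modes", {
  expect_identical(
    nrow(extract_centers(structure(array(0, c(32, 32, 3)),
                                   class = "density_map"),
                         postprocess_config())$points), 0L)

  modes <- data.frame(x = c(10L, 40L), y = c(20L, 30L), class = 1L)
  m <- generate_density_fixture(modes, c(64, 64), sigma = 3)
  det <- extract_centers(m, postprocess_config(threshold = 0.4))
  expect_identical(nrow(det$points), 2L)
  expect_true(all(det$points$class == 1L))
  for (i in 1:2) {
    d <- sqrt((det$points$x - modes$x[i])^2 + (det$points$y - modes$y[i])^2)
    expect_lte(min(d), 1)
  }
})

test_that("watershed splits overlapping blobs into separate detections", {
  # two modes 8 px apart: their 0.4-superlevel disks (radius ~4) merge into
  # one connected region with two distance-transform maxima
  modes <- data.frame(x = c(28L, 36L), y = c(32L, 32L), class = 0L)
  m <- generate_density_fixture(modes, c(64, 64), sigma = 3,
                                combine_mode = "max")
  bin <- threshold_map(m[, , 1], 0.4)
  lab1 <- watershed_labels(matrix(1, 64, 64), mask = bin > 0)
  expect_identical(max(lab1), 1L)  # single connected foreground region
  det <- extract_centers(m, postprocess_config(threshold = 0.4))
  expect_identical(nrow(det$points), 2L)
  # brute-force flooding confirms two basins on the negated transform
  D <- distance_transform(bin)
  oracle <- oracle_watershed(-D, 8, mask = bin > 0)
  expect_identical(max(oracle), 2L)
})

test_that("raising the threshold never increases the detection count", {
  withr::with_seed(5, {
    modes <- data.frame(x = sample(8:56, 6), y = sample(8:56, 6),
                        class = sample(0:2, 6, TRUE))
  })
  m <- generate_density_fixture(modes, c(64, 64), sigma = 2.5,
                                combine_mode = "max")
  counts <- vapply(c(0.2, 0.35, 0.5, 0.7, 0.9, 1.05),
                   function(T) nrow(extract_centers(
                     m, postprocess_config(threshold = T))$points),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[length(counts)], 0L)
})

test_that("small regions are suppressed by min_region_area", {
  m <- array(0, c(32, 32, 3))
  m[16, 16, 1] <- 1          # single-pixel spike
  m[5:9, 5:9, 1] <- 1        # 25-px block
  det <- extract_centers(structure(m, class = "density_map"),
                         postprocess_config(threshold = 0.5,
                                            min_region_area = 4))
  expect_identical(nrow(det$points), 1L)
  det0 <- extract_centers(structure(m, class = "density_map"),
                          postprocess_config(threshold = 0.5,
                                             min_region_area = 0))
  expect_identical(nrow(det0$points), 2L)
})
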