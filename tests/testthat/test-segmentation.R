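test_that("3x3 mean smoothing matches direct convolution", {
  expect_equal(smooth_mean3x3(matrix(7, 5, 5)), matrix(7, 5, 5))

  imp <- matrix(0, 5, 5); imp[3, 3] <- 9
  out <- smooth_mean3x3(imp)
  expect_equal(out[2:4, 2:4], matrix(1, 3, 3))
  expect_equal(sum(out), 9)

  ramp <- matrix(rep(1:6, each = 6), 6, 6)
  expect_equal(smooth_mean3x3(ramp)[2:5, 2:5], ramp[2:5, 2:5])

  expect_error(smooth_mean3x3(matrix(1, 2, 5)), "3x3")
})

test_that("Otsu binarization maximizes 256-bin between-class variance", {
  x <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  m <- otsu_binarize(x)
  expect_identical(mask_of(m), mask_of(x == 200))

  expect_warning(m0 <- otsu_binarize(matrix(5, 4, 4)), "constant")
  expect_false(any(m0))

  set.seed(11)
  for (i in 1:20) {
    x <- matrix(runif(256, 0, 4000)^1.3, 16, 16)
    m <- otsu_binarize(x)
    expect_identical(mask_of(m), mask_of(x > otsu_oracle_threshold(x)))
    # scale equivariance: doubling intensities scales the bins linearly
    expect_identical(mask_of(otsu_binarize(2 * x)), mask_of(m))
  }
})

test_that("mask border smoothing removes spurs and keeps bulk area", {
  d <- disk_mask(10)
  expect_identical(smooth_mask_borders(d, 0L), d)

  spur <- d
  spur[5, 16] <- TRUE  # 1-px spur sticking out of the top of the disk
  sm <- smooth_mask_borders(spur, 2L)
  expect_false(sm[5, 16])
  expect_lt(abs(sum(sm) - sum(d)) / sum(d), 0.05)

  full <- matrix(TRUE, 20, 20)
  expect_identical(smooth_mask_borders(full, 2L), full)
})

test_that("watershed splits overlapping disks and is a no-op otherwise", {
  d <- disk_mask(10, size = 40)
  lab <- watershed_split(d, 2)
  expect_identical(attr(lab, "n_labels"), 1L)
  expect_identical(unname(lab > 0), unname(d))  # disk minus nothing

  two <- disk_mask(10, size = 50, center = c(25, 17)) |
         disk_mask(10, size = 50, center = c(25, 33))
  lab2 <- watershed_split(two, 2)
  areas <- tabulate(lab2[lab2 > 0])
  lone <- sum(disk_mask(10))
  expect_identical(attr(lab2, "n_labels"), 2L)
  expect_true(all(abs(areas - lone) / lone < 0.2))
  # labels live inside the mask; what is lost to divide lines stays small
  expect_true(all(two[lab2 > 0]))
  expect_lt(sum(two) - sum(lab2 > 0), 60)

  sep <- disk_mask(8, size = 60, center = c(15, 15)) |
         disk_mask(8, size = 60, center = c(45, 45))
  lab3 <- watershed_split(sep, 2)
  expect_identical(attr(lab3, "n_labels"), 2L)
  expect_identical(unname(lab3 > 0), unname(sep))

  empty <- watershed_split(matrix(FALSE, 8, 8), 2)
  expect_identical(attr(empty, "n_labels"), 0L)
})

test_that("label dilation grows by Euclidean distance without merging", {
  d5 <- disk_mask(5, size = 21, center = c(11, 11))
  lab <- matrix(0L, 21, 21); lab[d5] <- 1L
  expect_identical(dilate_labels(lab, 0L), lab)

  grown <- dilate_labels(lab, 2L)
  # brute-force oracle: pixel in iff within distance 2 of some ROI pixel
  pts <- which(d5, arr.ind = TRUE)
  oracle <- matrix(FALSE, 21, 21)
  for (r in 1:21) for (c in 1:21)
    oracle[r, c] <- min((r - pts[, 1])^2 + (c - pts[, 2])^2) <= 4
  expect_identical(unname(grown > 0), unname(oracle))
  expect_identical(sum(grown > 0),
                   sum(disk_mask(7, size = 21, center = c(11, 11))))  # 149 px

  # two square labels 3 px apart, dilation 3: no merge, nearest-seed divide
  lab2 <- matrix(0L, 20, 20)
  lab2[8:12, 4:7] <- 1L; lab2[8:12, 11:14] <- 2L
  g2 <- dilate_labels(lab2, 3L)
  expect_identical(attr(g2, "n_labels"), 2L)
  p1 <- which(lab2 == 1L, arr.ind = TRUE); p2 <- which(lab2 == 2L, arr.ind = TRUE)
  for (idx in which(g2 > 0)) {
    r <- (idx - 1) %% 20 + 1; c <- (idx - 1) %/% 20 + 1
    d1 <- min((r - p1[, 1])^2 + (c - p1[, 2])^2)
    d2 <- min((r - p2[, 1])^2 + (c - p2[, 2])^2)
    want <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L  # tie -> lower id
    expect_identical(unname(g2[idx]), want)
  }
  # monotone: original pixels keep their labels
  expect_true(all(g2[lab2 > 0] == lab2[lab2 > 0]))
})

test_that("ROI extraction reports area, bbox, centroid and border contact", {
  expect_identical(nrow(extract_rois(matrix(0L, 6, 6))), 0L)

  lab <- matrix(0L, 8, 8)
  lab[3:5, 3:5] <- 1L
  roi <- extract_rois(lab)
  expect_identical(roi$area_px, 9L)
  expect_equal(c(roi$centroid_r, roi$centroid_c), c(3, 3))  # 0-based
  expect_identical(c(roi$bbox_r0, roi$bbox_c0, roi$bbox_r1, roi$bbox_c1),
                   c(2L, 2L, 5L, 5L))
  expect_false(roi$touches_border)

  lab[1, 6] <- 2L
  rois <- extract_rois(lab)
  expect_true(rois$touches_border[rois$area_px == 1L])
})

test_that("segmentation pipeline is deterministic and recovers simulated acini", {
  sim <- simulate_field(quick_sim(31))
  s1 <- segment_field(sim$pair$nuclear, quick_run_config())
  s2 <- segment_field(sim$pair$nuclear, quick_run_config())
  expect_identical(s1$label, s2$label)

  # one detected ROI per simulated acinus, each near its true center
  expect_identical(nrow(s1$rois), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    di <- sqrt((s1$rois$centroid_r - sim$truth$center_r[i])^2 +
               (s1$rois$centroid_c - sim$truth$center_c[i])^2)
    expect_lt(min(di), 5)
  }
})
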