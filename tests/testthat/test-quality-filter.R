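test_that("WAVR is zero for constant crops and tracks sharpness", {
  expect_warning(w0 <- wavr_focus(matrix(3, 20, 20)), "constant")
  expect_identical(w0, 0)

  set.seed(8)
  tex <- matrix(runif(64 * 64, 0, 255), 64, 64)  # aperiodic texture
  blur <- blur_series(tex, c(0, 2))
  expect_gt(wavr_focus(blur[[1]]), wavr_focus(blur[[2]]))
})

test_that("WAVR transform conserves energy and matches an independent DWT", {
  # orthonormal periodized db6: subband energies sum to the image energy,
  # and agree with an independently computed transform of the same image
  i <- matrix(rep(1:32, 32), 32, 32); j <- t(i)
  x <- sin(0.7 * i) + cos(1.3 * j) + 0.1 * sin(2.1 * i * j / 7)
  x <- x - min(x)
  w <- wavr_focus(x)
  expect_equal(w, 0.018299442845, tolerance = 1e-9)
  # value computed for the identically mirrored, normalized crop with
  # PyWavelets (db6, level 1, periodization); conventions differ in phase
  expect_lt(abs(w - 0.01898333391943834) / 0.01898333391943834, 0.05)
})

test_that("WAVR is invariant to intensity scaling", {
  sim <- simulate_field(quick_sim(3))
  crop <- sim$pair$nuclear[60:123, 60:123]
  expect_equal(wavr_focus(crop * 17), wavr_focus(crop), tolerance = 1e-12)
  expect_equal(wavr_focus(crop / 1000), wavr_focus(crop), tolerance = 1e-9)
})

test_that("WAVR strictly decreases along a defocus degradation series", {
  set.seed(41)
  for (rep in 1:5) {
    sim <- simulate_field(quick_sim(400 + rep))
    r <- sim$truth[1, ]
    crop <- sim$pair$nuclear[round(r$center_r) + (-20:20),
                             round(r$center_c) + (-20:20)]
    ws <- vapply(blur_series(crop, c(0, 0.5, 1, 2, 4)), wavr_focus, 1)
    expect_true(all(diff(ws) < 0))
  }
})

test_that("exclusion rules apply in order border, size, blur", {
  sim <- simulate_field(quick_sim(5))
  seg <- segment_field(sim$pair$nuclear, quick_run_config())
  rois <- seg$rois

  # force a border flag: rule must fire before any WAVR computation
  r2 <- rois; r2$touches_border[1] <- TRUE
  f <- apply_filters(r2, sim$pair$nuclear, 150, 20000, cutoff = 0)
  expect_identical(f$excluded_reason[1], "border")
  expect_true(is.na(f$wavr[1]))

  f2 <- apply_filters(rois, sim$pair$nuclear, min_area = 10000,
                      max_area = 20000, cutoff = 0)
  expect_true(all(f2$excluded_reason == "size"))
  expect_true(all(is.na(f2$wavr)))

  # cutoff straddling a computed value flips retention for that ROI only
  f3 <- apply_filters(rois, sim$pair$nuclear, 150, 20000, cutoff = 0)
  w <- sort(f3$wavr)
  mid <- (w[1] + w[2]) / 2
  f4 <- apply_filters(rois, sim$pair$nuclear, 150, 20000, cutoff = mid)
  expect_identical(sum(f4$excluded_reason == "blur"), 1L)
  expect_identical(f4$excluded_reason[which.min(f4$wavr)], "blur")

  # idempotent, and reasons partition the ROI set
  expect_identical(apply_filters(f4, sim$pair$nuclear, 150, 20000, mid), f4)
  expect_identical(sum(f4$excluded_reason %in%
                       c("none", "border", "size", "blur")), nrow(f4))
})

test_that("normal fit recovers parameters from binned draws", {
  set.seed(2)
  v <- rnorm(500, 0.9, 0.05)
  fit <- fit_normal(v)
  expect_lt(abs(fit$mean - 0.9), 0.02)
  expect_lt(abs(fit$sd - 0.05), 0.02)

  # exact Gaussian-shaped bin heights: parameters recovered, rss ~ 0
  mids <- seq(-1, 3, by = 0.1)
  counts <- 40 * exp(-(mids - 0.8)^2 / (2 * 0.3^2))
  f2 <- fit_normal(data.frame(mids = mids, counts = counts))
  expect_equal(f2$mean, 0.8, tolerance = 1e-6)
  expect_equal(f2$sd, 0.3, tolerance = 1e-6)
  expect_equal(f2$amplitude, 40, tolerance = 1e-5)
  expect_lt(f2$rss, 1e-10)

  expect_error(fit_normal(data.frame(mids = 1:3, counts = c(1, 2, 1))),
               "5 nonzero bins")
})

test_that("cutoff selection finds the equal-likelihood boundary", {
  nf <- function(m, s, a = 1) structure(list(mean = m, sd = s, amplitude = a),
                                        class = "normal_fit")
  expect_equal(choose_cutoff(nf(0.6, 0.1), nf(1.0, 0.1)), 0.8)

  # closed-form oracle for unequal sds, equal amplitude:
  # |x - m1| / s1 = |x - m2| / s2 between the means
  # => x = (s2 m1 + s1 m2) / (s1 + s2) = 0.1972 / 0.28
  cut <- choose_cutoff(nf(0.61, 0.08), nf(0.94, 0.20))
  expect_equal(cut, 0.1972 / 0.28, tolerance = 1e-12)

  expect_error(choose_cutoff(nf(0.8, 0.1), nf(0.8, 0.2)), "equal")
})
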