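# Daubechies-6 analysis filters (12 taps, orthonormal).
.db6_lo <- c(-0.0010773010853084796, 0.004777257510945511,
             0.0005538422011614961, -0.03158203931748603,
             0.027522865530305727, 0.09750160558732304,
             -0.12976686756726194, -0.22626469396543983,
             0.31525035170919763, 0.7511339080210954,
             0.49462389039845306, 0.11154074335010947)
.db6_hi <- c(-0.11154074335010947, 0.49462389039845306,
             -0.7511339080210954, 0.31525035170919763,
             0.22626469396543983, -0.12976686756726194,
             -0.09750160558732304, 0.027522865530305727,
             0.03158203931748603, 0.0005538422011614961,
             -0.004777257510945511, -0.0010773010853084796)

# Periodized filter-and-downsample along rows (first dimension). Returns a
# (nrow/2) x ncol matrix. nrow must be even.
.conv_ds_rows <- function(x, f) {
  n <- nrow(x)
  out <- matrix(0, n %/% 2L, ncol(x))
  base <- 2L * seq_len(n %/% 2L) - 1L
  for (t in seq_along(f)) {
    idx <- (base + t - 2L) %% n + 1L
    out <- out + f[t] * x[idx, , drop = FALSE]
  }
  out
}

# Single-level 2-D discrete wavelet transform, db6 basis, periodic
# extension (orthonormal, so subband coefficient energies equal the
# energies of the reconstructed subband images).
dwt2_db6 <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x)])
  lo_r <- .conv_ds_rows(x, .db6_lo)
  hi_r <- .conv_ds_rows(x, .db6_hi)
  list(LL = t(.conv_ds_rows(t(lo_r), .db6_lo)),
       LH = t(.conv_ds_rows(t(lo_r), .db6_hi)),
       HL = t(.conv_ds_rows(t(hi_r), .db6_lo)),
       HH = t(.conv_ds_rows(t(hi_r), .db6_hi)))
}

#' WAVR wavelet focus measure
#'
#' Measures the sharpness of an image crop as the ratio of detail to
#' approximation energy in a single-level 2-D Daubechies-6 wavelet
#' transform of the intensity-normalized crop:
#' \deqn{WAVR = (\sum H^2 + \sum V^2 + \sum D^2) / \sum A^2}
#' Defocused (blurred) crops lose high-frequency detail and score low;
#' higher means sharper. The crop is min-max normalized first, so the value
#' is invariant to intensity scaling. Crops smaller than 16x16 are padded
#' by edge replication.
#'
#' @param image_crop Numeric matrix (un-masked bounding-box crop of the
#'   nuclear channel).
#' @return Non-negative scalar; 0 (with a warning) for a constant crop.
#' @export
wavr_focus <- function(image_crop) {
  assert_raster(image_crop)
  x <- image_crop
  if (nrow(x) < 16L) x <- x[pmin.int(pmax.int(seq_len(16L) - (16L - nrow(x)) %/% 2L, 1L), nrow(x)), , drop = FALSE]
  if (ncol(x) < 16L) x <- x[, pmin.int(pmax.int(seq_len(16L) - (16L - ncol(x)) %/% 2L, 1L), ncol(x)), drop = FALSE]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant crop: no detail energy, WAVR = 0")
    return(0)
  }
  x <- (x - rng[1]) / (rng[2] - rng[1])
  # mirror the crop before the periodized transform: symmetric extension
  # avoids spurious detail energy from the wrap-around discontinuity
  x <- rbind(x, x[nrow(x):1, , drop = FALSE])
  x <- cbind(x, x[, ncol(x):1, drop = FALSE])
  w <- dwt2_db6(x)
  ea <- sum(w$LL^2)
  (sum(w$LH^2) + sum(w$HL^2) + sum(w$HH^2)) / ea
}

#' Apply border, size and focus exclusion rules
#'
#' Exclusions are applied in order border, size, blur; the first failing
#' rule is recorded in `excluded_reason`. The WAVR focus measure is
#' computed (on the un-masked nuclear-channel bounding-box crop, expanded
#' to at least 16x16 inside the image) only for ROIs that survive the
#' border and size rules; an ROI is excluded as blurred when its WAVR falls
#' below the cutoff.
#'
#' @param rois ROI data frame from [extract_rois()].
#' @param nuclear Nuclear-stain matrix the ROIs were segmented from.
#' @param min_area,max_area Retained area range in pixels.
#' @param cutoff WAVR cutoff; ROIs with `wavr < cutoff` are excluded.
#' @return The ROI data frame with `wavr` and `excluded_reason` filled in.
#' @export
apply_filters <- function(rois, nuclear, min_area, max_area, cutoff) {
  stopifnot(min_area <= max_area, cutoff >= 0)
  for (i in seq_len(nrow(rois))) {
    if (rois$touches_border[i]) {
      rois$excluded_reason[i] <- "border"
    } else if (rois$area_px[i] < min_area || rois$area_px[i] > max_area) {
      rois$excluded_reason[i] <- "size"
    } else {
      crop <- crop_bbox(nuclear, rois[i, ], min_side = 16L)
      rois$wavr[i] <- suppressWarnings(wavr_focus(crop))
      if (rois$wavr[i] < cutoff) rois$excluded_reason[i] <- "blur"
      else rois$excluded_reason[i] <- "none"
    }
  }
  rois
}

# Bounding-box crop, symmetrically expanded to min_side inside the image.
crop_bbox <- function(image, roi, min_side = 0L, margin = 0L) {
  r0 <- roi$bbox_r0 + 1L - margin; r1 <- roi$bbox_r1 + margin
  c0 <- roi$bbox_c0 + 1L - margin; c1 <- roi$bbox_c1 + margin
  while (r1 - r0 + 1L < min_side) { r0 <- r0 - 1L; r1 <- r1 + 1L }
  while (c1 - c0 + 1L < min_side) { c0 <- c0 - 1L; c1 <- c1 + 1L }
  image[max(1L, r0):min(nrow(image), r1),
        max(1L, c0):min(ncol(image), c1), drop = FALSE]
}

#' Histogram of focus-measure values
#'
#' Bins WAVR values with Freedman-Diaconis breaks for input to
#' [fit_normal()].
#'
#' @param values Numeric vector of WAVR values.
#' @param breaks Passed to [graphics::hist()]; defaults to
#'   Freedman-Diaconis with a floor of 10 bins.
#' @return Data frame with columns `mids` and `counts`.
#' @export
wavr_histogram <- function(values, breaks = NULL) {
  breaks <- breaks %||% max(grDevices::nclass.FD(values), 10L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(mids = h$mids, counts = h$counts)
}

#' Levenberg-Marquardt normal fit to binned values
#'
#' Fits `amplitude * exp(-(x - mean)^2 / (2 sd^2))` to histogram bin heights
#' by Levenberg-Marquardt nonlinear least squares, initialized from the
#' count-weighted sample mean and standard deviation.
#'
#' @param histogram Data frame with columns `mids` and `counts` (e.g. from
#'   [wavr_histogram()]), a `hist` object, or a raw numeric vector of
#'   values (binned internally). At least 5 nonzero bins are required.
#' @return Object of class `normal_fit`: list with `mean`, `sd`,
#'   `amplitude`, `rss` and the underlying `fit`.
#' @export
fit_normal <- function(histogram) {
  if (is.numeric(histogram) && is.null(dim(histogram)))
    histogram <- wavr_histogram(histogram)
  if (inherits(histogram, "histogram"))
    histogram <- data.frame(mids = histogram$mids, counts = histogram$counts)
  stopifnot(all(c("mids", "counts") %in% names(histogram)))
  if (sum(histogram$counts > 0) < 5L)
    stop("need at least 5 nonzero bins to fit a normal")
  x <- histogram$mids; y <- histogram$counts
  m0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum(y * (x - m0)^2) / sum(y))
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - m)^2 / (2 * s^2)),
    start = list(A = max(y), m = m0, s = max(s0, 1e-6)),
    lower = c(A = 1e-12, m = -Inf, s = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(mean = unname(co["m"]), sd = unname(co["s"]),
                 amplitude = unname(co["A"]),
                 rss = sum(stats::resid(fit)^2), fit = fit),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("<normal_fit> mean %.4g  sd %.4g  amplitude %.4g  rss %.3g\n",
              x$mean, x$sd, x$amplitude, x$rss))
  invisible(x)
}

#' Data-driven focus cutoff from per-class normal fits
#'
#' Given normal fits to the WAVR histograms of a blurry and a sharp class,
#' returns the equal-likelihood boundary: the intersection of the two
#' fitted curves lying between the class means. When no intersection falls
#' between the means, the midpoint of the means is returned.
#'
#' @param fit_blurry,fit_sharp `normal_fit` objects with
#'   `fit_blurry$mean < fit_sharp$mean`.
#' @return The cutoff (scalar).
#' @export
choose_cutoff <- function(fit_blurry, fit_sharp) {
  m1 <- fit_blurry$mean; s1 <- fit_blurry$sd; a1 <- fit_blurry$amplitude
  m2 <- fit_sharp$mean;  s2 <- fit_sharp$sd;  a2 <- fit_sharp$amplitude
  if (m1 == m2) stop("class means are equal: classes inseparable")
  if (m1 > m2) stop("fit_blurry must have the smaller mean")
  # a1 exp(-(x-m1)^2/2s1^2) = a2 exp(-(x-m2)^2/2s2^2)  =>  quadratic in x
  A <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  B <- -m1 / s1^2 + m2 / s2^2
  C <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - log(a1 / a2)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric() else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric()
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) > 0L) inside[1] else (m1 + m2) / 2
}
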