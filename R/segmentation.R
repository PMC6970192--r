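#' 3x3 mean smoothing
#'
#' Replaces each pixel by the mean of its 3x3 neighborhood; the one-pixel
#' border uses edge-reflected padding. Applied to the nuclear stain before
#' thresholding to suppress shot noise.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_mean3x3 <- function(image) {
  assert_raster(image)
  n <- nrow(image); m <- ncol(image)
  if (n < 3L || m < 3L) stop("image must be at least 3x3")
  p <- image[c(1L, 1:n, n), c(1L, 1:m, m)]  # reflect one pixel at each edge
  acc <- matrix(0, n, m)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + 1:n, dc + 1:m]
  acc / 9
}

#' Global Otsu binarization
#'
#' Thresholds an image at the cut of a 256-bin intensity histogram that
#' maximizes the between-class variance; the mask is `TRUE` strictly above
#' the threshold. A constant image yields an all-`FALSE` mask with a
#' warning.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return Logical matrix of the same dimensions, with attribute
#'   `threshold`.
#' @export
otsu_binarize <- function(image) {
  assert_raster(image)
  lo <- min(image); hi <- max(image)
  if (lo == hi) {
    warning("constant image: degenerate histogram, empty mask returned")
    return(structure(matrix(FALSE, nrow(image), ncol(image)), threshold = lo))
  }
  nb <- 256L
  w <- (hi - lo) / nb
  ix <- pmin.int(pmax.int(ceiling((image - lo) / w), 1L), nb)
  h <- as.numeric(tabulate(ix, nb))
  mids <- lo + (seq_len(nb) - 0.5) * w
  cw <- cumsum(h)
  cs <- cumsum(h * mids)
  tot_w <- cw[nb]; tot_s <- cs[nb]
  t <- seq_len(nb - 1L)
  w0 <- cw[t]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (w0 * w1 * (cs[t] / w0 - (tot_s - cs[t]) / w1)^2)[valid]
  tstar <- which.max(bcv)
  thr <- lo + tstar * w
  structure(matrix(ix > tstar, nrow(image), ncol(image)), threshold = thr)
}

#' Smooth the borders of a binary mask
#'
#' Morphological opening followed by closing with a disk structuring
#' element; removes pixel-scale spurs and notches that would otherwise seed
#' spurious watershed fragments. Radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels (integer, >= 0).
#' @return Logical matrix.
#' @export
smooth_mask_borders <- function(mask, radius = 2L) {
  stopifnot(is.matrix(mask), radius >= 0)
  if (radius == 0L) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  x <- EBImage::closing(EBImage::opening(mask * 1, k), k)
  matrix(as.numeric(x) > 0.5, nrow(mask), ncol(mask))
}

#' Split touching acini by distance-transform watershed
#'
#' Computes the Euclidean distance of each mask pixel to the background and
#' applies a watershed to the (negated) distance map. Shallow local maxima
#' within `min_seed_depth` of a neighboring catchment are suppressed, so a
#' single round blob is not fragmented. Pixels on the divide lines between
#' basins are set to background, and the surviving 8-connected components
#' are relabeled 1..n in raster-scan order of their first pixel.
#'
#' @param mask Logical matrix.
#' @param min_seed_depth Minimum height (in distance-map units, i.e. pixels)
#'   separating two seeds for them to found distinct labels.
#' @return Integer label matrix (0 = background) with attribute `n_labels`.
#' @export
watershed_split <- function(mask, min_seed_depth = 2) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(structure(matrix(0L, nrow(mask), ncol(mask)), n_labels = 0L))
  d <- EBImage::distmap(mask * 1)
  w <- matrix(as.integer(EBImage::watershed(d, tolerance = min_seed_depth, ext = 1L)),
              nrow(mask), ncol(mask))
  carved <- carve_divides(w)
  relabel8(carved > 0L)
}

# Zero every pixel that is 8-adjacent to a different, smaller positive
# label; afterwards no two distinct labels touch (a one-pixel divide line).
carve_divides <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  kill <- matrix(FALSE, n, m)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    nb <- shift_mat(lab, s[1], s[2])
    kill <- kill | (lab > 0L & nb > 0L & nb < lab)
  }
  lab[kill] <- 0L
  lab
}

# Shift a matrix by (dr, dc), padding with zeros.
shift_mat <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0L, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr); rd <- rs - dr
  cs <- max(1, 1 + dc):min(m, m + dc); cd <- cs - dc
  out[rs, cs] <- x[rd, cd]
  out
}

# 8-connected labeling: 4-connected components from EBImage::bwlabel, then
# union-find merging of diagonally adjacent labels; final ids follow
# raster-scan (row-major) order of each component's first pixel.
relabel8 <- function(mask) {
  lab4 <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  k <- max(lab4)
  if (k > 0L) {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (s in list(c(1, 1), c(1, -1))) {
      a <- lab4; b <- shift_mat(lab4, s[1], s[2])
      sel <- a > 0L & b > 0L & a != b
      u <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(u))) {
        ra <- find(u[i, 1]); rb <- find(u[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_len(k), find, 1L)
    lab4[lab4 > 0L] <- root[lab4[lab4 > 0L]]
  }
  renumber_raster_scan(lab4)
}

# Renumber positive labels 1..n by row-major order of first occurrence.
renumber_raster_scan <- function(lab) {
  pos <- which(t(lab) > 0L)              # t() => row-major scan order
  vals <- t(lab)[pos]
  first <- vals[!duplicated(vals)]
  map <- integer(max(c(0L, vals)))
  map[first] <- seq_along(first)
  out <- lab
  out[out > 0L] <- map[out[out > 0L]]
  structure(out, n_labels = length(first))
}

#' Dilate labeled ROIs into the background
#'
#' Grows every label by a Euclidean disk of the given radius, into
#' background pixels only: a contested pixel is assigned to the label whose
#' original ROI is nearest, with ties going to the lower label id. Labels
#' never merge and original pixels keep their label. The dilation accounts
#' for the true membrane edge of an acinus lying outside the ROI found from
#' the nuclear stain.
#'
#' @param labeled Integer label matrix.
#' @param radius Dilation radius in pixels (>= 0).
#' @return Integer label matrix with the same number of labels.
#' @export
dilate_labels <- function(labeled, radius = 3L) {
  stopifnot(is.matrix(labeled), radius >= 0)
  k <- max(labeled)
  if (radius == 0L || k == 0L) return(labeled)
  best <- matrix(Inf, nrow(labeled), ncol(labeled))
  arg <- matrix(0L, nrow(labeled), ncol(labeled))
  for (id in seq_len(k)) {
    dk <- EBImage::distmap((labeled != id) * 1)  # distance to label id
    upd <- dk < best                             # strict: ties keep lower id
    best[upd] <- dk[upd]
    arg[upd] <- id
  }
  grow <- labeled == 0L & best <= radius
  out <- labeled
  out[grow] <- arg[grow]
  structure(out, n_labels = k)
}

#' Extract per-ROI measurements from a label matrix
#'
#' @param labeled Integer label matrix (labels 1..n).
#' @return Data frame with one row per label: `acinus_id`, `area_px`,
#'   0-based half-open bounding box (`bbox_r0`, `bbox_c0`, `bbox_r1`,
#'   `bbox_c1`), 0-based centroid (`centroid_r`, `centroid_c`),
#'   `touches_border`, and placeholders `wavr` (NA) and `excluded_reason`
#'   ("none"). Ids follow raster-scan order of each label's first pixel.
#' @export
extract_rois <- function(labeled) {
  k <- max(labeled)
  empty <- data.frame(acinus_id = integer(), area_px = integer(),
                      bbox_r0 = integer(), bbox_c0 = integer(),
                      bbox_r1 = integer(), bbox_c1 = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      touches_border = logical(), wavr = numeric(),
                      excluded_reason = character())
  if (k == 0L) return(empty)
  idx <- which(labeled > 0L)
  rr <- (idx - 1L) %% nrow(labeled) + 1L
  cc <- (idx - 1L) %/% nrow(labeled) + 1L
  lv <- labeled[idx]
  f <- factor(lv, levels = seq_len(k))
  data.frame(
    acinus_id = seq_len(k),
    area_px = as.integer(tabulate(lv, k)),
    bbox_r0 = as.integer(tapply(rr, f, min)) - 1L,
    bbox_c0 = as.integer(tapply(cc, f, min)) - 1L,
    bbox_r1 = as.integer(tapply(rr, f, max)),
    bbox_c1 = as.integer(tapply(cc, f, max)),
    centroid_r = as.numeric(tapply(rr, f, mean)) - 1,
    centroid_c = as.numeric(tapply(cc, f, mean)) - 1,
    touches_border = as.logical(tapply(rr == 1L | rr == nrow(labeled) |
                                       cc == 1L | cc == ncol(labeled), f, any)),
    wavr = NA_real_,
    excluded_reason = "none")
}

#' Segment one field from its nuclear channel
#'
#' Convenience wrapper running the full segmentation chain: 3x3 mean
#' smoothing, Otsu binarization, border smoothing, distance-transform
#' watershed, and ROI dilation.
#'
#' @param nuclear Nuclear-stain matrix.
#' @param config Run configuration, see [default_run_config()].
#' @return List with `label` (integer matrix) and `rois` (data frame from
#'   [extract_rois()]).
#' @export
segment_field <- function(nuclear, config = default_run_config()) {
  sm <- smooth_mean3x3(nuclear)
  mask <- suppressWarnings(otsu_binarize(sm))
  mask <- smooth_mask_borders(mask, config$border_smooth_radius)
  lab <- watershed_split(mask, config$seed_suppression_depth)
  lab <- dilate_labels(lab, config$dilation_radius)
  list(label = lab, rois = extract_rois(lab))
}
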