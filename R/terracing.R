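#' Concentric equal-height terraces of an ROI
#'
#' Treats the ROI as a mountain whose height at each pixel is the Euclidean
#' distance to the nearest non-ROI pixel (boundary pixels adjacent to
#' background have height 1), and slices it into `n` contour terraces of
#' equal height range. The height bin is `k = ceiling(n * d / d_max)`
#' clamped to 1..n, and the terrace index is `i = n - k + 1`, so terrace 1
#' is the innermost (center, radial position 0) and terrace `n` the
#' outermost (periphery, radial position 1). ROIs that are one pixel thin
#' (`d_max <= 1`) or that leave any terrace empty are flagged degenerate.
#'
#' @param mask Logical matrix, `TRUE` on the ROI pixels (full image or a
#'   crop; the image border is treated as background).
#' @param n Number of terraces (>= 2).
#' @param acinus_id Optional id carried through to results.
#' @return Object of class `terrace_map`: list with `acinus_id`, `n`,
#'   `terrace` (integer matrix, same shape as `mask`, 0 outside the ROI),
#'   `pixel_counts` (length `n`), `d_max`, and `degenerate` (logical).
#' @export
terrace_map <- function(mask, n, acinus_id = NA_integer_) {
  stopifnot(is.matrix(mask), n >= 2, sum(mask) >= n)
  # pad one background pixel so the image edge counts as background
  pm <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  d <- matrix(as.numeric(EBImage::distmap(pm * 1)),
              nrow(pm), ncol(pm))[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  d_max <- max(d)
  terr <- matrix(0L, nrow(mask), ncol(mask))
  degenerate <- d_max <= 1
  if (!degenerate) {
    k <- as.integer(pmin.int(pmax.int(ceiling(n * d[mask] / d_max), 1L), n))
    terr[mask] <- as.integer(n) - k + 1L
  }
  counts <- tabulate(terr[terr > 0L], n)
  if (any(counts == 0L)) degenerate <- TRUE
  structure(list(acinus_id = acinus_id, n = as.integer(n), terrace = terr,
                 pixel_counts = counts, d_max = d_max,
                 degenerate = degenerate),
            class = "terrace_map")
}

#' @export
print.terrace_map <- function(x, ...) {
  cat(sprintf("<terrace_map> acinus %s, %d terraces, d_max %.2f px%s\n",
              x$acinus_id, x$n, x$d_max,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Normalized radial position of each terrace
#'
#' The acinus center has radial value 0 and the periphery 1; terrace `i`
#' sits at the center of its band, `r_i = (i - 0.5) / n`.
#'
#' @param tmap A `terrace_map`, or an integer terrace count.
#' @return Numeric vector of length `n`, strictly increasing in (0, 1).
#' @export
radial_positions <- function(tmap) {
  n <- if (inherits(tmap, "terrace_map")) tmap$n else as.integer(tmap)
  (seq_len(n) - 0.5) / n
}
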