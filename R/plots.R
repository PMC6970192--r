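#' Plot a WAVR histogram with per-class normal fits
#'
#' Mirrors the classic focus-QC figure: probability-density histograms of
#' WAVR for blurry and sharp acini, the fitted normal curves, and the
#' chosen cutoff.
#'
#' @param blurry,sharp Numeric vectors of WAVR values.
#' @param fit_blurry,fit_sharp Optional `normal_fit` objects (fitted from
#'   the data when omitted).
#' @param cutoff Optional cutoff to mark (vertical line).
#' @return Invisibly, the two fits.
#' @export
plot_wavr_fits <- function(blurry, sharp, fit_blurry = NULL, fit_sharp = NULL,
                           cutoff = NULL) {
  fit_blurry <- fit_blurry %||% fit_normal(blurry)
  fit_sharp <- fit_sharp %||% fit_normal(sharp)
  xs <- seq(min(c(blurry, sharp)), max(c(blurry, sharp)), length.out = 300)
  hb <- graphics::hist(blurry, breaks = "FD", plot = FALSE)
  hs <- graphics::hist(sharp, breaks = "FD", plot = FALSE)
  ylim <- c(0, max(hb$counts, hs$counts) * 1.1)
  graphics::plot(hb$mids, hb$counts, type = "h", col = "red", lwd = 4,
                 xlim = range(xs), ylim = ylim, xlab = "WAVR",
                 ylab = "count", main = "Focus measure by visual class")
  graphics::points(hs$mids, hs$counts, type = "h", col = "blue", lwd = 4)
  gauss <- function(f, x) f$amplitude * exp(-(x - f$mean)^2 / (2 * f$sd^2))
  graphics::lines(xs, gauss(fit_blurry, xs), col = "red")
  graphics::lines(xs, gauss(fit_sharp, xs), col = "blue")
  if (!is.null(cutoff)) graphics::abline(v = cutoff, lty = 2)
  graphics::legend("topright", c("blurry", "sharp"), col = c("red", "blue"),
                   lwd = 2, bty = "n")
  invisible(list(fit_blurry = fit_blurry, fit_sharp = fit_sharp))
}

#' Plot group-mean radial profiles
#'
#' One curve per group: mean normalized intensity RP_i against normalized
#' radius (0 = acinus center, 1 = periphery), with the uniform line RP = 1.
#'
#' @param summary Output of [summarize_groups()] (uses its `profiles`
#'   attribute).
#' @return Invisibly, the profile matrix.
#' @export
plot_group_profiles <- function(summary) {
  prof <- attr(summary, "profiles")
  stopifnot(!is.null(prof))
  r <- radial_positions(ncol(prof))
  cols <- grDevices::hcl.colors(nrow(prof), "Dark 3")
  graphics::matplot(r, t(prof), type = "b", pch = 16, lty = 1, col = cols,
                    xlab = "normalized radius", ylab = "normalized intensity",
                    main = "Group-mean radial profiles")
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", rownames(prof), col = cols, lwd = 2, bty = "n")
  invisible(prof)
}
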