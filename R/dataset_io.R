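#' Discover a condition-organized image dataset
#'
#' Scans `root_dir` for one sub-folder per condition, each containing paired
#' grayscale images whose filenames end in the configured channel suffixes
#' (before the extension). Each pair forms one field of view.
#'
#' @param root_dir Dataset root; its immediate sub-directories are the
#'   conditions.
#' @param suffixes Named character vector with elements `nuclear` and
#'   `polarity` giving the filename suffixes identifying the two channels.
#' @return A list of [field_pair()] objects of class `acini_dataset`, sorted
#'   by condition then field id (deterministic across runs).
#' @export
discover_dataset <- function(root_dir,
                             suffixes = c(nuclear = "_dapi", polarity = "_pol")) {
  stopifnot(all(c("nuclear", "polarity") %in% names(suffixes)))
  if (!dir.exists(root_dir)) stop("dataset root not found: ", root_dir)
  conds <- sort(basename(list.dirs(root_dir, recursive = FALSE)))
  if (length(conds) == 0L) stop("no condition sub-folders under ", root_dir)
  pairs <- list()
  for (cond in conds) {
    files <- sort(list.files(file.path(root_dir, cond),
                             pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE))
    stem <- tools::file_path_sans_ext(files)
    is_nuc <- endsWith(stem, suffixes[["nuclear"]])
    is_pol <- endsWith(stem, suffixes[["polarity"]])
    nuc_id <- sub(paste0(suffixes[["nuclear"]], "$"), "", stem[is_nuc])
    pol_id <- sub(paste0(suffixes[["polarity"]], "$"), "", stem[is_pol])
    orphans <- c(files[is_nuc][!(nuc_id %in% pol_id)],
                 files[is_pol][!(pol_id %in% nuc_id)],
                 files[!is_nuc & !is_pol])
    if (length(orphans) > 0L)
      stop("unpaired or unrecognized files in ", cond, ": ",
           paste(orphans, collapse = ", "))
    for (id in sort(nuc_id)) {
      nf <- file.path(root_dir, cond, files[is_nuc][nuc_id == id])
      pf <- file.path(root_dir, cond, files[is_pol][pol_id == id])
      pairs[[length(pairs) + 1L]] <-
        field_pair(cond, id, read_raster(nf), read_raster(pf))
    }
  }
  structure(pairs, class = "acini_dataset")
}

#' @export
print.acini_dataset <- function(x, ...) {
  conds <- vapply(x, `[[`, "", "condition")
  cat(sprintf("<acini_dataset> %d fields, %d conditions (%s)\n", length(x),
              length(unique(conds)), paste(unique(conds), collapse = ", ")))
  invisible(x)
}

# --- minimal 3x5 bitmap glyphs used to stamp RP indexes onto overlays ------
.glyphs <- local({
  def <- c(
    "0" = "111 101 101 101 111", "1" = "010 110 010 010 111",
    "2" = "111 001 111 100 111", "3" = "111 001 111 001 111",
    "4" = "101 101 111 001 001", "5" = "111 100 111 001 111",
    "6" = "111 100 111 101 111", "7" = "111 001 010 010 010",
    "8" = "111 101 111 101 111", "9" = "111 101 111 001 111",
    "." = "000 000 000 000 010", "-" = "000 000 111 000 000",
    "+" = "000 010 111 010 000")
  lapply(def, function(s) {
    rows <- strsplit(s, " ")[[1]]
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  })
})

# Stamp `text` onto the 3-channel array `rgb` with glyph top-left at
# (row, col), integer scale factor, color = length-3 vector in [0,1].
stamp_text <- function(rgb, text, row, col, scale = 2L, color = c(1, 1, 0)) {
  chars <- strsplit(text, "")[[1]]
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  for (ch in chars) {
    g <- .glyphs[[ch]]
    if (!is.null(g)) {
      g <- g[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
      on <- which(g == 1L, arr.ind = TRUE)
      rr <- row + on[, 1] - 1L; cc <- col + on[, 2] - 1L
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      for (k in 1:3) rgb[cbind(rr[ok], cc[ok], k)] <- color[k]
    }
    col <- col + 4L * scale
  }
  rgb
}

#' Write a polarity image annotated with acinus contours and RP indexes
#'
#' Renders the polarity channel in grayscale, draws the outline of every
#' detected ROI (green for retained acini, red for excluded ones) and stamps
#' the signed RP index next to each retained acinus. A field with no acini
#' yields an un-annotated grayscale render of the polarity image.
#'
#' @param pair A [field_pair()].
#' @param seg Segmentation for the field, as returned by [segment_field()]
#'   (a list with elements `label` and `rois`).
#' @param results Data frame of per-acinus results for the field (rows of
#'   the results table; may be empty).
#' @param out_path PNG output path, or `NULL` to skip writing.
#' @return The H x W x 3 RGB array, invisibly.
#' @export
write_annotated_overlay <- function(pair, seg, results, out_path) {
  img <- pair$polarity
  mx <- max(img)
  g <- if (mx > 0) img / mx else img
  rgb <- array(g, dim = c(dim(img), 3L))
  lab <- seg$label
  if (!is.null(lab) && max(lab) > 0L) {
    edge <- label_edges(lab)
    retained <- seg$rois$acinus_id[seg$rois$excluded_reason == "none"]
    for (k in seq_len(max(lab))) {
      colr <- if (k %in% retained) c(0, 1, 0) else c(1, 0.15, 0.15)
      on <- which(edge & lab == k, arr.ind = TRUE)
      for (ch in 1:3) rgb[cbind(on, ch)] <- colr[ch]
    }
    if (nrow(results) > 0L) {
      res <- results[results$excluded_reason == "none", , drop = FALSE]
      for (i in seq_len(nrow(res))) {
        id <- res$acinus_id[i]
        roi <- seg$rois[seg$rois$acinus_id == id, ]
        txt <- sprintf("%+.2f", res$rp_index[i])
        rgb <- stamp_text(rgb, txt, row = round(roi$centroid_r) + 1L,
                          col = round(roi$centroid_c) + 2L)
      }
    }
  }
  if (!is.null(out_path)) png::writePNG(rgb, out_path)
  invisible(rgb)
}

# TRUE at label pixels having a 4-neighbor with a different value (object
# outlines, one pixel wide, inside the object).
label_edges <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  e <- matrix(FALSE, n, m)
  e[-1, ] <- e[-1, ] | (lab[-1, ] != lab[-n, ])
  e[-n, ] <- e[-n, ] | (lab[-n, ] != lab[-1, ])
  e[, -1] <- e[, -1] | (lab[, -1] != lab[, -m])
  e[, -m] <- e[, -m] | (lab[, -m] != lab[, -1])
  e[1, ] <- e[1, ] | lab[1, ] > 0; e[n, ] <- e[n, ] | lab[n, ] > 0
  e[, 1] <- e[, 1] | lab[, 1] > 0; e[, m] <- e[, m] | lab[, m] > 0
  e & lab > 0
}

#' Export acinus crops and a randomized blind-scoring manifest
#'
#' Replaces interactive supervised scoring: every retained acinus is cropped
#' from its nuclear and polarity images and written under a randomized
#' numeric name, in an order given by a seeded permutation. The manifest
#' lists only crop ids and file names — condition labels are withheld so an
#' external scorer is blind to treatment — while a separate key file maps
#' crop ids back to (condition, field_id, acinus_id).
#'
#' @param analysis An `acini_analysis` object from [analyze_dataset()].
#' @param seed Integer seed for the presentation order.
#' @param out_dir Output directory (created if needed).
#' @param margin Extra pixels around each ROI bounding box.
#' @return Invisibly, a list with paths `manifest` and `key`.
#' @export
write_blind_manifest <- function(analysis, seed, out_dir, margin = 8L) {
  tab <- analysis$table
  keep <- tab[tab$excluded_reason == "none", , drop = FALSE]
  if (nrow(keep) == 0L) stop("no retained acini to export")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- with_seed(seed, sample.int(nrow(keep)))
  keep <- keep[ord, , drop = FALSE]
  crop_id <- sprintf("acinus_%03d", seq_len(nrow(keep)))
  nuc_file <- paste0(crop_id, "_nuclear.png")
  pol_file <- paste0(crop_id, "_marker.png")
  for (i in seq_len(nrow(keep))) {
    fld <- analysis$fields[[paste(keep$condition[i], keep$field_id[i], sep = "/")]]
    roi <- fld$seg$rois[fld$seg$rois$acinus_id == keep$acinus_id[i], ]
    dm <- dim(fld$pair$nuclear)
    r <- max(1L, roi$bbox_r0 + 1L - margin):min(dm[1], roi$bbox_r1 + margin)
    cc <- max(1L, roi$bbox_c0 + 1L - margin):min(dm[2], roi$bbox_c1 + margin)
    for (ch in c("nuclear", "polarity")) {
      crop <- fld$pair[[ch]][r, cc, drop = FALSE]
      if (max(crop) > 0) crop <- crop / max(crop) * 255
      f <- if (ch == "nuclear") nuc_file[i] else pol_file[i]
      write_raster(crop, file.path(out_dir, f), bit_depth = 8L)
    }
  }
  manifest <- data.frame(crop_id = crop_id, nuclear_file = nuc_file,
                         polarity_file = pol_file)
  key <- data.frame(crop_id = crop_id, condition = keep$condition,
                    field_id = keep$field_id, acinus_id = keep$acinus_id)
  mp <- file.path(out_dir, "manifest.csv"); kp <- file.path(out_dir, "key.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  utils::write.csv(key, kp, row.names = FALSE)
  invisible(list(manifest = mp, key = kp))
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
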