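#' Configuration for the synthetic acinus field simulator
#'
#' Defines the study conditions a simulated field emulates: round acini
#' whose nuclear channel is a ring of bright nuclei over a dim intra-acinar
#' haze (the out-of-focus light that fills the acinus interior in widefield
#' images), and whose polarity-marker channel follows a monotone radial
#' law — `I(rho) = 1 + a (1 - rho)` for apical, `1 + a rho` for basal and
#' flat for nonpolar acini, with `rho` the normalized radius. Intensities
#' are on a [0, 1] dynamic-range scale until written to 16-bit files.
#'
#' @param image_size Field height and width in pixels.
#' @param n_acini Acini per field.
#' @param radius_range Min and max acinus radius (px, >= 5).
#' @param phenotype_mix Proportions for apical, basal, nonpolar (sum 1).
#' @param gradient_strength Radial-law slope parameter `a` (>= 0).
#' @param nuclei_per_acinus,nucleus_radius Ring of Gaussian nuclei: count
#'   and blob sigma (px).
#' @param noise_sd Additive Gaussian noise sd, fraction of dynamic range.
#' @param defocus_fraction Fraction of acini rendered defocused.
#' @param defocus_sigma Gaussian defocus sigma (px).
#' @param seed Integer seed; the field is deterministic given the config.
#' @param background Background level (fraction of dynamic range).
#' @param nuclear_amp,haze_amp,polarity_amp Channel amplitudes.
#' @param min_gap Minimum clearance between acinus rims (px).
#' @param n_border_touching Acini deliberately placed across the image
#'   border (exercises the border filter).
#' @param texture_sd Relative sd of the fine-grained chromatin texture
#'   multiplying the nuclei (0 disables it).
#' @param lumen_frac For `lumen_mode = "annular"`, the normalized radius of
#'   the apical peak; the default `"small"` mode peaks at the center.
#' @param lumen_mode `"small"` (apical marker peaks at the center, small
#'   lumen) or `"annular"` (peak on a ring, large lumen).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(image_size = c(512L, 512L), n_acini = 8L,
                              radius_range = c(15, 25),
                              phenotype_mix = c(apical = 1/3, basal = 1/3,
                                                nonpolar = 1/3),
                              gradient_strength = 1,
                              nuclei_per_acinus = 10L, nucleus_radius = 3,
                              noise_sd = 0.02, defocus_fraction = 0,
                              defocus_sigma = 3, seed = 1L,
                              background = 0.05, nuclear_amp = 0.6,
                              haze_amp = 0.35, polarity_amp = 0.6,
                              min_gap = 4, n_border_touching = 0L,
                              texture_sd = 0.25,
                              lumen_frac = 0.5, lumen_mode = "small") {
  stopifnot(length(image_size) == 2L, image_size >= 64,
            radius_range[1] >= 5, radius_range[1] <= radius_range[2],
            abs(sum(phenotype_mix) - 1) < 1e-8, gradient_strength >= 0,
            noise_sd >= 0, defocus_fraction >= 0, defocus_fraction <= 1,
            lumen_mode %in% c("small", "annular"))
  cfg <- as.list(environment())
  names(cfg$phenotype_mix) <- c("apical", "basal", "nonpolar")
  structure(cfg, class = "simulation_config")
}

# Radial intensity law on [0,1], peak-normalized to 1.
.polarity_law <- function(rho, phenotype, a, lumen_mode, lumen_frac) {
  base <- switch(phenotype,
    apical = if (lumen_mode == "small") 1 + a * (1 - rho)
             else 1 + a * pmax(0, 1 - abs(rho - lumen_frac) / (1 - lumen_frac)),
    basal = 1 + a * rho,
    nonpolar = rep(1, length(rho)))
  base / (if (phenotype == "nonpolar") 1 else 1 + a)
}

#' Simulate one field of synthetic acini with ground truth
#'
#' Places non-overlapping acini by bounded rejection sampling and renders
#' the nuclear and polarity channels per the configured laws; defocused
#' acini are Gaussian-blurred in both channels before field-wide additive
#' noise. Output is valid pipeline input with no special-casing.
#'
#' @param config A [simulation_config()].
#' @param condition,field_id Labels attached to the returned pair.
#' @return List with `pair` (a [field_pair()], intensities on the 16-bit
#'   scale 0..65535) and `truth` (data frame with one row per acinus:
#'   0-based `center_r`, `center_c`, `radius`, `phenotype`, `defocused`,
#'   `touches_border`).
#' @export
simulate_field <- function(config = simulation_config(), condition = "sim",
                           field_id = "field01") {
  cfg <- config
  with_seed(cfg$seed, {
    H <- cfg$image_size[1]; W <- cfg$image_size[2]
    n <- cfg$n_acini
    radii <- stats::runif(n, cfg$radius_range[1], cfg$radius_range[2])
    inside <- n - cfg$n_border_touching
    centers <- matrix(NA_real_, n, 2L)
    tries <- 0L
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > 10000L)
          stop("infeasible acinus placement: use fewer or smaller acini")
        margin <- radii[i] + cfg$min_gap + 4
        cand <- if (i <= inside)
          c(stats::runif(1, margin, H - margin), stats::runif(1, margin, W - margin))
        else  # center close to a border so the rim crosses the image edge
          c(stats::runif(1, 1, H), sample(c(stats::runif(1, 0, radii[i] / 2),
                                            W - stats::runif(1, 0, radii[i] / 2)), 1))
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (sqrt(sum((cand - centers[j, ])^2)) <
              radii[i] + radii[j] + cfg$min_gap) { ok <- FALSE; break }
        }
        if (ok) { centers[i, ] <- cand; break }
      }
    }
    phen <- sample(names(cfg$phenotype_mix), n, replace = TRUE,
                   prob = cfg$phenotype_mix)
    defoc <- stats::runif(n) < cfg$defocus_fraction
    nuc <- matrix(cfg$background, H, W)
    pol <- matrix(cfg$background, H, W)
    for (i in seq_len(n)) {
      R <- radii[i]
      pad <- ceiling(3 * cfg$defocus_sigma) + 4L
      half <- ceiling(R) + pad
      side <- 2L * half + 1L
      dr <- matrix(rep(-half:half, side), side, side)
      dc <- t(dr)
      dist <- sqrt(dr^2 + dc^2)
      rho <- dist / R
      # the marker membrane edge lies slightly outside the nuclear extent,
      # which is why segmentation dilates the nuclear-derived ROI
      env <- 1 / (1 + exp((dist - (R + 2.5)) / 1.5))
      # nuclear channel: intra-acinar haze + ring of sharp-edged nuclei
      pn <- cfg$haze_amp * exp(-(rho / 0.85)^6)
      angles <- stats::runif(1, 0, 2 * pi) +
        2 * pi * seq_len(cfg$nuclei_per_acinus) / cfg$nuclei_per_acinus +
        stats::rnorm(cfg$nuclei_per_acinus, 0, 0.1)
      rads <- 0.7 * R * stats::runif(cfg$nuclei_per_acinus, 0.9, 1.1)
      amps <- cfg$nuclear_amp * stats::runif(cfg$nuclei_per_acinus, 0.8, 1.2)
      nuclei <- matrix(0, side, side)
      for (k in seq_len(cfg$nuclei_per_acinus)) {
        nr <- rads[k] * cos(angles[k]); nc <- rads[k] * sin(angles[k])
        nd <- sqrt((dr - nr)^2 + (dc - nc)^2)
        nuclei <- nuclei + amps[k] /
          (1 + exp((nd - cfg$nucleus_radius) / 0.7))  # disc, ~1.5 px edge
      }
      # chromatin texture: fine-grained speckle, lost under defocus
      if (cfg$texture_sd > 0) {
        z <- matrix(as.numeric(EBImage::gblur(
          matrix(stats::rnorm(side^2), side, side), sigma = 1)), side, side)
        nuclei <- nuclei * pmax(0, 1 + cfg$texture_sd * z / stats::sd(z))
      }
      pn <- pn + nuclei
      pp <- cfg$polarity_amp * env *
        .polarity_law(pmin(rho, 1), phen[i], cfg$gradient_strength,
                      cfg$lumen_mode, cfg$lumen_frac)
      if (defoc[i]) {
        pn <- as.matrix(EBImage::gblur(pn, sigma = cfg$defocus_sigma))
        pp <- as.matrix(EBImage::gblur(pp, sigma = cfg$defocus_sigma))
      }
      rr <- round(centers[i, 1]) + (-half:half)
      cc <- round(centers[i, 2]) + (-half:half)
      rok <- rr >= 1L & rr <= H; cok <- cc >= 1L & cc <= W
      nuc[rr[rok], cc[cok]] <- nuc[rr[rok], cc[cok]] + pn[rok, cok]
      pol[rr[rok], cc[cok]] <- pol[rr[rok], cc[cok]] + pp[rok, cok]
    }
    if (cfg$noise_sd > 0) {
      nuc <- nuc + stats::rnorm(H * W, 0, cfg$noise_sd)
      pol <- pol + stats::rnorm(H * W, 0, cfg$noise_sd)
    }
    to16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535)
    truth <- data.frame(acinus_id = seq_len(n),
                        center_r = centers[, 1] - 1,
                        center_c = centers[, 2] - 1,
                        radius = radii, phenotype = phen, defocused = defoc,
                        touches_border = seq_len(n) > inside,
                        condition = condition, field_id = field_id)
    list(pair = field_pair(condition, field_id, to16(nuc), to16(pol)),
         truth = truth)
  })
}

#' Series of Gaussian-blurred copies of an image
#'
#' Used to build defocus degradation series for validating the WAVR focus
#' measure; sigma 0 returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param sigmas Non-negative, increasing blur sigmas.
#' @return List of matrices, one per sigma.
#' @export
blur_series <- function(image, sigmas) {
  stopifnot(all(sigmas >= 0), !is.unsorted(sigmas))
  lapply(sigmas, function(s) {
    if (s == 0) image
    else matrix(as.numeric(EBImage::gblur(image, sigma = s)),
                nrow(image), ncol(image))
  })
}

#' Simulate a whole on-disk dataset in pipeline-readable layout
#'
#' Writes one sub-folder per condition containing 16-bit TIFF channel
#' pairs, plus a `ground_truth.csv` at the root.
#'
#' @param out_dir Output directory.
#' @param conditions Named list of [simulation_config()] objects, one per
#'   condition.
#' @param fields_per_condition Fields simulated per condition.
#' @param seed Base seed; each field gets a distinct derived seed.
#' @param suffixes Channel filename suffixes (as in [discover_dataset()]).
#' @return Invisibly, the ground-truth data frame.
#' @export
simulate_dataset <- function(out_dir,
                             conditions = list(
                               polarized = simulation_config(
                                 phenotype_mix = c(1, 0, 0)),
                               nonpolar = simulation_config(
                                 phenotype_mix = c(0, 0, 1))),
                             fields_per_condition = 3L, seed = 1L,
                             suffixes = c(nuclear = "_dapi", polarity = "_pol")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  fi <- 0L
  for (cond in names(conditions)) {
    dir.create(file.path(out_dir, cond), showWarnings = FALSE)
    for (f in seq_len(fields_per_condition)) {
      fi <- fi + 1L
      cfg <- conditions[[cond]]
      cfg$seed <- (seed * 1009L + fi * 9973L) %% 2147483647L
      fid <- sprintf("field%02d", f)
      sim <- simulate_field(cfg, condition = cond, field_id = fid)
      write_raster(sim$pair$nuclear,
                   file.path(out_dir, cond,
                             paste0(fid, suffixes[["nuclear"]], ".tif")))
      write_raster(sim$pair$polarity,
                   file.path(out_dir, cond,
                             paste0(fid, suffixes[["polarity"]], ".tif")))
      truth[[fi]] <- sim$truth
    }
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}

#' Score pipeline output against simulator ground truth
#'
#' Matches detected acini to simulated ones by centroid distance and
#' reports detection sensitivity, focus-filter sensitivity and specificity,
#' per-phenotype sign-recovery accuracy and RP-index distributions.
#'
#' @param table Results table (all detected acini, excluded included).
#' @param truth Ground-truth data frame from the simulator.
#' @param match_radius Maximum centroid-to-center distance for a match (px).
#' @return List of class `rp_evaluation`: `matches` (per-truth-acinus data
#'   frame) and `metrics` (named list).
#' @export
evaluate_against_truth <- function(table, truth, match_radius = 10) {
  bad <- setdiff(unique(table$field_id), unique(truth$field_id))
  if (length(bad) > 0L)
    stop("field ids in results but not in truth: ", paste(bad, collapse = ", "))
  truth$detected <- FALSE
  truth$excluded_reason <- NA_character_
  truth$sign <- NA_integer_
  truth$rp_index <- NA_real_
  for (key in unique(paste(truth$condition, truth$field_id))) {
    ti <- which(paste(truth$condition, truth$field_id) == key)
    di <- which(paste(table$condition, table$field_id) == key)
    if (length(di) == 0L) next
    dmat <- outer(seq_along(ti), seq_along(di), function(a, b)
      sqrt((truth$center_r[ti[a]] - table$centroid_r[di[b]])^2 +
           (truth$center_c[ti[a]] - table$centroid_c[di[b]])^2))
    while (TRUE) {
      m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = FALSE]
      if (!is.finite(dmat[m]) || dmat[m] > match_radius) break
      a <- ti[m[1]]; b <- di[m[2]]
      truth$detected[a] <- TRUE
      truth$excluded_reason[a] <- table$excluded_reason[b]
      truth$sign[a] <- table$sign[b]
      truth$rp_index[a] <- table$rp_index[b]
      dmat[m[1], ] <- Inf; dmat[, m[2]] <- Inf
    }
  }
  interior <- !truth$touches_border
  det <- truth$detected
  sharp <- det & !truth$defocused & interior
  blurred <- det & truth$defocused & interior
  retained <- det & !is.na(truth$excluded_reason) &
    truth$excluded_reason == "none"
  metrics <- list(
    n_truth = nrow(truth),
    n_detected = sum(det),
    detection_sensitivity = mean(det[interior]),
    focus_sensitivity = if (any(blurred))
      mean(truth$excluded_reason[blurred] == "blur") else NA_real_,
    focus_specificity = if (any(sharp))
      mean(truth$excluded_reason[sharp] != "blur") else NA_real_,
    sign_accuracy_apical = {
      s <- retained & truth$phenotype == "apical"
      if (any(s)) mean(truth$sign[s] == 1L) else NA_real_
    },
    sign_accuracy_basal = {
      s <- retained & truth$phenotype == "basal"
      if (any(s)) mean(truth$sign[s] == -1L) else NA_real_
    },
    mean_rp_by_phenotype = vapply(c("apical", "basal", "nonpolar"),
      function(ph) {
        s <- retained & truth$phenotype == ph
        if (any(s)) mean(truth$rp_index[s]) else NA_real_
      }, numeric(1)))
  structure(list(matches = truth, metrics = metrics), class = "rp_evaluation")
}

#' @export
print.rp_evaluation <- function(x, ...) {
  m <- x$metrics
  cat("<rp_evaluation>\n")
  cat(sprintf("  detected %d / %d (sensitivity %.3f among interior acini)\n",
              m$n_detected, m$n_truth, m$detection_sensitivity))
  cat(sprintf("  focus filter: sensitivity %.3f, specificity %.3f\n",
              m$focus_sensitivity, m$focus_specificity))
  cat(sprintf("  sign recovery: apical %.3f, basal %.3f\n",
              m$sign_accuracy_apical, m$sign_accuracy_basal))
  cat("  mean rp_index:",
      paste(names(m$mean_rp_by_phenotype),
            sprintf("%.3f", m$mean_rp_by_phenotype), collapse = ", "), "\n")
  invisible(x)
}
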