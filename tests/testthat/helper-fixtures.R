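# Geometric fixtures built in code; all tests are self-contained.

# Rasterized solid disk: TRUE where (r-cr)^2 + (c-cc)^2 <= R^2.
disk_mask <- function(R, size = 2 * R + 11, center = c(size, size) / 2) {
  rr <- matrix(rep(seq_len(size), size), size, size)
  cc <- t(rr)
  (rr - center[1])^2 + (cc - center[2])^2 <= R^2
}

# Drop attributes (e.g. the threshold) so masks compare by content.
mask_of <- function(m) matrix(as.vector(m), nrow(m))

# Brute-force Otsu: try every one of the 255 histogram cuts, recomputing
# class weights and means directly.
otsu_oracle_threshold <- function(x) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / 256
  ix <- pmin(pmax(ceiling((x - lo) / w), 1), 256)
  mids <- lo + (1:256 - 0.5) * w
  best <- -Inf; bt <- lo
  for (t in 1:255) {
    in0 <- ix <= t
    if (!any(in0) || all(in0)) next
    v <- sum(in0) * sum(!in0) * (mean(mids[ix[in0]]) - mean(mids[ix[!in0]]))^2
    if (v > best) { best <- v; bt <- lo + t * w }
  }
  bt
}

# Small, fast simulator configuration used throughout the suite; named
# arguments override the quick defaults.
quick_sim <- function(seed, ...) {
  args <- list(image_size = c(256L, 256L), n_acini = 4L,
               radius_range = c(12, 16), seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

quick_run_config <- function(...) {
  args <- list(min_area = 150L, wavr_cutoff = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(default_run_config, args)
}

# Collect per-acinus rows from several seeded simulated fields.
simulate_batch <- function(seeds, config_fun, run_config = quick_run_config()) {
  tabs <- list(); truths <- list()
  for (s in seeds) {
    sim <- simulate_field(config_fun(s), field_id = sprintf("f%04d", s))
    an <- analyze_field(sim$pair, run_config)
    tabs[[length(tabs) + 1L]] <- an$table
    truths[[length(truths) + 1L]] <- sim$truth
  }
  list(table = do.call(rbind, tabs), truth = do.call(rbind, truths))
}

# Match detected acini to truth by nearest centroid; returns merged rows.
match_to_truth <- function(table, truth, match_radius = 10) {
  out <- list()
  for (i in seq_len(nrow(truth))) {
    sel <- table$field_id == truth$field_id[i]
    if (!any(sel)) next
    tb <- table[sel, , drop = FALSE]
    d <- sqrt((tb$centroid_r - truth$center_r[i])^2 +
              (tb$centroid_c - truth$center_c[i])^2)
    j <- which.min(d)
    if (d[j] <= match_radius)
      out[[length(out) + 1L]] <- cbind(truth[i, c("phenotype", "defocused")],
                                       tb[j, , drop = FALSE])
  }
  do.call(rbind, out)
}
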