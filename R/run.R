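#' Default run configuration
#'
#' Analysis parameters for the batch pipeline. Defaults target 20x
#' magnification widefield images; the dilation radius and terrace count in
#' particular should be adapted to the magnification in use.
#'
#' @param n_terraces Radial bins per acinus (default 8).
#' @param min_area,max_area Retained ROI area range (px).
#' @param dilation_radius ROI dilation beyond the nuclear mask (px).
#' @param border_smooth_radius Disk radius for mask border smoothing (px).
#' @param seed_suppression_depth Watershed seed suppression depth (px).
#' @param wavr_cutoff WAVR focus cutoff, or `"auto"` to derive it from
#'   per-class normal fits when a labeled blur series is available.
#' @param suffixes Channel filename suffixes.
#' @param seed Seed driving all randomized outputs (blind manifest).
#' @return List of class `run_config`.
#' @export
default_run_config <- function(n_terraces = 8L, min_area = 300L,
                               max_area = 20000L, dilation_radius = 3L,
                               border_smooth_radius = 2L,
                               seed_suppression_depth = 2,
                               wavr_cutoff = 0.8,
                               suffixes = c(nuclear = "_dapi",
                                            polarity = "_pol"),
                               seed = 1L) {
  stopifnot(n_terraces >= 2L, min_area <= max_area, dilation_radius >= 0,
            border_smooth_radius >= 0, seed_suppression_depth >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$suffixes <- unlist(y$suffixes)
  do.call(default_run_config, y[names(y) %in% names(formals(default_run_config))])
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.null(names(x))) x else as.list(x)), path)
  invisible(path)
}

#' Analyze every field of a dataset
#'
#' @param dataset An `acini_dataset` from [discover_dataset()].
#' @param config Run configuration.
#' @return Object of class `acini_analysis`: `fields` (named list of
#'   [analyze_field()] outputs, keyed `condition/field_id`), `table` (the
#'   combined results table) and `config`.
#' @export
analyze_dataset <- function(dataset, config = default_run_config()) {
  fields <- lapply(dataset, analyze_field, config = config)
  names(fields) <- vapply(dataset, function(p)
    paste(p$condition, p$field_id, sep = "/"), "")
  tab <- do.call(rbind, lapply(fields, `[[`, "table"))
  rownames(tab) <- NULL
  structure(list(fields = fields, table = tab, config = config),
            class = "acini_analysis")
}

#' @export
print.acini_analysis <- function(x, ...) {
  cat(sprintf("<acini_analysis> %d fields, %d acini (%d retained)\n",
              length(x$fields), nrow(x$table),
              sum(x$table$excluded_reason == "none")))
  invisible(x)
}

#' Run the unsupervised batch analysis
#'
#' Discovers the dataset, analyzes every field, and writes all outputs:
#' `results.csv` (one row per detected acinus), `qc.csv`, `summary.csv`,
#' `comparisons.csv` (pairwise condition t-tests), annotated overlays under
#' `overlays/`, the configuration as `config.yaml`, and `log.txt` with
#' per-field exclusion counts. Deterministic: re-running with the same
#' inputs and configuration reproduces the CSVs byte for byte.
#'
#' @param input Dataset root directory.
#' @param output Output directory (created).
#' @param config Run configuration (`run_config` list or YAML path).
#' @param overlays Write annotated overlay PNGs.
#' @return Invisibly, the `acini_analysis` object.
#' @export
rp_run <- function(input, output, config = default_run_config(),
                   overlays = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  ds <- discover_dataset(input, config$suffixes)
  an <- analyze_dataset(ds, config)
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  tab <- an$table
  utils::write.csv(format_num(tab), file.path(output, "results.csv"),
                   row.names = FALSE)
  qc <- tab[, c("condition", "field_id", "acinus_id", "area_px", "wavr",
                "excluded_reason")]
  utils::write.csv(format_num(qc), file.path(output, "qc.csv"),
                   row.names = FALSE)
  summ <- withCallingHandlers(summarize_groups(tab),
                              warning = function(w) invokeRestart("muffleWarning"))
  utils::write.csv(format_num(summ), file.path(output, "summary.csv"),
                   row.names = FALSE)
  comp <- suppressWarnings(compare_groups(tab))
  if (!is.null(comp))
    utils::write.csv(format_num(comp), file.path(output, "comparisons.csv"),
                     row.names = FALSE)
  if (overlays) {
    dir.create(file.path(output, "overlays"), showWarnings = FALSE)
    for (key in names(an$fields)) {
      fld <- an$fields[[key]]
      write_annotated_overlay(fld$pair, fld$seg, fld$table,
        file.path(output, "overlays", paste0(gsub("/", "_", key), ".png")))
    }
  }
  write_run_config(config, file.path(output, "config.yaml"))
  writeLines(run_log_lines(an), file.path(output, "log.txt"))
  invisible(an)
}

# Fixed-precision formatting so CSV output is byte-stable across platforms.
format_num <- function(df) {
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.6g", df[[cl]])
  df
}

run_log_lines <- function(an) {
  lines <- character()
  for (key in names(an$fields)) {
    t <- an$fields[[key]]$table
    cnt <- function(r) sum(t$excluded_reason == r)
    lines <- c(lines, sprintf(
      "%s: detected %d | border %d | size %d | blur %d | degenerate %d | retained %d",
      key, nrow(t), cnt("border"), cnt("size"), cnt("blur"),
      cnt("degenerate"), cnt("none")))
  }
  c(lines, sprintf("total acini: %d", nrow(an$table)))
}

#' Simulate a dataset from the command-line entry point
#'
#' Thin wrapper over [simulate_dataset()] used by the `simulate`
#' subcommand: two conditions by default, a polarized (apical) one and a
#' nonpolar one.
#'
#' @param output Output directory.
#' @param fields_per_condition Fields per condition.
#' @param seed Base seed.
#' @param defocus_fraction Fraction of defocused acini in both conditions.
#' @return Invisibly, the ground-truth data frame.
#' @export
rp_simulate <- function(output, fields_per_condition = 3L, seed = 1L,
                        defocus_fraction = 0) {
  simulate_dataset(
    output,
    conditions = list(
      polarized = simulation_config(phenotype_mix = c(1, 0, 0),
                                    defocus_fraction = defocus_fraction),
      nonpolar = simulation_config(phenotype_mix = c(0, 0, 1),
                                   defocus_fraction = defocus_fraction)),
    fields_per_condition = fields_per_condition, seed = seed)
}

#' Evaluate a finished run against simulator ground truth
#'
#' @param results_csv `results.csv` written by [rp_run()].
#' @param truth_csv `ground_truth.csv` written by the simulator.
#' @param out_path Optional CSV path for the metric report.
#' @return The `rp_evaluation` object, invisibly.
#' @export
rp_evaluate <- function(results_csv, truth_csv, out_path = NULL) {
  tab <- utils::read.csv(results_csv)
  truth <- utils::read.csv(truth_csv)
  ev <- evaluate_against_truth(tab, truth)
  if (!is.null(out_path)) {
    m <- ev$metrics
    flat <- data.frame(
      metric = c("n_truth", "n_detected", "detection_sensitivity",
                 "focus_sensitivity", "focus_specificity",
                 "sign_accuracy_apical", "sign_accuracy_basal",
                 paste0("mean_rp_", names(m$mean_rp_by_phenotype))),
      value = c(m$n_truth, m$n_detected, m$detection_sensitivity,
                m$focus_sensitivity, m$focus_specificity,
                m$sign_accuracy_apical, m$sign_accuracy_basal,
                unname(m$mean_rp_by_phenotype)))
    utils::write.csv(flat, out_path, row.names = FALSE)
  }
  invisible(ev)
}
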