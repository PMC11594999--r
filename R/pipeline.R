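#' Per-cell feature vector
#'
#' Computes the full feature vector of one cell ROI: the six raw
#' lifetime-histogram statistics, the four riu2-LBP summary statistics, and
#' (optionally) the P+2-bin normalized LBP code histogram.
#'
#' @param mat Lifetime matrix of the cell.
#' @param roi [roi_rect()] of the cell.
#' @param lbp [lbp_params()].
#' @param entropy_bins,entropy_base Passed to [histogram_stats()] /
#'   [lbp_stats()].
#' @param include_histogram Append the normalized LBP histogram columns
#'   \code{lbp_h00..}.
#' @return One-row data frame.
#' @export
cell_features <- function(mat, roi, lbp = lbp_params(), entropy_bins = 32L,
                          entropy_base = "e", include_histogram = FALSE) {
  r <- extract_roi(mat, roi)
  hs <- histogram_stats(r, entropy_bins, entropy_base)
  cm <- lbp_transform(r, lbp)
  ls <- lbp_stats(cm, entropy_base)
  out <- data.frame(mean_ps = hs$mean_ps, sd_ps = hs$sd_ps,
                    skewness = hs$skewness, entropy = hs$entropy,
                    p5_ps = hs$p5_ps, p95_ps = hs$p95_ps,
                    lbp_mean = ls$lbp_mean, lbp_sd = ls$lbp_sd,
                    lbp_skewness = ls$lbp_skewness,
                    lbp_entropy = ls$lbp_entropy)
  if (include_histogram) {
    hnorm <- lbp_histogram(cm)$normalized
    hdf <- as.data.frame(t(hnorm))
    names(hdf) <- sprintf("lbp_h%02d", seq_along(hnorm) - 1L)
    out <- cbind(out, hdf)
  }
  out
}

#' Feature table for a cohort or manifest
#'
#' @param cohort A [generate_cohort()] result or a manifest data frame.
#' @param base_dir Root for relative matrix paths when reading from disk.
#' @inheritParams cell_features
#' @return Data frame: manifest identity columns plus feature columns, one
#'   row per cell.
#' @export
cohort_features <- function(cohort, lbp = lbp_params(), entropy_bins = 32L,
                            entropy_base = "e", include_histogram = FALSE,
                            base_dir = ".") {
  if (inherits(cohort, "flim_cohort")) {
    manifest <- cohort$manifest
    get_mat <- function(i) cohort$cells[[manifest$cell_id[i]]]$matrix
  } else {
    manifest <- cohort
    get_mat <- function(i)
      read_lifetime_matrix(file.path(base_dir, manifest$path[i]))
  }
  feats <- lapply(seq_len(nrow(manifest)), function(i)
    cell_features(get_mat(i), manifest_roi(manifest[i, ]), lbp,
                  entropy_bins, entropy_base, include_histogram))
  cbind(manifest[c("cell_id", "patient_id", "group", "subtype",
                   "shape_class")],
        do.call(rbind, feats))
}

lbp_feature_names <- c("lbp_mean", "lbp_sd", "lbp_skewness", "lbp_entropy")

feature_set_columns <- function(feature_set, available) {
  switch(feature_set,
         summary4 = lbp_feature_names,
         lbp26 = grep("^lbp_h[0-9]+$", available, value = TRUE),
         all = setdiff(available[grepl("^(mean_ps|sd_ps|skewness|entropy|p5_ps|p95_ps|lbp_)",
                                       available)], character(0)),
         stop("unknown feature_set: ", feature_set))
}

#' Classify control vs SCD from a feature table
#'
#' Runs the study-shaped discriminant analysis on control cells vs the
#' morphologically normal (non-sickled) SCD cells. At \code{level =
#' "cell"} every cell is a validation unit; at \code{level = "patient"}
#' features are first averaged per patient ([aggregate_per_patient()]).
#' Stepwise selection over the LBP summary statistics (default) is followed
#' by leave-one-out validation, plus a repeated 50/50 hold-out run of the
#' LDA classifier reporting mean accuracy and macro F-score.
#'
#' @param features Output of [cohort_features()].
#' @param level \code{"cell"} or \code{"patient"}.
#' @param feature_set \code{"summary4"} (four LBP statistics, default),
#'   \code{"lbp26"} (code histogram), or \code{"all"}.
#' @param stepwise Run stepwise selection (default TRUE).
#' @param holdout_repeats Repeats of the 50/50 hold-out (default 10).
#' @param seed Seed for the hold-out splits.
#' @param sw_args Extra arguments for [stepwise_select()].
#' @return List of class \code{"flim_classification"}: \code{level},
#'   \code{selected}, \code{loo} and \code{holdout} validation reports.
#' @export
classify_cohort <- function(features, level = c("cell", "patient"),
                            feature_set = c("summary4", "lbp26", "all"),
                            stepwise = TRUE, holdout_repeats = 10L,
                            seed = 1L, sw_args = list()) {
  level <- match.arg(level)
  feature_set <- match.arg(feature_set)
  keep <- features$subtype %in% c("control", "nonsickled")
  feats <- features[keep, , drop = FALSE]
  if (level == "patient") {
    manifest <- feats[c("cell_id", "patient_id", "group")]
    feats <- aggregate_per_patient(
      feats[c("cell_id", names(feats)[vapply(feats, is.numeric, logical(1L))])],
      manifest)
    unit_ids <- feats$patient_id
  } else {
    unit_ids <- feats$cell_id
  }
  cols <- feature_set_columns(feature_set, names(feats))
  X <- feats[cols]
  y <- factor(feats$group, levels = c("control", "SCD"))
  loo <- loo_validate(X, y, unit_ids = unit_ids, stepwise = stepwise,
                      sw_args = sw_args)
  ho <- holdout_validate(X, y, repeats = holdout_repeats, seed = seed,
                         stepwise = FALSE)
  structure(list(level = level, feature_set = feature_set,
                 selected = loo$selected_features, loo = loo, holdout = ho,
                 n = nrow(X)), class = "flim_classification")
}

#' @export
print.flim_classification <- function(x, ...) {
  cat(sprintf("Classification at %s level (%s features)\n", x$level,
              x$feature_set))
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  accuracy %.1f%%, LOO %.1f%% (n = %d)\n",
              100 * x$loo$accuracy, 100 * x$loo$accuracy_loo, x$n))
  cat(sprintf("  hold-out %.1f%% +/- %.1f%%, macro F %.2f +/- %.2f\n",
              100 * x$holdout$accuracy, 100 * x$holdout$accuracy_sd,
              x$holdout$f_score_mean, x$holdout$f_score_sd))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Flat key-value configuration covering the generator, LBP and entropy
#' settings, stepwise thresholds and validation settings. Round-trips
#' through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @return Named list of class \code{"flim_config"}.
#' @export
default_pipeline_config <- function() {
  structure(list(
    controls = 27L, scd_patients = 45L,
    cells_control = 10L, cells_nonsickled = 10L, cells_sickled = 5L,
    cell_diameter_px = 60L, background_lifetime_ps = 450,
    mean_control = 175.531, mean_nonsickled = 193.891, mean_sickled = 253.335,
    sd_control = 30.222, sd_nonsickled = 28.091, sd_sickled = 58.614,
    cell_mean_jitter_ps = 8,
    texture_fine_sigma_px = 0.8, texture_coarse_sigma_px = 1.8,
    fine_frac_control = 0.15, fine_frac_nonsickled = 0.15,
    fine_frac_sickled = 0.40,
    coarse_frac_control = 0.05, coarse_frac_nonsickled = 0.12,
    coarse_frac_sickled = 0.20,
    impulse_frac_control = 0.005, impulse_frac_nonsickled = 0.012,
    impulse_frac_sickled = 0.030, texture_impulse_amp = 3,
    texture_cell_sd = 0.05, texture_patient_sd = 0.04,
    impulse_cell_sd = 0.004, impulse_patient_sd = 0.003,
    dot_count_min = 0L, dot_count_max = 3L, dot_radius_px = 2,
    dot_lifetime_offset_ps = 150,
    patch_area_min = 0.10, patch_area_max = 0.30,
    patch_offset_min_ps = 80, patch_offset_max_ps = 200,
    pixel_noise_model = "gaussian",
    lbp_P = 24L, lbp_R = 3, entropy_bins = 32L, entropy_base = "e",
    f_enter = 3.84, f_remove = 2.71,
    holdout_repeats = 10L, foci_threshold_sd = 4, foci_min_area_px = 3L
  ), class = "flim_config")
}

config_to_params <- function(cfg) {
  flim_default_params(
    cell_diameter_px = cfg$cell_diameter_px,
    background_lifetime_ps = cfg$background_lifetime_ps,
    class_means_ps = c(control = cfg$mean_control,
                       nonsickled = cfg$mean_nonsickled,
                       sickled = cfg$mean_sickled),
    class_sds_ps = c(control = cfg$sd_control,
                     nonsickled = cfg$sd_nonsickled,
                     sickled = cfg$sd_sickled),
    cell_mean_jitter_ps = cfg$cell_mean_jitter_ps,
    texture_fine_sigma_px = cfg$texture_fine_sigma_px,
    texture_coarse_sigma_px = cfg$texture_coarse_sigma_px,
    texture_fine_frac = c(control = cfg$fine_frac_control,
                          nonsickled = cfg$fine_frac_nonsickled,
                          sickled = cfg$fine_frac_sickled),
    texture_coarse_frac = c(control = cfg$coarse_frac_control,
                            nonsickled = cfg$coarse_frac_nonsickled,
                            sickled = cfg$coarse_frac_sickled),
    texture_impulse_frac = c(control = cfg$impulse_frac_control,
                             nonsickled = cfg$impulse_frac_nonsickled,
                             sickled = cfg$impulse_frac_sickled),
    texture_impulse_amp = cfg$texture_impulse_amp,
    texture_cell_sd = cfg$texture_cell_sd,
    texture_patient_sd = cfg$texture_patient_sd,
    impulse_cell_sd = cfg$impulse_cell_sd,
    impulse_patient_sd = cfg$impulse_patient_sd,
    dot_count_range = c(cfg$dot_count_min, cfg$dot_count_max),
    dot_radius_px = cfg$dot_radius_px,
    dot_lifetime_offset_ps = cfg$dot_lifetime_offset_ps,
    patch_area_fraction = c(cfg$patch_area_min, cfg$patch_area_max),
    patch_lifetime_offset_ps = c(cfg$patch_offset_min_ps,
                                 cfg$patch_offset_max_ps),
    pixel_noise_model = cfg$pixel_noise_model)
}

#' Read / write a pipeline configuration
#'
#' Plain \code{key = value} text; unknown keys are rejected, missing keys
#' take their defaults. Numeric-looking values are parsed as numbers.
#'
#' @param path Config file.
#' @return A \code{"flim_config"} list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- default_pipeline_config()
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) {
      if (is.integer(default_pipeline_config()[[key]])) as.integer(num) else num
    } else val
  }
  validate_gen_params(config_to_params(cfg))  # fail early on bad values
  cfg
}

#' @param cfg A \code{"flim_config"} list.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "flim_config") || is.list(cfg))
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.numeric(v)) format(v, digits = 17) else v)
  }, character(1L))
  writeLines(fmt, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' simulate -> features -> classify (cell and patient level) -> compare ->
#' foci, writing every intermediate in its documented text format under
#' \code{out_dir} together with a plain-text log (one line per stage with
#' wall time and record counts). The configuration is written first and its
#' MD5 hash embedded in the log for provenance. Fully deterministic for a
#' fixed seed.
#'
#' @param config A \code{"flim_config"} list (default
#'   [default_pipeline_config()]).
#' @param out_dir Output directory (created).
#' @param seed Master seed.
#' @return Invisibly, a list with the manifest, feature table, cell/patient
#'   classification reports, comparison tables and foci report.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    cat(sprintf("stage %-10s ok %6.2fs  %s\n", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                attr(res, "log_note") %||% ""),
        file = log_path, append = TRUE)
    res
  }

  cfg_path <- file.path(out_dir, "config.txt")
  write_pipeline_config(config, cfg_path)
  cat(sprintf("flimtex run  seed=%d  config_md5=%s  R=%s\n", seed,
              unname(tools::md5sum(cfg_path)), getRversion()),
      file = log_path, append = TRUE)

  params <- config_to_params(config)
  cohort <- stage("simulate", {
    co <- generate_cohort(
      patients_per_group = c(control = config$controls,
                             scd = config$scd_patients),
      cells_per_patient = c(control = config$cells_control,
                            nonsickled = config$cells_nonsickled,
                            sickled = config$cells_sickled),
      params = params, seed = seed, out_dir = out_dir)
    attr(co, "log_note") <- sprintf("%d cells", nrow(co$manifest))
    co
  })

  feats <- stage("features", {
    f <- cohort_features(cohort, lbp_params(config$lbp_P, config$lbp_R),
                         config$entropy_bins, config$entropy_base,
                         include_histogram = TRUE)
    utils::write.table(f, file.path(out_dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    attr(f, "log_note") <- sprintf("%d rows x %d cols", nrow(f), ncol(f))
    f
  })

  sw_args <- list(f_enter = config$f_enter, f_remove = config$f_remove)
  cls_cell <- stage("classify_c", {
    r <- classify_cohort(feats, "cell", seed = seed,
                         holdout_repeats = config$holdout_repeats,
                         sw_args = sw_args)
    attr(r, "log_note") <- sprintf("LOO %.3f", r$loo$accuracy_loo)
    r
  })
  cls_patient <- stage("classify_p", {
    r <- classify_cohort(feats, "patient", seed = seed,
                         holdout_repeats = config$holdout_repeats,
                         sw_args = sw_args)
    attr(r, "log_note") <- sprintf("LOO %.3f", r$loo$accuracy_loo)
    r
  })
  for (cl in list(cls_cell, cls_patient)) {
    rep <- list(level = cl$level, selected = cl$selected,
                accuracy = cl$loo$accuracy, accuracy_loo = cl$loo$accuracy_loo,
                holdout_accuracy_mean = cl$holdout$accuracy,
                holdout_accuracy_sd = cl$holdout$accuracy_sd,
                f_score_mean = cl$holdout$f_score_mean,
                f_score_sd = cl$holdout$f_score_sd,
                per_repeat_accuracy = cl$holdout$per_repeat_accuracy,
                confusion_loo = as.vector(cl$loo$confusion))
    jsonlite::write_json(rep, file.path(out_dir,
                                        sprintf("classification_%s.json",
                                                cl$level)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  comparisons <- stage("compare", {
    num_cols <- c("mean_ps", "sd_ps", "skewness", "entropy", "p5_ps",
                  "p95_ps", lbp_feature_names)
    cn <- feats[feats$subtype %in% c("control", "nonsickled"), ]
    tab1 <- compare_groups(cn[num_cols], cn$subtype)
    out <- list(control_vs_nonsickled = tab1)
    if (any(feats$subtype == "sickled")) {
      # paired at patient level: mean per patient and class
      scd <- feats[feats$subtype %in% c("nonsickled", "sickled"), ]
      agg <- stats::aggregate(scd[num_cols],
                              by = list(patient_id = scd$patient_id,
                                        subtype = scd$subtype), FUN = mean)
      ns <- agg[agg$subtype == "nonsickled", ]
      sk <- agg[agg$subtype == "sickled", ]
      common <- intersect(ns$patient_id, sk$patient_id)
      ns <- ns[match(common, ns$patient_id), ]
      sk <- sk[match(common, sk$patient_id), ]
      both <- rbind(ns, sk)
      tab2 <- compare_groups(both[num_cols], both$subtype, paired = TRUE)
      out$nonsickled_vs_sickled <- tab2
    } else {
      cat("notice: no sickled cells generated; nonsickled-vs-sickled comparison skipped\n",
          file = log_path, append = TRUE)
    }
    for (nm in names(out))
      utils::write.table(out[[nm]],
                         file.path(out_dir, sprintf("compare_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    attr(out, "log_note") <- paste(names(out), collapse = ", ")
    out
  })

  foci <- stage("foci", {
    fr <- foci_report(cohort, config$foci_threshold_sd,
                      config$foci_min_area_px)
    utils::write.table(fr, file.path(out_dir, "foci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    attr(fr, "log_note") <- sprintf("mean foci/cell %.2f",
                                    mean(fr$foci_count))
    fr
  })

  cat(sprintf("pipeline done in %.1fs\n",
              as.numeric(difftime(Sys.time(), t_all, units = "secs"))),
      file = log_path, append = TRUE)
  invisible(list(manifest = cohort$manifest, features = feats,
                 classification_cell = cls_cell,
                 classification_patient = cls_patient,
                 comparisons = comparisons, foci = foci))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
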