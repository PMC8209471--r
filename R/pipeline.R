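#' Pipeline configuration
#'
#' Returns the full analysis configuration with every default set to the
#' published analysis settings: theta band 4-7 Hz, connectivity window
#' (0.1, 0.6) s, 50-point Morlet bank over 3.9-40 Hz with 3-11.4 cycles,
#' baseline (-0.2, -0.1) s, MVAR order chosen by BIC (the clinical analysis
#' fixed 9), 5,000 phase-randomized surrogates at alpha 0.05, selection grids
#' to 50 features, 10,000 permutations for both the cluster and the
#' classifier tests, FDR q 0.05. Any field may be overridden.
#'
#' @param ... Named overrides of the defaults (nested lists are merged
#'   field-wise).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band = c(4, 7),
    window = c(0.1, 0.6),
    baseline = c(-0.2, -0.1),
    tf_channels = c("F3", "F4"),
    wavelet = list(f_min = 3.9, f_max = 40, n_points = 50L,
                   c_min = 3, c_max = 11.4),
    mvar = list(order = "auto", p_range = 1:12, freq_step = 0.25),
    surrogate = list(enabled = TRUE, n = 5000L, alpha = 0.05),
    selection = list(n_max = 50L, l_max = 50L, rank_mode = "within_fold"),
    svm = list(cost = 1),
    stats = list(n_perm_cluster = 10000L, pixel_alpha = 0.01,
                 fw_alpha = 0.05, stat_window = c(-0.2, 1.0),
                 n_perm_classifier = 10000L, fdr_q = 0.05),
    positive_class = "SZ",
    seed = 1L
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

validate_pipeline_config <- function(cfg) {
  stopifnot(length(cfg$band) == 2L, cfg$band[1] <= cfg$band[2],
            length(cfg$window) == 2L, cfg$window[1] < cfg$window[2],
            cfg$baseline[2] <= 0,
            cfg$wavelet$f_min > 0, cfg$wavelet$f_min < cfg$wavelet$f_max,
            cfg$wavelet$n_points >= 2,
            cfg$surrogate$n >= 100, cfg$surrogate$alpha > 0,
            cfg$surrogate$alpha < 1,
            cfg$selection$n_max >= 1, cfg$selection$l_max >= 2,
            cfg$selection$rank_mode %in% c("within_fold", "whole_data"),
            cfg$svm$cost > 0,
            cfg$stats$n_perm_cluster >= 100,
            cfg$stats$pixel_alpha > 0, cfg$stats$pixel_alpha < 1,
            cfg$stats$fw_alpha > 0, cfg$stats$fw_alpha < 1,
            cfg$stats$n_perm_classifier >= 100,
            cfg$stats$fdr_q > 0, cfg$stats$fdr_q < 1)
  if (!(identical(cfg$mvar$order, "auto") ||
        (is.numeric(cfg$mvar$order) && cfg$mvar$order >= 1))) {
    stop("validation error: mvar$order must be \"auto\" or a positive integer")
  }
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' A YAML document whose keys override the defaults of [pipeline_config()];
#' an empty document reproduces the published settings.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(pipeline_config, over)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))
  }
}

load_study_subjects <- function(study) {
  if (inherits(study, "two_group_study")) {
    return(list(subjects = study$subjects, manifest = study$manifest))
  }
  if (is.character(study) && length(study) == 1L) study <- read_manifest(study)
  if (is.data.frame(study)) {
    subjects <- lapply(study$path, read_epochset)
    names(subjects) <- study$subject_id
    return(list(subjects = subjects, manifest = study))
  }
  stop("validation error: `study` must be a two_group_study, a manifest data ",
       "frame, or a manifest path")
}

#' Run the full connectivity-fusion analysis
#'
#' Executes every stage on a cohort of epoched subjects: Morlet
#' time-frequency maps and the cluster-based permutation comparison of group
#' power; per-subject PLI and (surrogate-thresholded) PDC connectivity; the
#' fused feature table; the three Fisher-score selection strategies with
#' LOOCV linear-SVM classification; the modified permutation significance
#' test of the best strategy; and the rank-sum + FDR comparison of the
#' winning feature set. Fully deterministic given `config$seed`.
#'
#' @param study A `two_group_study`, a manifest data frame, or a manifest
#'   path.
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, the report tables are
#'   written there as TSV/YAML.
#' @param verbose Emit one log line per stage.
#' @return An object of class `pipeline_report`: `cluster_test`, `tf_maps`,
#'   `feature_table`, `results` (list of the three `cv_result`s), `best`
#'   (name of the winning strategy), `performance` (Table-1-shaped data
#'   frame), `perm_test`, `feature_comparison` (Table-2-shaped data frame),
#'   `order` (MVAR order used), `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  set.seed(config$seed)
  loaded <- load_study_subjects(study)
  subjects <- loaded$subjects
  manifest <- loaded$manifest
  groups <- unique(manifest$group)
  if (length(groups) != 2L || any(table(manifest$group) < 2L)) {
    stop("validation error: manifest must contain two groups with >= 2 ",
         "subjects each")
  }
  fs <- subjects[[1]]$fs
  bank <- build_wavelet_bank(config$wavelet$f_min, config$wavelet$f_max,
                             config$wavelet$n_points, config$wavelet$c_min,
                             config$wavelet$c_max, fs = fs)

  tf_channels <- intersect(config$tf_channels, subjects[[1]]$montage)
  cluster <- NULL
  tf_maps <- NULL
  if (length(tf_channels) > 0L) {
    t0 <- Sys.time()
    tf_maps <- lapply(subjects, tf_power_map, bank = bank,
                      channels = tf_channels, baseline = config$baseline)
    cluster <- cluster_permutation_test(
      tf_maps[manifest$group == groups[1]],
      tf_maps[manifest$group == groups[2]],
      n_perm = config$stats$n_perm_cluster,
      pixel_alpha = config$stats$pixel_alpha,
      fw_alpha = config$stats$fw_alpha,
      time_window = config$stats$stat_window)
    log_stage(verbose, "timefreq", "cluster test on %d maps (%.1f s)",
              length(tf_maps), as.numeric(Sys.time() - t0, units = "secs"))
  }

  t0 <- Sys.time()
  order_p <- config$mvar$order
  if (identical(order_p, "auto")) {
    per_subj <- vapply(subjects, function(ep) {
      select_order_bic(ep, window = config$window,
                       p_range = config$mvar$p_range)
    }, integer(1))
    order_p <- as.integer(round(stats::median(per_subj)))
    log_stage(verbose, "mvar", "BIC order selection: using order %d", order_p)
  }
  order_p <- as.integer(order_p)

  pli_list <- list()
  pdc_list <- list()
  for (sid in names(subjects)) {
    ep <- subjects[[sid]]
    pli_list[[sid]] <- pli_matrix(ep, bank, band = config$band,
                                  window = config$window)
    covs <- ensemble_covariance(ep, config$window, max_lag = order_p)
    model <- suppressWarnings(fit_mvar(covs, order_p))
    pd <- band_average_pdc(model, band = config$band,
                           freq_step = config$mvar$freq_step)
    if (isTRUE(config$surrogate$enabled)) {
      null <- surrogate_threshold(ep, config$window, config$band, order_p,
                                  n_surrogates = config$surrogate$n,
                                  alpha = config$surrogate$alpha,
                                  freq_step = config$mvar$freq_step)
      pd <- apply_threshold(pd, null)
    }
    pdc_list[[sid]] <- pd
  }
  log_stage(verbose, "connectivity", "%d subjects (%.1f s)", length(subjects),
            as.numeric(Sys.time() - t0, units = "secs"))

  table <- build_feature_table(pli_list, pdc_list, manifest$group,
                               subject_ids = manifest$subject_id)
  t0 <- Sys.time()
  res_pli <- select_and_classify_single(
    table, "PLI", n_max = min(config$selection$n_max, 190L),
    rank_mode = config$selection$rank_mode,
    positive_class = config$positive_class, cost = config$svm$cost)
  res_pdc <- select_and_classify_single(
    table, "PDC", n_max = min(config$selection$n_max, 380L),
    rank_mode = config$selection$rank_mode,
    positive_class = config$positive_class, cost = config$svm$cost)
  res_comb <- select_and_classify_combined(
    table, l_max = config$selection$l_max,
    rank_mode = config$selection$rank_mode,
    positive_class = config$positive_class, cost = config$svm$cost)
  results <- list(PLI = res_pli, PDC = res_pdc, combined = res_comb)
  log_stage(verbose, "classify", "three strategies (%.1f s)",
            as.numeric(Sys.time() - t0, units = "secs"))

  best_name <- names(results)[order(
    -vapply(results, `[[`, 1, "acc"),
    vapply(results, `[[`, 1, "n_features"))][1]
  best <- results[[best_name]]
  sel_values <- table$values[, best$selection$feature_cols, drop = FALSE]
  perm <- modified_permutation_test(
    sel_values, table$labels, n_perm = config$stats$n_perm_classifier,
    positive_class = config$positive_class, cost = config$svm$cost)
  comparison <- compare_selected_features(
    sel_values, table$labels, alpha_fdr = config$stats$fdr_q,
    positive_class = config$positive_class)
  log_stage(verbose, "stats", "permutation p = %.4g", perm$p_value)

  performance <- data.frame(
    feature_set = names(results),
    acc = vapply(results, `[[`, 1, "acc"),
    spe = vapply(results, `[[`, 1, "spe"),
    sen = vapply(results, `[[`, 1, "sen"),
    auc = vapply(results, `[[`, 1, "auc"),
    n_features = vapply(results, `[[`, 1, "n_features"),
    row.names = NULL
  )
  report <- structure(
    list(cluster_test = cluster, tf_maps = tf_maps, feature_table = table,
         results = results, best = best_name, performance = performance,
         perm_test = perm, feature_comparison = comparison, order = order_p,
         config = config),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$performance,
                     file.path(out_dir, "performance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$feature_comparison,
                     file.path(out_dir, "selected_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ft <- data.frame(subject_id = report$feature_table$subject_ids,
                   group = as.character(report$feature_table$labels),
                   report$feature_table$values, check.names = FALSE)
  utils::write.table(ft, file.path(out_dir, "feature_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$cluster_test)) {
    ct <- report$cluster_test
    summary <- data.frame(
      n_significant_clusters = length(ct$clusters),
      largest_significant = if (length(ct$clusters)) {
        max(vapply(ct$clusters, `[[`, 1L, "size"))
      } else 0L,
      critical_size = ct$crit_size)
    utils::write.table(summary, file.path(out_dir, "cluster_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- report$config
  cfg$mvar$p_range <- as.integer(cfg$mvar$p_range)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  MVAR order %d; best strategy: %s\n", x$order, x$best))
  print(x$performance, digits = 4)
  cat(sprintf("  permutation p of best strategy: %.4g\n", x$perm_test$p_value))
  if (!is.null(x$cluster_test)) {
    cat(sprintf("  %d significant time-frequency cluster(s)\n",
                length(x$cluster_test$clusters)))
  }
  invisible(x)
}
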