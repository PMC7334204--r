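#' Default pipeline configuration
#'
#' All analysis thresholds in one place: visit cell size 1000 m, summer
#' window coverage 0.95, minimum 11 active days retained (i.e.
#' participants active on 10 or fewer days removed), isopleth levels
#' 0.95/0.60, KDE grid 256 with reference bandwidth and minimum 5
#' distinct locations, k-means up to k = 5 with 25 restarts, silhouette
#' support threshold 0.5, log offset 0.001, master seed 1.
#'
#' @return Named list of defaults; override any element via the `config`
#'   argument of [run_all()].
#' @export
default_config <- function() {
  list(
    cell_size = 1000,
    coverage = 0.95,
    min_active_days = 11,
    levels = c(active = 0.95, core = 0.60),
    bandwidth = "href",
    grid_n = 256,
    min_points = 5,
    k_max = 5,
    n_restarts = 25,
    asw_support = 0.5,
    seed = 1,
    combined_pca = FALSE
  )
}

#' Run the full recorder-behaviour analysis
#'
#' load/accept records -> assign 1 km cells -> summer windows and rarity
#' ranking on the full dataset -> remove transient participants -> ten
#' metrics per participant -> behaviour axes (per-group PCAs) ->
#' k-means/SSI/ASW cluster scan per group -> reports. Deterministic
#' given the config seed.
#'
#' @param table a `record_table` (or path to a records CSV readable by
#'   [load_records()] with default column names).
#' @param config list of overrides to [default_config()].
#' @param out_dir optional directory; when given, writes `metrics.csv`,
#'   `axes_scores.csv`, `loadings.csv`, `clusters.json`,
#'   `filter_summary.json` and `run_log.txt` there.
#' @return List with `metrics`, `axes`, `correlations`, `scans`,
#'   `cluster_report`, `filter_summary`, `windows`, `rarity`, `log`
#'   (and `combined_pca` when enabled).
#' @export
run_all <- function(table, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(table)) table <- load_records(table)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("records: %d rows, %d participants", nrow(table),
      length(unique(table$participant_id)))
  table <- assign_cell(table, cell_size = cfg$cell_size)
  windows <- summer_windows(table, coverage = cfg$coverage)
  rarity <- rarity_table(table)
  flt <- filter_participants(table, min_active_days = cfg$min_active_days)
  fs <- flt$summary
  say("filter: %d/%d participants retained (%.1f%% removed), %d/%d records",
      fs$n_participants_retained, fs$n_participants_in,
      fs$pct_participants_removed, fs$n_records_retained, fs$n_records_in)
  metrics <- participant_metrics(flt$table, windows = windows,
                                 pool_table = table,
                                 cell_size = cfg$cell_size,
                                 bandwidth = cfg$bandwidth,
                                 grid_n = cfg$grid_n,
                                 min_points = cfg$min_points,
                                 levels = cfg$levels)
  for (g in names(metric_groups())) {
    n_inc <- sum(complete.cases(metrics[, metric_groups()[[g]], with = FALSE]))
    say("metrics: %s group complete for %d/%d participants", g, n_inc,
        nrow(metrics))
  }
  axes <- fit_axes(metrics)
  for (g in names(axes$var_explained)) {
    say("axes: %s PC1 explains %.1f%% of variation", g,
        axes$var_explained[[g]][1])
  }
  correlations <- axis_correlations(axes)
  scans <- lapply(setNames(nm = names(metric_groups())), function(g) {
    kmeans_scan(metrics, k_max = cfg$k_max, n_restarts = cfg$n_restarts,
                seed = cfg$seed + match(g, names(metric_groups())), group = g)
  })
  report <- cluster_support_report(scans)
  for (g in names(scans)) {
    say("clusters: %s best_k = %d, ASW = %.3f (%s)", g, scans[[g]]$best_k,
        scans[[g]]$asw,
        if (scans[[g]]$supported) "supported" else "not supported")
  }
  out <- list(metrics = metrics, axes = axes, correlations = correlations,
              scans = scans, cluster_report = report,
              filter_summary = fs, windows = windows, rarity = rarity,
              log = log_lines, config = cfg)
  if (isTRUE(cfg$combined_pca)) {
    out$combined_pca <- combined_pca(metrics)
    say("combined 10-metric PCA: first four components explain %.1f%%",
        sum(out$combined_pca$var_explained[1:4]))
  }
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  out
}

# optional output-only PCA across all ten metrics together; no
# orientation guarantees — the per-group analysis is the primary one
combined_pca <- function(metrics) {
  cols <- unlist(metric_groups())
  dt <- as.data.table(metrics)[, c("participant_id", cols), with = FALSE]
  dt <- dt[complete.cases(dt)]
  tm <- transform_metrics(dt)
  x <- as.matrix(tm[, cols, with = FALSE])
  rownames(x) <- tm$participant_id
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  list(loadings = p$rotation,
       var_explained = 100 * p$sdev^2 / sum(p$sdev^2),
       scores = p$x, n = nrow(x))
}

write_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(out$metrics, file.path(out_dir, "metrics.csv"))
  fwrite(out$axes$scores, file.path(out_dir, "axes_scores.csv"))
  write_loadings(out$axes, file.path(out_dir, "loadings.csv"))
  jsonlite::write_json(out$cluster_report,
                       file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$filter_summary,
                       file.path(out_dir, "filter_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Sensitivity of the analysis to the transient-participant threshold
#'
#' Reruns the pipeline removing participants active on `t` or fewer days
#' for each `t` in `thresholds`, and compares runs pairwise: participant
#' overlap, Spearman rank correlation of each axis over shared
#' participants, and best_k/ASW per metric group.
#'
#' @param table a `record_table`.
#' @param thresholds integer vector of removal thresholds (default
#'   `c(7, 10, 15)`).
#' @param config list of overrides to [default_config()].
#' @return List with `runs` (per threshold: filter summary, axes,
#'   scans), `pairwise` (`data.table` of threshold pairs x axes with
#'   `n_shared` and `rho`), and `cluster_table`.
#' @export
sensitivity <- function(table, thresholds = c(7, 10, 15), config = list()) {
  stopifnot(length(thresholds) >= 2)
  runs <- lapply(thresholds, function(t) {
    run_all(table, config = utils::modifyList(config,
                                              list(min_active_days = t + 1)))
  })
  names(runs) <- as.character(thresholds)
  axis_names <- names(axis_definitions())
  pairs <- utils::combn(seq_along(thresholds), 2)
  pw <- rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
    a <- runs[[pairs[1, i]]]$axes$scores
    b <- runs[[pairs[2, i]]]$axes$scores
    shared <- intersect(a$participant_id, b$participant_id)
    rbindlist(lapply(axis_names, function(ax) {
      av <- a[[ax]][match(shared, a$participant_id)]
      bv <- b[[ax]][match(shared, b$participant_id)]
      ok <- complete.cases(av, bv)
      rho <- if (sum(ok) >= 3L) {
        suppressWarnings(cor(av[ok], bv[ok], method = "spearman"))
      } else {
        NA_real_
      }
      data.table(threshold_a = thresholds[pairs[1, i]],
                 threshold_b = thresholds[pairs[2, i]],
                 axis = ax, n_shared = sum(ok), rho = rho)
    }))
  }))
  ct <- rbindlist(lapply(names(runs), function(t) {
    rbindlist(lapply(names(runs[[t]]$scans), function(g) {
      sc <- runs[[t]]$scans[[g]]
      data.table(threshold = as.integer(t), group = g,
                 best_k = sc$best_k, asw = sc$asw, supported = sc$supported)
    }))
  }))
  list(runs = runs, pairwise = pw[], cluster_table = ct[])
}
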