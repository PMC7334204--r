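#' Transform and standardise behaviour metrics
#'
#' Applies the skew-removing transform to the five right-skewed metrics
#' — `log10(x + 0.001)` for active area size, number of recording areas,
#' periodicity variation, periodicity and activity ratio (the 0.001
#' offset prevents large negative values at zero) — then centres every
#' metric column on its mean and divides by its sample standard
#' deviation (n - 1). Missing values are ignored when computing centres
#' and scales and propagate through.
#'
#' @param metrics data.frame/data.table of participant metrics (from
#'   [participant_metrics()] or equivalent); any column listed in
#'   `metric_groups()` is transformed, others pass through.
#' @return `data.table` of the same shape; attributes `centres`, `sds`
#'   and `log_offsets` (named vectors over the metric columns) record
#'   the transform for later projection.
#' @export
transform_metrics <- function(metrics) {
  dt <- as.data.table(metrics)
  cols <- intersect(unlist(metric_groups()), names(dt))
  logc <- intersect(log_transformed_metrics(), cols)
  for (cc in logc) {
    v <- dt[[cc]]
    if (any(v < 0, na.rm = TRUE)) stop("transform_metrics: negative values in ", cc)
    set(dt, j = cc, value = log10(v + 0.001))
  }
  centres <- sds <- setNames(numeric(length(cols)), cols)
  for (cc in cols) {
    v <- dt[[cc]]
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("transform_metrics: zero variance in column ", cc)
    }
    centres[cc] <- mu
    sds[cc] <- s
    set(dt, j = cc, value = (v - mu) / s)
  }
  offs <- setNames(ifelse(cols %in% logc, 0.001, NA_real_), cols)
  setattr(dt, "centres", centres)
  setattr(dt, "sds", sds)
  setattr(dt, "log_offsets", offs)
  dt[]
}

# transformed, scaled, complete-case matrix for one metric group;
# centres/scales are computed on the complete-case rows themselves so
# the PCA needs no further centring and one (centre, sd) pair per
# metric suffices for projection
group_matrix <- function(metrics, group) {
  cols <- metric_groups()[[group]]
  dt <- as.data.table(metrics)
  missing_cols <- setdiff(cols, names(dt))
  if (length(missing_cols) > 0L) {
    stop("group_matrix: metrics missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sub <- dt[, c("participant_id", cols), with = FALSE]
  cc <- complete.cases(sub)
  sub <- sub[cc]
  tm <- transform_metrics(sub)
  x <- as.matrix(tm[, cols, with = FALSE])
  rownames(x) <- tm$participant_id
  attr(x, "centres") <- attr(tm, "centres")
  attr(x, "sds") <- attr(tm, "sds")
  attr(x, "log_offsets") <- attr(tm, "log_offsets")
  attr(x, "n_dropped") <- sum(!cc)
  x
}

#' Principal components analysis of one metric group
#'
#' PCA (via singular value decomposition) of the transformed, scaled,
#' complete-case metrics of one group. Because every column is already
#' standardised, covariance- and correlation-based PCA coincide.
#'
#' @param metrics participant metrics table (raw scale; transformation
#'   is applied internally so that the stored centres/scales refer to
#'   exactly the rows entering the PCA).
#' @param group `"temporal"`, `"spatial"` or `"content"`.
#' @return List with `group`, `loadings` (metrics x components),
#'   `var_explained` (percentages, non-increasing, summing to 100),
#'   `scores` (participants x components), `centres`, `sds`,
#'   `log_offsets`, `n`, `n_dropped`.
#' @export
fit_group_pca <- function(metrics, group = c("temporal", "spatial", "content")) {
  group <- match.arg(group)
  x <- group_matrix(metrics, group)
  if (nrow(x) < 3L) stop("fit_group_pca: fewer than 3 complete rows for ", group)
  if (nrow(x) < ncol(x)) {
    stop("fit_group_pca: fewer complete rows than metrics for ", group)
  }
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(group = group,
       loadings = p$rotation,
       var_explained = ve,
       scores = p$x,
       centres = attr(x, "centres"),
       sds = attr(x, "sds"),
       log_offsets = attr(x, "log_offsets"),
       n = nrow(x),
       n_dropped = attr(x, "n_dropped"))
}

# component sign anchors making PCA orientation deterministic: each
# named axis is flipped, if needed, so the anchor metric loads positively
axis_definitions <- function() {
  list(
    recording_intensity = list(group = "temporal", component = 1L,
                               anchor = "activity_ratio"),
    spatial_extent = list(group = "spatial", component = 1L,
                          anchor = "active_area_size"),
    recording_potential = list(group = "content", component = 1L,
                               anchor = "proportion_taxa"),
    rarity_recording = list(group = "content", component = 2L,
                            anchor = "rarity_recording")
  )
}

#' Orient group PCAs into the four axes of participant behaviour
#'
#' PCA components are defined only up to sign. Orientation is fixed by
#' anchor metrics so the axes are deterministic and interpretable:
#' recording intensity (temporal PC1; activity ratio loads positively),
#' spatial extent (spatial PC1; active area size positive), recording
#' potential (content PC1; proportion of taxa positive) and rarity
#' recording (content PC2; the rarity recording metric positive).
#'
#' @param fragments named list of [fit_group_pca()] results for
#'   `temporal`, `spatial` and `content`.
#' @return An `axes_result`: list with oriented `pca` fragments,
#'   `var_explained` per group, and `scores` — a `data.table` of
#'   per-participant axis scores (participants missing any metric of a
#'   group get `NA` on that group's axes).
#' @export
orient_axes <- function(fragments) {
  defs <- axis_definitions()
  for (ax in names(defs)) {
    d <- defs[[ax]]
    fr <- fragments[[d$group]]
    if (is.null(fr)) stop("orient_axes: missing group PCA: ", d$group)
    lo <- fr$loadings[d$anchor, d$component]
    if (lo == 0) stop("orient_axes: zero loading of anchor ", d$anchor,
                      " on ", d$group, " component ", d$component,
                      "; cannot orient")
    if (lo < 0) {
      fragments[[d$group]]$loadings[, d$component] <-
        -fragments[[d$group]]$loadings[, d$component]
      fragments[[d$group]]$scores[, d$component] <-
        -fragments[[d$group]]$scores[, d$component]
    }
  }
  ids <- sort(unique(unlist(lapply(fragments, function(f) rownames(f$scores)))))
  scores <- data.table(participant_id = ids)
  for (ax in names(defs)) {
    d <- defs[[ax]]
    s <- fragments[[d$group]]$scores[, d$component]
    set(scores, j = ax,
        value = s[match(ids, rownames(fragments[[d$group]]$scores))])
  }
  structure(list(pca = fragments,
                 var_explained = lapply(fragments, `[[`, "var_explained"),
                 scores = scores[]),
            class = "axes_result")
}

#' Fit the four axes of participant behaviour
#'
#' Runs the three per-group PCAs on a participant metrics table and
#' orients them (see [orient_axes()]). Carries `n_records` per
#' participant into the scores table when present, for correlation
#' analyses against contribution volume.
#'
#' @param metrics participant metrics table from
#'   [participant_metrics()].
#' @return An `axes_result`; see [orient_axes()].
#' @export
fit_axes <- function(metrics) {
  fragments <- lapply(setNames(nm = names(metric_groups())),
                      function(g) fit_group_pca(metrics, g))
  res <- orient_axes(fragments)
  dt <- as.data.table(metrics)
  if ("n_records" %in% names(dt)) {
    res$scores <- merge(res$scores,
                        dt[, .(participant_id, n_records)],
                        by = "participant_id", all.x = TRUE, sort = TRUE)
  }
  res
}

#' @export
print.axes_result <- function(x, ...) {
  cat("Axes of participant behaviour\n")
  for (g in names(x$var_explained)) {
    ve <- x$var_explained[[g]]
    cat(sprintf("  %-8s PCA (n = %d): %s\n", g, x$pca[[g]]$n,
                paste(sprintf("PC%d %.1f%%", seq_along(ve), ve),
                      collapse = ", ")))
  }
  cat(sprintf("  %d participants scored\n", nrow(x$scores)))
  invisible(x)
}

#' Write reference loadings, centres and scales to CSV
#'
#' The file contains everything needed to place new participants on the
#' axes fitted here (see [project_axes()]): one row per group x metric x
#' component with the oriented loading, plus the metric's centre, scale
#' and log offset.
#'
#' @param axes an `axes_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(axes, path) {
  rows <- list()
  for (g in names(axes$pca)) {
    fr <- axes$pca[[g]]
    for (j in seq_len(ncol(fr$loadings))) {
      rows[[length(rows) + 1L]] <- data.table(
        group = g,
        metric = rownames(fr$loadings),
        component = j,
        loading = fr$loadings[, j],
        centre = fr$centres[rownames(fr$loadings)],
        sd = fr$sds[rownames(fr$loadings)],
        log_offset = fr$log_offsets[rownames(fr$loadings)]
      )
    }
  }
  fwrite(rbindlist(rows), path)
  invisible(path)
}

#' Read a reference loadings file
#' @param path CSV written by [write_loadings()].
#' @return Reference list usable by [project_axes()].
#' @export
read_loadings <- function(path) {
  dt <- fread(path)
  ref <- list(pca = list())
  for (g in unique(dt$group)) {
    sub <- dt[group == g]
    metrics <- unique(sub$metric)
    k <- max(sub$component)
    lo <- matrix(NA_real_, length(metrics), k,
                 dimnames = list(metrics, paste0("PC", seq_len(k))))
    for (j in seq_len(k)) {
      sj <- sub[component == j]
      lo[sj$metric, j] <- sj$loading
    }
    one <- sub[component == 1L]
    ref$pca[[g]] <- list(group = g, loadings = lo,
                         centres = setNames(one$centre, one$metric),
                         sds = setNames(one$sd, one$metric),
                         log_offsets = setNames(one$log_offset, one$metric))
  }
  ref
}

#' Project new participants onto reference axes
#'
#' Applies a previously fitted transform (log offsets, centres, scales)
#' and the oriented loadings to a new metrics table, without refitting —
#' the mechanism for comparing participants across studies on a common
#' set of axes.
#'
#' @param new_metrics participant metrics table (raw scale).
#' @param reference an `axes_result` from [fit_axes()] or the list from
#'   [read_loadings()].
#' @return `data.table` of axis scores for the new participants
#'   (complete-case per group, as in fitting).
#' @export
project_axes <- function(new_metrics, reference) {
  dt <- as.data.table(new_metrics)
  defs <- axis_definitions()
  ids <- sort(unique(as.character(dt$participant_id)))
  out <- data.table(participant_id = ids)
  for (ax in names(defs)) {
    d <- defs[[ax]]
    fr <- reference$pca[[d$group]]
    if (is.null(fr)) stop("project_axes: reference lacks group ", d$group)
    metrics <- rownames(fr$loadings)
    missing_cols <- setdiff(metrics, names(dt))
    if (length(missing_cols) > 0L) {
      stop("project_axes: new metrics missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    x <- as.matrix(dt[, metrics, with = FALSE])
    rownames(x) <- dt$participant_id
    for (m in metrics) {
      if (!is.na(fr$log_offsets[m])) x[, m] <- log10(x[, m] + fr$log_offsets[m])
      x[, m] <- (x[, m] - fr$centres[m]) / fr$sds[m]
    }
    s <- as.vector(x %*% fr$loadings[, d$component])
    set(out, j = ax, value = s[match(ids, rownames(x))])
  }
  out[]
}

#' Correlations among the axes and with contribution volume
#'
#' Pearson correlations (with two-sided p-values) for every pair of
#' axes, and for each axis against `log10(n_records)`. The recording
#' potential x rarity recording pair is flagged as orthogonal by
#' construction when both come from the same content PCA fit.
#'
#' @param axes an `axes_result` whose scores include `n_records`.
#' @return `data.table` with `var1`, `var2`, `r`, `p`, `n`,
#'   `orthogonal_by_construction`.
#' @export
axis_correlations <- function(axes) {
  sc <- as.data.table(axes$scores)
  axis_names <- names(axis_definitions())
  vars <- intersect(axis_names, names(sc))
  if ("n_records" %in% names(sc)) {
    sc[, log10_n_records := log10(n_records)]
    vars <- c(vars, "log10_n_records")
  }
  pairs <- utils::combn(vars, 2)
  rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ok <- complete.cases(sc[[v1]], sc[[v2]])
    if (sum(ok) < 3L) {
      return(data.table(var1 = v1, var2 = v2, r = NA_real_, p = NA_real_,
                        n = sum(ok), orthogonal_by_construction = FALSE))
    }
    ct <- cor.test(sc[[v1]][ok], sc[[v2]][ok])
    data.table(var1 = v1, var2 = v2,
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               orthogonal_by_construction =
                 setequal(c(v1, v2), c("recording_potential", "rarity_recording")))
  }))[]
}

#' Refit the behaviour axes from a published per-participant metrics CSV
#'
#' Reads a CSV of per-participant metric values (for example the
#' anonymised metrics distributed alongside a study), maps its columns
#' onto the ten canonical metric names, and refits the per-group PCAs
#' with the standard transform and scaling. Useful for reproducing a
#' study's variance-explained percentages and for obtaining reference
#' loadings without access to the raw records.
#'
#' @param path CSV path; must contain the ten metric columns (any
#'   naming, via `column_map`) and optionally a participant identifier
#'   and record count.
#' @param column_map named character vector mapping canonical metric
#'   names to file columns; defaults to identical names.
#' @return An `axes_result`.
#' @export
axes_from_metrics <- function(path, column_map = NULL) {
  dt <- fread(path)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (!column_map[[canon]] %in% names(dt)) {
        stop("axes_from_metrics: column not in file: ", column_map[[canon]])
      }
      setnames(dt, column_map[[canon]], canon)
    }
  }
  needed <- unlist(metric_groups())
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols) > 0L) {
    stop("axes_from_metrics: metrics file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"participant_id" %in% names(dt)) {
    dt[, participant_id := sprintf("row%06d", .I)]
  }
  fit_axes(dt)
}
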