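#' The ten behaviour metrics for every participant
#'
#' Convenience wrapper combining the temporal, spatial and data-content
#' metric sets, plus record and active-day counts, into one table with a
#' row per participant.
#'
#' Temporal metrics are computed inside summer windows; spatial and
#' content metrics use all of a participant's records. Windows and the
#' rarity ranking should come from the full dataset when `table` has
#' been filtered — pass them via `windows` / `pool_table`.
#'
#' @param table a `record_table`; `cell_id` is assigned (1 km) if
#'   missing.
#' @param windows summer windows from the full dataset ([summer_windows()]);
#'   computed from `table` if `NULL`.
#' @param pool_table full dataset defining taxon pool and rarity
#'   ranking; defaults to `table`.
#' @param region optional region restriction for content metrics.
#' @param cell_size visit grid cell size in metres (default 1000).
#' @param ... passed to [spatial_metrics()] (bandwidth, grid resolution,
#'   minimum points).
#' @return `data.table`, one row per participant: identifier, the ten
#'   metrics, `n_records` and `n_active_days`.
#' @export
participant_metrics <- function(table, windows = NULL, pool_table = NULL,
                                region = NULL, cell_size = 1000, ...) {
  dt <- as.data.table(table)
  if (!"cell_id" %in% names(dt)) {
    dt <- assign_cell(restore_record_table(dt, table), cell_size = cell_size)
  }
  counts <- dt[, .(n_records = .N, n_active_days = uniqueN(obs_date)),
               by = participant_id]
  tm <- temporal_metrics(dt, windows = windows)
  sm <- spatial_metrics_all(dt, ...)
  cm <- content_metrics(dt, pool_table = pool_table, region = region)
  out <- Reduce(function(a, b) merge(a, b, by = "participant_id", all = TRUE),
                list(counts, tm, sm, cm))
  setcolorder(out, c("participant_id",
                     "activity_ratio", "weekly_activity", "periodicity",
                     "periodicity_variation",
                     "active_area_size", "n_recording_areas",
                     "spatial_aggregation",
                     "proportion_taxa", "rarity_recording",
                     "single_species_lists",
                     "n_records", "n_active_days"))
  out[]
}

restore_record_table <- function(dt, orig) {
  setattr(dt, "crs", attr(orig, "crs"))
  setattr(dt, "provenance", attr(orig, "provenance"))
  if (!inherits(dt, "record_table")) {
    setattr(dt, "class", c("record_table", class(dt)))
  }
  dt
}

#' Metric grouping used by the axes and clustering analyses
#' @return Named list of character vectors: the temporal, spatial and
#'   content metric column names.
#' @export
metric_groups <- function() {
  list(
    temporal = c("activity_ratio", "weekly_activity", "periodicity",
                 "periodicity_variation"),
    spatial = c("active_area_size", "n_recording_areas",
                "spatial_aggregation"),
    content = c("proportion_taxa", "rarity_recording",
                "single_species_lists")
  )
}

# metrics that are log10(x + 0.001) transformed to remove skew
log_transformed_metrics <- function() {
  c("active_area_size", "n_recording_areas", "periodicity_variation",
    "periodicity", "activity_ratio")
}
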