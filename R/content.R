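#' Species rarity table
#'
#' Ranks taxa by their record count over the whole dataset (1 = most
#' recorded) and maps ranks linearly onto \[1, 100\]: the most-commonly
#' reported taxon gets rarity value 1, the most-rarely reported 100, with
#' step `99 / (S - 1)` for `S` taxa. Taxa tied on count share the mean of
#' their ranks' values.
#'
#' @param table a `record_table`.
#' @param region optional region restriction: a list
#'   `list(type = "polygon", x = ..., y = ...)` clipping the dataset to a
#'   polygon before counting (requires the mgcv package), or
#'   `list(type = "buffer", radius = r, centre = c(x, y))` keeping
#'   records within `r` metres of `centre`.
#' @return `data.table` with `taxon_id`, `n_records`, `rank`,
#'   `rarity_value`, sorted by descending count.
#' @export
rarity_table <- function(table, region = NULL) {
  dt <- clip_region(as.data.table(table), region)
  counts <- dt[, .(n_records = .N), by = taxon_id]
  s <- nrow(counts)
  if (s < 2L) stop("rarity_table: rarity is undefined with fewer than 2 taxa")
  counts[, rank := rank(-n_records, ties.method = "average")]
  counts[, rarity_value := 1 + 99 * (rank - 1) / (s - 1)]
  setorder(counts, -n_records, taxon_id)
  counts[]
}

clip_region <- function(dt, region) {
  if (is.null(region)) return(dt)
  if (identical(region$type, "polygon")) {
    if (!requireNamespace("mgcv", quietly = TRUE)) {
      stop("clip_region: polygon regions require the mgcv package")
    }
    inside <- mgcv::in.out(cbind(region$x, region$y), cbind(dt$x, dt$y))
    out <- dt[inside]
  } else if (identical(region$type, "buffer")) {
    out <- dt[sqrt((x - region$centre[1])^2 + (y - region$centre[2])^2) <= region$radius]
  } else {
    stop("clip_region: unknown region type: ", region$type)
  }
  if (nrow(out) == 0L) stop("clip_region: no records inside region")
  out
}

#' Proportion of taxa recorded
#'
#' The number of distinct taxa a participant has recorded, as a
#' proportion of the distinct taxa recorded by all participants (within
#' the region, if one is given).
#'
#' @inheritParams rarity_table
#' @param participant_id single participant identifier.
#' @return Fraction in (0, 1\].
#' @export
proportion_taxa <- function(table, participant_id, region = NULL) {
  pid <- participant_id
  dt <- clip_region(as.data.table(table), region)
  mine <- dt[participant_id == pid]
  if (nrow(mine) == 0L) stop("proportion_taxa: participant has no records (in region): ", pid)
  uniqueN(mine$taxon_id) / uniqueN(dt$taxon_id)
}

#' Rarity recording metric
#'
#' The median rarity value across all of the participant's records
#' (records, not distinct taxa) minus the median rarity value across all
#' records in the dataset. Positive values mean the participant records
#' rarer taxa more often than the project as a whole; negative values,
#' commoner taxa.
#'
#' @inheritParams proportion_taxa
#' @param rarity a rarity table from [rarity_table()]; computed from
#'   `table` if `NULL`.
#' @return Value in \[-99, 99\].
#' @export
rarity_recording <- function(table, participant_id, rarity = NULL, region = NULL) {
  pid <- participant_id
  dt <- clip_region(as.data.table(table), region)
  if (is.null(rarity)) rarity <- rarity_table(dt)
  rv <- rarity$rarity_value[match(dt$taxon_id, rarity$taxon_id)]
  mine <- rv[dt$participant_id == pid]
  if (length(mine) == 0L) stop("rarity_recording: participant has no records (in region): ", pid)
  median(mine, na.rm = TRUE) - median(rv, na.rm = TRUE)
}

#' Proportion of single-species lists
#'
#' The fraction of a participant's visits (unique participant x date x
#' 1 km cell combinations) on which exactly one record was submitted.
#' High values indicate one-off sightings; low values indicate fuller
#' site lists.
#'
#' @param visits visit table from [build_visits()] (any participants; it
#'   is subset internally).
#' @param participant_id single participant identifier.
#' @return Fraction in \[0, 1\].
#' @export
single_species_lists <- function(visits, participant_id) {
  pid <- participant_id
  v <- as.data.table(visits)[participant_id == pid]
  if (nrow(v) == 0L) stop("single_species_lists: participant has no visits: ", pid)
  mean(v$n_records == 1L)
}

#' All three data-content metrics for every participant
#'
#' @param table a `record_table` with `cell_id` assigned (the full
#'   dataset used for the species pool and rarity ranking may be passed
#'   as `pool_table` when `table` has been filtered).
#' @param pool_table `record_table` defining the taxon pool and rarity
#'   ranking; defaults to `table`.
#' @param region optional region restriction, see [rarity_table()].
#' @return `data.table` with `participant_id`, `proportion_taxa`,
#'   `rarity_recording`, `single_species_lists`.
#' @export
content_metrics <- function(table, pool_table = NULL, region = NULL) {
  dt <- as.data.table(table)
  pool <- if (is.null(pool_table)) dt else as.data.table(pool_table)
  pool <- clip_region(pool, region)
  rar <- rarity_table(pool)
  n_pool_taxa <- uniqueN(pool$taxon_id)
  pool_median <- median(rar$rarity_value[match(pool$taxon_id, rar$taxon_id)])
  visits <- build_visits(dt)
  dtc <- clip_region(dt, region)
  ids <- sort(unique(dt$participant_id))
  rbindlist(lapply(ids, function(id) {
    mine <- dtc[participant_id == id]
    if (nrow(mine) == 0L) {
      return(data.table(participant_id = id, proportion_taxa = NA_real_,
                        rarity_recording = NA_real_,
                        single_species_lists = single_species_lists(visits, id)))
    }
    rv <- rar$rarity_value[match(mine$taxon_id, rar$taxon_id)]
    data.table(
      participant_id = id,
      proportion_taxa = uniqueN(mine$taxon_id) / n_pool_taxa,
      rarity_recording = median(rv, na.rm = TRUE) - pool_median,
      single_species_lists = single_species_lists(visits, id)
    )
  }))[]
}
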