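#' @import data.table
#' @importFrom stats median sd quantile var prcomp dnorm rbeta rbinom rexp
#'   rnorm rpois runif complete.cases cor cor.test dist kmeans setNames
#'   aggregate
#' @importFrom utils head
NULL

#' Construct a record table from an in-memory data frame
#'
#' A record table is the package's canonical container for occurrence
#' records: one row per record with a participant identifier, a taxon
#' identifier, an observation date and a point location. Coordinates are
#' planar (metric) unless declared otherwise via `crs`.
#'
#' @param df data.frame with columns `participant_id`, `taxon_id`,
#'   `obs_date` (Date or ISO-8601 character), `x`, `y` and optionally
#'   `count`.
#' @param crs free-text coordinate reference tag. Anything containing
#'   "4326", "lonlat" or "longlat" is treated as geographic; everything
#'   else as metric (units of metres).
#' @return A `record_table`: a `data.table` with attributes `crs` and
#'   `provenance`.
#' @export
record_table <- function(df, crs = "metric") {
  req <- c("participant_id", "taxon_id", "obs_date", "x", "y")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("record_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dt <- as.data.table(df)
  if (!inherits(dt$obs_date, "Date")) dt[, obs_date := as.Date(as.character(obs_date))]
  dt[, participant_id := as.character(participant_id)]
  dt[, taxon_id := as.character(taxon_id)]
  n_in <- nrow(dt)
  keep <- !is.na(dt$obs_date) & is.finite(dt$x) & is.finite(dt$y) &
    !is.na(dt$participant_id) & nzchar(dt$participant_id) &
    !is.na(dt$taxon_id) & nzchar(dt$taxon_id)
  dt <- dt[keep]
  if (nrow(dt) == 0L) stop("record_table: no valid records")
  setattr(dt, "crs", crs)
  setattr(dt, "provenance",
          list(source = "<in-memory>", rows_read = n_in,
               rows_dropped = n_in - nrow(dt)))
  setattr(dt, "class", c("record_table", class(dt)))
  dt[]
}

#' Read occurrence records from a delimited text file
#'
#' Reads a CSV/TSV of occurrence records, maps its columns onto the
#' canonical schema, parses dates and drops (and counts) rows that fail
#' validation: unparseable dates, non-finite coordinates, or empty
#' participant/taxon identifiers.
#'
#' @param path path to a delimited text file (delimiter auto-detected by
#'   [data.table::fread()]).
#' @param column_map named character vector mapping canonical names to
#'   file columns; must name `participant`, `taxon`, `date`, `x`, `y`
#'   (optionally `count`). Defaults to identically named columns.
#' @param crs coordinate reference tag, see [record_table()].
#' @param date_format format string for [base::as.Date()]; default
#'   ISO-8601 `"%Y-%m-%d"`.
#' @return A `record_table`; its `provenance` attribute records the
#'   source path and the read/dropped row counts.
#' @export
load_records <- function(path,
                         column_map = c(participant = "participant_id",
                                        taxon = "taxon_id",
                                        date = "obs_date",
                                        x = "x", y = "y"),
                         crs = "metric",
                         date_format = "%Y-%m-%d") {
  if (!file.exists(path)) stop("load_records: file not found: ", path)
  needed <- c("participant", "taxon", "date", "x", "y")
  missing_map <- setdiff(needed, names(column_map))
  if (length(missing_map) > 0L) {
    stop("load_records: column_map must name: ", paste(missing_map, collapse = ", "))
  }
  header <- names(fread(path, nrows = 0L))
  absent <- setdiff(unname(column_map[needed]), header)
  if (length(absent) > 0L) {
    bad <- names(column_map)[match(absent, column_map)]
    stop("load_records: mapped column(s) not in file: ",
         paste(sprintf("%s (mapped from '%s')", absent, bad), collapse = ", "))
  }
  raw <- fread(path, colClasses = list(
    character = unname(column_map[c("participant", "taxon", "date")])))
  df <- data.table(
    participant_id = as.character(raw[[column_map[["participant"]]]]),
    taxon_id = as.character(raw[[column_map[["taxon"]]]]),
    obs_date = as.Date(as.character(raw[[column_map[["date"]]]]), format = date_format),
    x = as.numeric(raw[[column_map[["x"]]]]),
    y = as.numeric(raw[[column_map[["y"]]]])
  )
  if ("count" %in% names(column_map) && column_map[["count"]] %in% names(raw)) {
    df[, count := as.integer(raw[[column_map[["count"]]]])]
  }
  n_in <- nrow(df)
  keep <- !is.na(df$obs_date) & is.finite(df$x) & is.finite(df$y) &
    nzchar(df$participant_id) & nzchar(df$taxon_id) &
    !is.na(df$participant_id) & !is.na(df$taxon_id)
  dt <- df[keep]
  if (nrow(dt) == 0L) stop("load_records: zero valid records retained from ", path)
  message(sprintf("load_records: %d rows read, %d retained, %d dropped",
                  n_in, nrow(dt), n_in - nrow(dt)))
  setattr(dt, "crs", crs)
  setattr(dt, "provenance",
          list(source = path, rows_read = n_in, rows_dropped = n_in - nrow(dt)))
  setattr(dt, "class", c("record_table", class(dt)))
  dt[]
}

#' Write a record table to CSV in the canonical column order
#' @param table a `record_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(table, path) {
  cols <- intersect(c("participant_id", "taxon_id", "obs_date", "x", "y", "cell_id", "count"),
                    names(table))
  fwrite(as.data.table(table)[, cols, with = FALSE], path)
  invisible(path)
}

is_geographic_crs <- function(crs) {
  grepl("4326|lonlat|longlat|wgs84", tolower(crs %||% "metric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign grid-cell identifiers to records
#'
#' Snaps each record to the square grid cell containing it, by flooring
#' the planar coordinates: `cell = (floor(x / cell_size), floor(y /
#' cell_size))`. The default 1 km cells define the spatial component of a
#' visit.
#'
#' @param table a `record_table` with metric coordinates.
#' @param cell_size cell edge length in metres (default 1000).
#' @return The table with a `cell_id` character column (`"cx_cy"`).
#' @export
assign_cell <- function(table, cell_size = 1000) {
  if (is_geographic_crs(attr(table, "crs"))) {
    stop("assign_cell: coordinates are geographic (", attr(table, "crs"),
         "); project records to a metric CRS (e.g. a national transverse ",
         "Mercator grid) before assigning cells")
  }
  dt <- copy(as.data.table(table))
  dt[, cell_id := paste(floor(x / cell_size), floor(y / cell_size), sep = "_")]
  setattr(dt, "crs", attr(table, "crs"))
  setattr(dt, "provenance", attr(table, "provenance"))
  setattr(dt, "class", c("record_table", class(dt)))
  dt[]
}

#' Active days of a participant
#'
#' An active day is a calendar day on which the participant observed at
#' least one record (the observation date, not the submission date).
#'
#' @param table a `record_table`.
#' @param participant_id single participant identifier.
#' @return Sorted vector of distinct `Date`s; empty (with a warning) for
#'   an unknown participant.
#' @export
active_days <- function(table, participant_id) {
  pid <- participant_id
  d <- as.data.table(table)[participant_id == pid, obs_date]
  if (length(d) == 0L) {
    warning("active_days: participant not in table: ", pid)
    return(as.Date(character(0)))
  }
  sort(unique(d))
}

#' Remove transient participants
#'
#' Retains participants whose number of active days is at least
#' `min_active_days`. The default 11 removes participants active on 10 or
#' fewer days, for whom several metrics cannot be estimated reliably.
#'
#' @param table a `record_table`.
#' @param min_active_days minimum active-day count to retain (>= 1).
#' @return List with `table` (the retained `record_table`) and `summary`
#'   (participant/record counts and percentages removed).
#' @export
filter_participants <- function(table, min_active_days = 11) {
  stopifnot(min_active_days >= 1)
  dt <- as.data.table(table)
  act <- dt[, .(n_active_days = uniqueN(obs_date)), by = participant_id]
  keep_ids <- act[n_active_days >= min_active_days, participant_id]
  out <- dt[participant_id %in% keep_ids]
  if (nrow(out) == 0L) warning("filter_participants: no participants retained")
  summary <- list(
    min_active_days = min_active_days,
    n_participants_in = nrow(act),
    n_participants_retained = length(keep_ids),
    n_participants_removed = nrow(act) - length(keep_ids),
    pct_participants_removed = 100 * (nrow(act) - length(keep_ids)) / nrow(act),
    n_records_in = nrow(dt),
    n_records_retained = nrow(out),
    pct_records_removed = 100 * (nrow(dt) - nrow(out)) / nrow(dt)
  )
  setattr(out, "crs", attr(table, "crs"))
  setattr(out, "provenance", attr(table, "provenance"))
  setattr(out, "class", c("record_table", class(out)))
  list(table = out[], summary = summary)
}

#' Build visits from gridded records
#'
#' A visit is the unique combination of participant, observation date and
#' grid cell; it is the unit over which list-length metrics are defined.
#'
#' @param table a `record_table` with `cell_id` assigned (see
#'   [assign_cell()]).
#' @return `data.table` with one row per visit: `participant_id`,
#'   `obs_date`, `cell_id`, `n_records`, `n_taxa`.
#' @export
build_visits <- function(table) {
  dt <- as.data.table(table)
  if (!"cell_id" %in% names(dt)) {
    stop("build_visits: cell_id missing; run assign_cell() first")
  }
  dt[, .(n_records = .N, n_taxa = uniqueN(taxon_id)),
     by = .(participant_id, obs_date, cell_id)]
}
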