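#' Per-year summer recording windows
#'
#' Biological recording of many taxa (butterflies especially) is strongly
#' seasonal. Temporal metrics are therefore computed inside a per-year
#' "summer window": the day-of-year range containing the central
#' `coverage` fraction of all records made in that year, across all
#' participants. Without this, temporal metrics mostly reflect the time
#' of year a participant joined.
#'
#' The window bounds are the `(1 - coverage)/2` and `1 - (1 -
#' coverage)/2` empirical quantiles of day-of-year (inverse-CDF order
#' statistics, quantile type 1), rounded outward (floor/ceiling), which
#' guarantees the window contains at least the requested fraction of the
#' year's records.
#'
#' @param table a `record_table` (the full dataset; windows are a dataset
#'   property and are computed before participant filtering).
#' @param coverage central fraction of records each window must contain,
#'   in (0, 1]; default 0.95.
#' @return `data.frame` with columns `year`, `start_day`, `end_day`
#'   (day-of-year integers).
#' @export
summer_windows <- function(table, coverage = 0.95) {
  stopifnot(coverage > 0, coverage <= 1)
  dt <- as.data.table(table)
  if (nrow(dt) == 0L) stop("summer_windows: empty table")
  doy <- day_of_year(dt$obs_date)
  yr <- year_of(dt$obs_date)
  out <- lapply(sort(unique(yr)), function(y) {
    d <- doy[yr == y]
    if (length(d) < 2L) {
      warning("summer_windows: year ", y, " has < 2 records; window degenerates")
      return(data.frame(year = y, start_day = as.integer(min(d)),
                        end_day = as.integer(max(d))))
    }
    a <- (1 - coverage) / 2
    q <- quantile(d, c(a, 1 - a), type = 1, names = FALSE)
    data.frame(year = y,
               start_day = as.integer(max(1, floor(q[1]))),
               end_day = as.integer(min(366, ceiling(q[2]))))
  })
  do.call(rbind, out)
}

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

year_of <- function(dates) as.POSIXlt(dates)$year + 1900L

#' Which dates fall inside the summer windows
#' @param dates vector of `Date`s.
#' @param windows output of [summer_windows()].
#' @return logical vector; `FALSE` for dates in years with no window.
#' @export
in_window <- function(dates, windows) {
  doy <- day_of_year(dates)
  yr <- year_of(dates)
  i <- match(yr, windows$year)
  !is.na(i) & doy >= windows$start_day[i] & doy <= windows$end_day[i]
}

#' Activity ratio
#'
#' The proportion of days on which a participant was active, relative to
#' the days they remained linked to the project. Both numerator and
#' denominator count only days inside summer windows: the numerator is
#' the number of in-window active days, the denominator the number of
#' in-window calendar days between the first and last in-window active
#' day (inclusive, so a single active day gives ratio 1).
#'
#' @param days the participant's active days (`Date` vector).
#' @param windows output of [summer_windows()].
#' @return Fraction in (0, 1], or `NA` (with a warning) if no active day
#'   falls inside a window.
#' @export
activity_ratio <- function(days, windows) {
  act <- sort(unique(days))
  act <- act[in_window(act, windows)]
  if (length(act) == 0L) {
    warning("activity_ratio: no active days inside summer windows")
    return(NA_real_)
  }
  span_days <- seq(min(act), max(act), by = "day")
  span <- sum(in_window(span_days, windows))
  length(act) / span
}

#' Weekly activity
#'
#' The median number of active days per week, over the ISO-8601 weeks in
#' which the participant was active at all (so periods of absence do not
#' dilute it). Computed on in-window active days.
#'
#' @inheritParams activity_ratio
#' @return Days per week in \[1, 7\], or `NA` if no in-window active day.
#' @export
weekly_activity <- function(days, windows) {
  act <- sort(unique(days))
  act <- act[in_window(act, windows)]
  if (length(act) == 0L) return(NA_real_)
  wk <- format(act, "%G-%V")
  median(as.numeric(table(wk)))
}

within_year_gaps <- function(days, windows) {
  act <- sort(unique(days))
  act <- act[in_window(act, windows)]
  if (length(act) == 0L) return(numeric(0))
  unlist(lapply(split(act, year_of(act)), function(d) {
    if (length(d) < 2L) numeric(0) else as.numeric(diff(sort(d)))
  }), use.names = FALSE)
}

#' Periodicity
#'
#' The median gap, in days, between consecutive active days within a
#' summer. Gaps never span years: years with a single in-window active
#' day contribute nothing. Gaps are pooled across years before taking
#' the median.
#'
#' @inheritParams activity_ratio
#' @return Median gap in days (>= 1), or `NA` if no within-year gap
#'   exists.
#' @export
periodicity <- function(days, windows) {
  g <- within_year_gaps(days, windows)
  if (length(g) == 0L) return(NA_real_)
  median(g)
}

#' Periodicity variation
#'
#' The sample standard deviation (n - 1 denominator) of the same pooled
#' within-summer gaps used by [periodicity()].
#'
#' @inheritParams activity_ratio
#' @return SD of gaps in days (>= 0), or `NA` with fewer than two gaps.
#' @export
periodicity_variation <- function(days, windows) {
  g <- within_year_gaps(days, windows)
  if (length(g) < 2L) return(NA_real_)
  sd(g)
}

#' All four temporal metrics for every participant
#'
#' @param table a `record_table`.
#' @param windows output of [summer_windows()]; computed from `table`
#'   itself if `NULL` (pass windows from the full, unfiltered dataset
#'   when `table` has been filtered).
#' @return `data.table` with columns `participant_id`, `activity_ratio`,
#'   `weekly_activity`, `periodicity`, `periodicity_variation`.
#' @export
temporal_metrics <- function(table, windows = NULL) {
  dt <- as.data.table(table)
  if (is.null(windows)) windows <- summer_windows(dt)
  ids <- sort(unique(dt$participant_id))
  res <- rbindlist(lapply(ids, function(id) {
    days <- unique(dt[participant_id == id, obs_date])
    data.table(
      participant_id = id,
      activity_ratio = suppressWarnings(activity_ratio(days, windows)),
      weekly_activity = weekly_activity(days, windows),
      periodicity = periodicity(days, windows),
      periodicity_variation = periodicity_variation(days, windows)
    )
  }))
  res[]
}
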