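# brute-force reference implementations, written independently of the
# package internals (loops and first-principles arithmetic only); used
# to freeze expected values and for the randomized oracle comparison

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# inverse-CDF empirical quantile (type 1), written out longhand
oracle_quantile1 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  v[max(1, ceiling(n * p))]
}

oracle_summer_window <- function(doys, coverage = 0.95) {
  a <- (1 - coverage) / 2
  c(start = max(1, floor(oracle_quantile1(doys, a))),
    end = min(366, ceiling(oracle_quantile1(doys, 1 - a))))
}

oracle_doy <- function(d) as.integer(strftime(d, "%j"))

oracle_in_window <- function(d, windows) {
  y <- as.integer(strftime(d, "%Y"))
  doy <- oracle_doy(d)
  any(windows$year == y & windows$start_day <= doy & windows$end_day >= doy)
}

oracle_activity_ratio <- function(dates, windows) {
  act <- unique(dates[vapply(dates, oracle_in_window, logical(1), windows)])
  if (length(act) == 0) return(NA_real_)
  span <- 0
  for (d in seq(min(act), max(act), by = "day")) {
    if (oracle_in_window(as.Date(d, origin = "1970-01-01"), windows)) {
      span <- span + 1
    }
  }
  length(act) / span
}

# ISO-8601 week label computed from first principles: the ISO week of a
# date is determined by the Thursday of its Mon-Sun week
oracle_iso_week <- function(d) {
  wd <- as.POSIXlt(d)$wday          # 0 = Sunday
  wd <- ifelse(wd == 0, 7, wd)      # 1 = Monday .. 7 = Sunday
  thu <- d + (4 - wd)
  yr <- as.integer(strftime(thu, "%Y"))
  jan1 <- as.Date(sprintf("%d-01-01", yr))
  sprintf("%d-W%02d", yr, 1 + as.integer(thu - jan1) %/% 7)
}

oracle_weekly_activity <- function(dates, windows) {
  act <- unique(dates[vapply(dates, oracle_in_window, logical(1), windows)])
  if (length(act) == 0) return(NA_real_)
  wk <- vapply(act, oracle_iso_week, character(1))
  oracle_median(as.numeric(table(wk)))
}

oracle_gaps <- function(dates, windows) {
  act <- sort(unique(dates[vapply(dates, oracle_in_window, logical(1), windows)]))
  gaps <- numeric(0)
  for (y in unique(as.integer(strftime(act, "%Y")))) {
    dy <- act[as.integer(strftime(act, "%Y")) == y]
    if (length(dy) >= 2) {
      for (i in 2:length(dy)) gaps <- c(gaps, as.numeric(dy[i] - dy[i - 1]))
    }
  }
  gaps
}

oracle_periodicity <- function(dates, windows) {
  g <- oracle_gaps(dates, windows)
  if (length(g) == 0) NA_real_ else oracle_median(g)
}

oracle_periodicity_variation <- function(dates, windows) {
  g <- oracle_gaps(dates, windows)
  if (length(g) < 2) return(NA_real_)
  m <- sum(g) / length(g)
  sqrt(sum((g - m)^2) / (length(g) - 1))
}

# rarity values by enumerating taxa sorted by count; ties share mean of
# the tied ranks' values
oracle_rarity_values <- function(taxa) {
  counts <- sort(table(taxa), decreasing = TRUE)
  s <- length(counts)
  vals <- 1 + 99 * (seq_len(s) - 1) / (s - 1)
  out <- numeric(s)
  names(out) <- names(counts)
  i <- 1
  while (i <= s) {
    j <- i
    while (j < s && counts[j + 1] == counts[i]) j <- j + 1
    out[i:j] <- sum(vals[i:j]) / (j - i + 1)
    i <- j + 1
  }
  out
}

oracle_proportion_taxa <- function(tab, pid) {
  mine <- unique(tab$taxon_id[tab$participant_id == pid])
  length(mine) / length(unique(tab$taxon_id))
}

oracle_rarity_recording <- function(tab, pid) {
  rv <- oracle_rarity_values(tab$taxon_id)
  all_vals <- rv[tab$taxon_id]
  mine <- all_vals[tab$participant_id == pid]
  unname(oracle_median(mine) - oracle_median(all_vals))
}

oracle_single_species_lists <- function(tab, pid, cell_size = 1000) {
  mine <- tab[tab$participant_id == pid, ]
  key <- paste(as.character(mine$obs_date),
               floor(mine$x / cell_size), floor(mine$y / cell_size))
  n_single <- 0
  for (k in unique(key)) if (sum(key == k) == 1) n_single <- n_single + 1
  n_single / length(unique(key))
}
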