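# in-code fixtures shared across test files

# quick record_table builder; dates as strings, coords in metres
make_records <- function(participant, taxon, date, x = 0, y = 0) {
  record_table(data.frame(
    participant_id = participant, taxon_id = taxon,
    obs_date = as.Date(date), x = x, y = y,
    stringsAsFactors = FALSE))
}

# windows covering the whole year(s), for tests that do not exercise the
# seasonal windowing itself
full_windows <- function(years) {
  data.frame(year = years, start_day = 1L, end_day = 366L)
}

# a small random record set (<= max_records rows) with a handful of
# participants, taxa, days and cells
random_tiny_records <- function(seed, max_records = 30) {
  set.seed(seed)
  n <- sample(5:max_records, 1)
  make_records(
    participant = sprintf("p%d", sample(1:4, n, replace = TRUE)),
    taxon = sprintf("t%d", sample(1:6, n, replace = TRUE)),
    date = as.Date("2015-05-01") + sample(0:120, n, replace = TRUE),
    x = runif(n, 0, 5000),
    y = runif(n, 0, 5000))
}

# isotropic Gaussian point cloud in metres
gaussian_points <- function(n, sd_m = 1000, centre = c(0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(x = rnorm(n, centre[1], sd_m), y = rnorm(n, centre[2], sd_m))
}
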