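test_that("summer_windows matches the outward-rounded quantile construction", {
  # one record per day on days 1..100 -> central 95% window [3, 98]
  tab <- make_records(rep("p1", 100), "t1",
                      as.Date("2015-01-01") + 0:99)
  w <- summer_windows(tab)
  expect_equal(w$start_day, 3)
  expect_equal(w$end_day, 98)
  expect_equal(unname(oracle_summer_window(1:100)), c(3, 98))

  # heavy interior mass: days {100 x20, 150 x60, 200 x20} -> [100, 200]
  doys <- rep(c(100, 150, 200), c(20, 60, 20))
  tab2 <- make_records(rep("p1", 100), "t1",
                       as.Date("2015-01-01") + doys - 1)
  w2 <- summer_windows(tab2)
  expect_equal(c(w2$start_day, w2$end_day),
               unname(oracle_summer_window(doys)))
  expect_equal(c(w2$start_day, w2$end_day), c(100, 200))

  # all records on one day degenerate to that day
  tab3 <- make_records(rep("p1", 5), "t1", rep("2015-06-29", 5))
  w3 <- summer_windows(tab3)
  expect_equal(w3$start_day, w3$end_day)
  expect_equal(w3$start_day, 180)

  # windows truly contain >= coverage of records, per year
  set.seed(21)
  tab4 <- make_records(rep("p1", 400), "t1",
                       as.Date("2014-01-01") +
                         sample(0:1400, 400, replace = TRUE))
  w4 <- summer_windows(tab4, coverage = 0.9)
  inw <- in_window(tab4$obs_date, w4)
  for (y in w4$year) {
    yy <- as.POSIXlt(tab4$obs_date)$year + 1900 == y
    expect_gte(mean(inw[yy]), 0.9)
  }
})

test_that("activity_ratio counts in-window days between first and last active day", {
  w <- full_windows(2015)
  # active every day between first and last -> 1
  expect_equal(activity_ratio(as.Date("2015-06-01") + 0:9, w), 1)
  # single active day -> 1 (span is inclusive)
  expect_equal(activity_ratio(as.Date("2015-06-01"), w), 1)
  # two active days ten window-days apart -> 2/10
  expect_equal(activity_ratio(as.Date("2015-06-01") + c(0, 9), w), 0.2)
  # no in-window active day -> NA with warning
  w_aug <- data.frame(year = 2015, start_day = 213, end_day = 244)
  expect_warning(r <- activity_ratio(as.Date("2015-06-01"), w_aug))
  expect_true(is.na(r))
})

test_that("activity_ratio excludes days outside summer windows from both sides", {
  # windows: days 152-181 each of 2015 and 2016 (June)
  w <- data.frame(year = c(2015, 2016), start_day = 152, end_day = 181)
  # active June 1 2015 and June 30 2016: span = 30 + 30 in-window days
  days <- as.Date(c("2015-06-01", "2016-06-29"))
  expect_equal(activity_ratio(days, w), 2 / 60)
  # records outside windows are invisible to the metric
  days2 <- c(days, as.Date(c("2015-12-25", "2016-01-01")))
  expect_equal(activity_ratio(days2, w), 2 / 60)
  expect_equal(activity_ratio(days2, w), oracle_activity_ratio(days2, w))
})

test_that("weekly_activity is the median over active ISO weeks", {
  w <- full_windows(2015)
  expect_equal(weekly_activity(as.Date("2015-06-03"), w), 1)
  # 14 consecutive days aligned Mon-Sun twice -> {7, 7} -> 7
  expect_equal(weekly_activity(as.Date("2015-06-29") + 0:13, w), 7)
  # weeks with {2, 1} active days -> 1.5
  days <- as.Date(c("2015-06-29", "2015-06-30", "2015-07-08"))
  expect_equal(weekly_activity(days, w), 1.5)
  expect_equal(weekly_activity(days, w), oracle_weekly_activity(days, w))
})

test_that("periodicity pools within-year gaps and never spans years", {
  w <- full_windows(2014:2017)
  # constant gaps {2,2,2} -> 2
  expect_equal(periodicity(as.Date("2015-06-01") + c(0, 2, 4, 6), w), 2)
  # year 1 gaps {2}, year 2 single day contributes nothing -> 2
  days <- as.Date(c("2015-06-10", "2015-06-12", "2016-02-19"))
  expect_equal(periodicity(days, w), 2)
  # one active day per year over 3 years -> no gaps -> NA, not 0
  lonely <- as.Date(c("2014-06-01", "2015-06-01", "2016-06-01"))
  expect_true(is.na(periodicity(lonely, w)))
  expect_true(is.na(periodicity_variation(lonely, w)))
})

test_that("periodicity_variation is the sample SD of pooled gaps", {
  w <- full_windows(2015)
  expect_equal(periodicity_variation(as.Date("2015-06-01") + c(0, 2, 4, 6), w), 0)
  # gaps {1, 3} -> sd = sqrt(2)
  days <- as.Date("2015-06-01") + c(0, 1, 4)
  expect_equal(periodicity_variation(days, w), sqrt(2), tolerance = 1e-12)
  # single gap -> NA
  expect_true(is.na(periodicity_variation(as.Date("2015-06-01") + c(0, 3), w)))
})

test_that("temporal metrics are invariant to duplicates and whole-year shifts", {
  set.seed(31)
  days <- sort(sample(as.Date("2015-05-01") + 0:120, 25))
  tab <- make_records(rep("p1", 50), "t1", rep(days, 2))
  w <- summer_windows(tab)
  m <- temporal_metrics(tab, w)
  # duplicate records on the same day do not change any metric
  m1 <- temporal_metrics(make_records(rep("p1", 25), "t1", days), w)
  expect_equal(m, m1)
  # shifting all dates one year on (by 52 weeks, keeping weekday
  # alignment; windows recomputed) is neutral
  base <- make_records(rep("p1", 25), "t1", days)
  m <- temporal_metrics(base, summer_windows(base))
  shifted <- make_records(rep("p1", 25), "t1", days + 364)
  m2 <- temporal_metrics(shifted, summer_windows(shifted))
  expect_equal(m$activity_ratio, m2$activity_ratio)
  expect_equal(m$weekly_activity, m2$weekly_activity)
  expect_equal(m$periodicity, m2$periodicity)
  expect_equal(m$periodicity_variation, m2$periodicity_variation)
})

test_that("activity_ratio recovers the daily activity probability of a Bernoulli recorder", {
  w <- data.frame(year = 2015, start_day = 1, end_day = 300)
  for (p in c(0.3, 0.7)) {
    set.seed(round(1000 * p))
    est <- replicate(40, {
      act <- as.Date("2014-12-31") + which(runif(300) < p)
      activity_ratio(act, w)
    })
    expect_lt(abs(mean(est, na.rm = TRUE) - p), 0.05)
  }
})
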