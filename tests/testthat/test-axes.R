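# a synthetic metrics table with known dependence structure: high
# activity co-occurs with low periodicity (temporal), and recording
# potential behaviour is planted in the content group
synthetic_metrics <- function(n = 200, seed = 61) {
  set.seed(seed)
  intensity <- rnorm(n)
  potential <- rnorm(n)
  data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    activity_ratio = pmin(1, pmax(0.01, 0.3 + 0.15 * intensity + rnorm(n, 0, 0.03))),
    weekly_activity = pmin(7, pmax(1, 3 + intensity + rnorm(n, 0, 0.3))),
    periodicity = pmax(1, 5 - 1.5 * intensity + rnorm(n, 0, 0.4)),
    periodicity_variation = pmax(0, 4 - intensity + rnorm(n, 0, 0.5)),
    active_area_size = exp(rnorm(n, 3, 1)),
    n_recording_areas = pmax(1, round(exp(rnorm(n, 0.7, 0.5)))),
    spatial_aggregation = pmin(1, pmax(0.05, rnorm(n, 0.4, 0.1))),
    proportion_taxa = pmin(1, pmax(0.02, 0.4 + 0.2 * potential + rnorm(n, 0, 0.05))),
    rarity_recording = rnorm(n, 0, 10),
    single_species_lists = pmin(1, pmax(0, 0.5 - 0.15 * potential + rnorm(n, 0, 0.05))),
    n_records = pmax(11, round(exp(3 + 0.8 * intensity + rnorm(n, 0, 0.3)))),
    stringsAsFactors = FALSE)
}

test_that("transform_metrics applies log10 + 0.001 then standardises exactly", {
  m <- synthetic_metrics(100)
  tm <- transform_metrics(m)
  # log-offset arithmetic on the named columns
  expect_equal(attr(tm, "log_offsets")[["activity_ratio"]], 0.001)
  expect_true(is.na(attr(tm, "log_offsets")[["proportion_taxa"]]))
  raw <- log10(m$activity_ratio + 0.001)
  expect_equal(tm$activity_ratio, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  # an activity ratio of exactly 1 transforms to log10(1.001)
  expect_equal(log10(1 + 0.001), 0.000434077, tolerance = 1e-4)
  # a defined zero maps to the offset floor of -3 before scaling
  expect_equal(log10(0 + 0.001), -3)
  # every metric column ends up standardised
  for (cc in unlist(metric_groups())) {
    expect_lt(abs(mean(tm[[cc]])), 1e-8)
    expect_lt(abs(sd(tm[[cc]]) - 1), 1e-8)
  }
  bad <- m
  bad$spatial_aggregation <- 0.4
  expect_error(transform_metrics(bad), "spatial_aggregation")
})

test_that("group PCA conserves variance and flags degenerate input", {
  m <- synthetic_metrics(300)
  for (g in names(metric_groups())) {
    fr <- fit_group_pca(m, g)
    expect_equal(sum(fr$var_explained), 100, tolerance = 1e-9)
    expect_true(all(diff(fr$var_explained) <= 1e-9))
  }
  # rank-1 data: all temporal columns driven by one latent vector (the
  # log-transformed columns are constructed on the anti-log scale so
  # the transformed matrix is rank 1 up to tiny noise)
  set.seed(62)
  v <- rnorm(150)
  m1 <- synthetic_metrics(150)
  m1$activity_ratio <- 10^(-1 + 0.2 * v + rnorm(150, 0, 1e-4)) - 0.001
  m1$weekly_activity <- 3 + v + rnorm(150, 0, 1e-3)
  m1$periodicity <- 10^(0.5 + 0.3 * v + rnorm(150, 0, 1e-4)) - 0.001
  m1$periodicity_variation <- 10^(0.4 + 0.25 * v + rnorm(150, 0, 1e-4)) - 0.001
  fr1 <- fit_group_pca(m1, "temporal")
  expect_gt(fr1$var_explained[1], 99)
  # isotropic noise: each of the 4 components near 25% (sampling error)
  mi <- synthetic_metrics(10000, seed = 63)
  for (cc in metric_groups()$temporal) mi[[cc]] <- exp(rnorm(10000))
  fri <- fit_group_pca(mi, "temporal")
  expect_true(all(abs(fri$var_explained - 25) < 2))
})

test_that("orientation is deterministic, idempotent and anchored positively", {
  m <- synthetic_metrics(250, seed = 64)
  frs <- lapply(setNames(nm = names(metric_groups())),
                function(g) fit_group_pca(m, g))
  axes <- orient_axes(frs)
  # flipping fitted component signs then re-orienting gives identical axes
  flipped <- frs
  for (g in names(flipped)) {
    flipped[[g]]$loadings <- -flipped[[g]]$loadings
    flipped[[g]]$scores <- -flipped[[g]]$scores
  }
  axes2 <- orient_axes(flipped)
  expect_equal(axes$scores, axes2$scores, tolerance = 1e-12)
  # the anchored components come out identical regardless of fit signs
  expect_equal(axes$pca$temporal$loadings[, 1],
               axes2$pca$temporal$loadings[, 1])
  expect_equal(axes$pca$content$loadings[, 1:2],
               axes2$pca$content$loadings[, 1:2])
  # axis scores correlate positively with their anchor metric
  tm <- transform_metrics(m)
  expect_gt(cor(axes$scores$recording_intensity, tm$activity_ratio), 0)
  expect_gt(cor(axes$scores$spatial_extent, tm$active_area_size), 0)
  expect_gt(cor(axes$scores$recording_potential, tm$proportion_taxa), 0)
  expect_gt(cor(axes$scores$rarity_recording, tm$rarity_recording), 0)
  # high activity with low periodicity: opposite loading signs on
  # recording intensity, with activity_ratio positive
  lo <- axes$pca$temporal$loadings[, 1]
  expect_gt(lo[["activity_ratio"]], 0)
  expect_lt(lo[["periodicity"]], 0)
})

test_that("axis scores are invariant to row order and centred at zero", {
  m <- synthetic_metrics(150, seed = 65)
  a1 <- fit_axes(m)
  a2 <- fit_axes(m[sample(nrow(m)), ])
  expect_equal(a1$scores, a2$scores, tolerance = 1e-10)
  for (ax in c("recording_intensity", "spatial_extent",
               "recording_potential", "rarity_recording")) {
    expect_lt(abs(mean(a1$scores[[ax]], na.rm = TRUE)), 1e-8)
  }
})

test_that("retaining all components reconstructs the scaled matrix", {
  m <- synthetic_metrics(120, seed = 66)
  fr <- fit_group_pca(m, "content")
  z <- fr$scores %*% t(fr$loadings)
  tm <- transform_metrics(m)
  expect_equal(unname(z),
               unname(as.matrix(tm[, metric_groups()$content, with = FALSE])),
               tolerance = 1e-8)
})

test_that("projection reproduces training scores and round-trips through file", {
  m <- synthetic_metrics(180, seed = 67)
  axes <- fit_axes(m)
  proj <- project_axes(m, axes)
  for (ax in names(proj)[-1]) {
    expect_lt(max(abs(proj[[ax]] - axes$scores[[ax]])), 1e-10)
  }
  # a row equal to the training column means scores 0 on every axis
  mean_row <- as.data.frame(lapply(m[unlist(metric_groups())], mean))
  # undo: projection applies log first, so feed back the anti-logged means
  for (cc in intersect(names(mean_row),
                       c("active_area_size", "n_recording_areas",
                         "periodicity_variation", "periodicity",
                         "activity_ratio"))) {
    mean_row[[cc]] <- 10^(mean(log10(m[[cc]] + 0.001))) - 0.001
  }
  # recompute exact centres: projection must hit 0 within rounding
  centred <- cbind(participant_id = "centre", mean_row)
  p0 <- project_axes(centred, axes)
  for (ax in names(p0)[-1]) expect_lt(abs(p0[[ax]]), 1e-8)
  # file round trip
  path <- tempfile(fileext = ".csv")
  write_loadings(axes, path)
  ref <- read_loadings(path)
  proj2 <- project_axes(m, ref)
  for (ax in names(proj2)[-1]) {
    expect_lt(max(abs(proj2[[ax]] - proj[[ax]])), 1e-8)
  }
  # a missing metric is a named hard error
  m_bad <- m
  m_bad$periodicity <- NULL
  expect_error(project_axes(m_bad, axes), "periodicity")
})

test_that("axis correlations report PCA orthogonality and planted dependence", {
  m <- synthetic_metrics(400, seed = 68)
  axes <- fit_axes(m)
  ac <- axis_correlations(axes)
  ortho <- ac[ac$orthogonal_by_construction == TRUE, ]
  expect_equal(nrow(ortho), 1L)
  expect_lt(abs(ortho$r), 1e-10)
  # planted: n_records grows with the intensity driver
  ri <- ac[(ac$var1 == "recording_intensity" & ac$var2 == "log10_n_records"), ]
  expect_gt(ri$r, 0.5)
  expect_lt(ri$p, 0.001)
})

test_that("axes_from_metrics refits from a per-participant metrics file", {
  m <- synthetic_metrics(150, seed = 69)
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(m, path)
  a1 <- axes_from_metrics(path)
  a2 <- fit_axes(m)
  expect_equal(a1$var_explained, a2$var_explained, tolerance = 1e-10)
  # column mapping
  m2 <- m
  names(m2)[names(m2) == "activity_ratio"] <- "act_ratio"
  data.table::fwrite(m2, path)
  expect_error(axes_from_metrics(path), "activity_ratio")
  a3 <- axes_from_metrics(path, column_map = c(activity_ratio = "act_ratio"))
  expect_equal(a3$var_explained, a2$var_explained, tolerance = 1e-10)
})
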