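#' Simple Structure Index of a k-means partition
#'
#' Composite index used to pick the number of clusters. For cluster
#' centres `c_kj` over standardised columns `j`, with column ranges
#' `r_j = max_k c_kj - min_k c_kj` and overall column spread `s_j`
#' (the standard deviation of column `j`), the index is the product of
#' three elements:
#'
#' * `a` — the proportion of columns that discriminate between clusters,
#'   i.e. with `r_j > s_j`;
#' * `b` — the mean, over those discriminating columns, of the
#'   normalised range `r_j / max_j r_j`;
#' * `c` — the evenness of cluster sizes, the smallest cluster's size
#'   divided by the largest's (so solutions that shave a genuine cluster
#'   into fragments are penalised).
#'
#' `ssi = a * b * c`, in \[0, 1\]; 0 if no column discriminates. Larger
#' values indicate a partition with few, strongly contrasting,
#' evenly-sized clusters.
#'
#' @param x numeric matrix (rows = participants, standardised columns).
#' @param labels integer cluster labels.
#' @return Single numeric value.
#' @export
simple_structure_index <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) return(0)
  centres <- t(vapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE]),
                      numeric(ncol(x))))
  r <- apply(centres, 2, function(v) max(v) - min(v))
  s <- apply(x, 2, sd)
  disc <- r > s
  if (!any(disc)) return(0)
  a <- mean(disc)
  b <- mean(r[disc] / max(r))
  sizes <- tabulate(match(labels, ks))
  c_even <- min(sizes) / max(sizes)
  a * b * c_even
}

# k-means++ seeding: first centre uniform, then each next centre drawn
# with probability proportional to squared distance to nearest chosen
kmeanspp_centres <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centres[1L, ] <- x[i, ]
  d2 <- colSums((t(x) - centres[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centres[j, ] <- x[i, ]
    d2 <- pmin(d2, colSums((t(x) - centres[j, ])^2))
  }
  centres
}

#' Average silhouette width of a partition
#'
#' Mean silhouette value over all points, with Euclidean distances
#' (via [cluster::silhouette()], which assigns silhouette 0 to points in
#' singleton clusters). Values below 0.5 are taken as evidence that the
#' clusters are not well supported.
#'
#' @param x numeric matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return Average silhouette width in \[-1, 1\].
#' @export
silhouette_width <- function(x, labels) {
  if (length(unique(labels)) < 2L) {
    stop("silhouette_width: need at least 2 clusters")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}

#' K-means scan with SSI selection and silhouette support
#'
#' Runs k-means for each `k` in `2..k_max` with `n_restarts` k-means++
#' initialisations (keeping the solution with the lowest within-cluster
#' sum of squares), scores each partition with the Simple Structure
#' Index and average silhouette width, and selects `best_k` as the `k`
#' maximising SSI. Support is judged by the ASW at `best_k`: below 0.5
#' the clusters are considered unsupported and the continuous axes the
#' better description.
#'
#' @param x numeric matrix of transformed group metrics (complete
#'   cases), or a metrics table plus `group` to build it.
#' @param k_max maximum number of clusters to consider (default 5).
#' @param n_restarts random initialisations per `k` (default 25).
#' @param seed integer seed making the scan reproducible.
#' @param group optional group name; if given, `x` is taken to be a raw
#'   metrics table and the transformed complete-case matrix for that
#'   group is built internally.
#' @return A `cluster_scan`: list with `per_k` (data.table of `k`,
#'   `ssi`, `asw`, `tot_withinss`), `labels` (list by `k`), `best_k`,
#'   `asw` (at `best_k`), `supported` (`asw >= 0.5`), `n`.
#' @export
kmeans_scan <- function(x, k_max = 5, n_restarts = 25, seed = 1,
                        group = NULL) {
  if (!is.null(group)) x <- group_matrix(x, group)
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (n_distinct < 2L) stop("kmeans_scan: all rows identical; clustering degenerate")
  if (nrow(x) < k_max + 1L) stop("kmeans_scan: need at least k_max + 1 rows")
  set.seed(seed)
  per_k <- list()
  labels <- list()
  for (k in 2:k_max) {
    if (k > n_distinct) {
      warning("kmeans_scan: k = ", k, " exceeds distinct rows; skipped")
      next
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- suppressWarnings(
        kmeans(x, centers = kmeanspp_centres(x, k), iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    labels[[as.character(k)]] <- best$cluster
    per_k[[as.character(k)]] <- data.table(
      k = k,
      ssi = simple_structure_index(x, best$cluster),
      asw = silhouette_width(x, best$cluster),
      tot_withinss = best$tot.withinss
    )
  }
  if (length(per_k) == 0L) stop("kmeans_scan: no feasible k")
  per_k <- rbindlist(per_k)
  best_k <- per_k$k[which.max(per_k$ssi)]
  structure(list(per_k = per_k[],
                 labels = labels,
                 best_k = best_k,
                 asw = per_k$asw[per_k$k == best_k],
                 supported = per_k$asw[per_k$k == best_k] >= 0.5,
                 n = nrow(x)),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("k-means scan (n = %d): best_k = %d, ASW = %.3f (%s)\n",
              x$n, x$best_k, x$asw,
              if (x$supported) "supported" else "not supported"))
  print(x$per_k)
  invisible(x)
}

#' Cluster-support report across metric groups
#'
#' Summarises per-group k-means scans: the SSI-selected number of
#' clusters, the average silhouette width at that `k`, and whether the
#' clustering is supported (ASW >= 0.5; exactly 0.5 counts as
#' supported). Where clustering is unsupported, participants are better
#' described by their positions along the continuous behaviour axes
#' than by discrete group membership.
#'
#' @param scans named list of `cluster_scan` objects (one per group).
#' @return List (JSON-ready): per group `best_k`, `asw`, `supported`
#'   and the per-k SSI/ASW table, plus an `interpretation` string.
#' @export
cluster_support_report <- function(scans) {
  groups <- lapply(scans, function(sc) {
    list(best_k = sc$best_k,
         asw = sc$asw,
         supported = sc$supported,
         per_k = lapply(seq_len(nrow(sc$per_k)), function(i) {
           list(k = sc$per_k$k[i], ssi = sc$per_k$ssi[i], asw = sc$per_k$asw[i])
         }))
  })
  any_supported <- any(vapply(scans, `[[`, logical(1), "supported"))
  list(
    groups = groups,
    interpretation = if (any_supported) {
      "At least one metric group shows supported clustering (ASW >= 0.5)."
    } else {
      paste("No metric group reaches ASW >= 0.5: clusters fall along a",
            "continuum, so continuous axes of participant behaviour are",
            "preferred over discrete groupings.")
    }
  )
}
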