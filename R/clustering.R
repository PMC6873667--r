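#' L1 and L2 distances between feature vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
l1_distance <- function(u, v) {
  if (length(u) != length(v))
    pb_stop("pb_dim_mismatch", "vectors of unequal length")
  sum(abs(u - v))
}

#' @rdname l1_distance
#' @export
l2_distance <- function(u, v) {
  if (length(u) != length(v))
    pb_stop("pb_dim_mismatch", "vectors of unequal length")
  sqrt(sum((u - v)^2))
}

#' k-medoids clustering of feature rows
#'
#' Partitional clustering in which every cluster representative is an
#' actual data row, making the result robust to outliers. The procedure
#' alternates (a) assignment of every row to the nearest medoid by L2
#' distance (ties to the lowest medoid index) and (b) a medoid update that,
#' within each cluster, swaps the medoid with the member minimizing the
#' total within-cluster dissimilarity; it stops when the assignment no
#' longer changes. Initial medoids are drawn at random, and the best of
#' `restarts` runs by total cost is returned, so results are reproducible
#' given `seed`.
#'
#' @param x Numeric feature matrix (rows are clustered).
#' @param C Number of clusters, `1 <= C <= nrow(x)`.
#' @param seed Integer seed for the random initializations.
#' @param max_iter Maximum alternation sweeps per restart (default 100).
#' @param restarts Number of random restarts (default 10).
#' @return An object of class `phasebin_kmedoids`: list with `labels`
#'   (1-based cluster per row), `medoid_indices`, `total_cost` (sum of
#'   distances to assigned medoids), `iterations`, and `cost_trace` (cost
#'   after each sweep of the winning restart).
#' @export
kmedoids <- function(x, C, seed = NULL, max_iter = 100L, restarts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) pb_stop("pb_empty_input", "no rows to cluster")
  C <- as.integer(C)
  if (C < 1L || C > n)
    pb_stop("pb_bad_C", "C must be in [1, %d], got %d", n, C)
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(dist(x))
  best <- NULL
  for (r in seq_len(restarts)) {
    med <- sort(sample.int(n, C))
    lab <- max.col(-D[, med, drop = FALSE], ties.method = "first")
    trace <- numeric(0)
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      for (ci in seq_len(C)) {           # swap step: best member per cluster
        memb <- which(lab == ci)
        if (length(memb) == 0L) next
        within <- colSums(D[memb, memb, drop = FALSE])
        med[ci] <- memb[which.min(within)]
      }
      newlab <- max.col(-D[, med, drop = FALSE], ties.method = "first")
      trace <- c(trace, sum(D[cbind(seq_len(n), med[newlab])]))
      if (all(newlab == lab)) break
      lab <- newlab
    }
    cost <- sum(D[cbind(seq_len(n), med[lab])])
    if (is.null(best) || cost < best$total_cost)
      best <- list(labels = lab, medoid_indices = med, total_cost = cost,
                   iterations = iters, cost_trace = trace)
  }
  class(best) <- "phasebin_kmedoids"
  best
}

#' Estimate the number of species by cluster occupancy
#'
#' Runs k-means for an increasing number of candidate clusters `k` and stops
#' as soon as the data stop supporting that many centers: when the number of
#' non-empty clusters falls below `occupancy * k`, the previous candidate is
#' returned. Initial centers are drawn from a Gaussian fitted to the feature
#' moments (per-column mean and sd), so centers that land away from any
#' dense region can lose all their points — the signal the stopping rule
#' relies on. The non-empty count is averaged over `restarts` seeded Lloyd
#' runs per candidate to stabilize the estimate.
#'
#' @param x Feature matrix (typically phase-1 style features over all
#'   contigs).
#' @param k_min Smallest candidate (default 2).
#' @param step Candidate increment (default 1).
#' @param occupancy Required fraction of non-empty clusters (default 0.8).
#' @param seed Integer seed.
#' @param k_max Hard cap; if the rule never trips, `k_max` is returned with
#'   a warning (default `nrow(x)`).
#' @param restarts k-means runs averaged per candidate (default 10).
#' @return The estimated number of clusters.
#' @export
estimate_num_clusters <- function(x, k_min = 2L, step = 1L, occupancy = 0.8,
                                  seed = NULL, k_max = nrow(x), restarts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= k_min, k_min >= 1L, step >= 1L)
  k_max <- min(k_max, n)
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(x)
  sg <- apply(x, 2L, sd)
  k <- k_min
  repeat {
    ne <- vapply(seq_len(restarts), function(r) {
      centers <- matrix(rnorm(k * ncol(x), mean = rep(mu, each = k),
                              sd = rep(sg, each = k)), nrow = k)
      cl <- tryCatch(
        suppressWarnings(kmeans(x, centers, iter.max = 50L,
                                algorithm = "Lloyd")$cluster),
        error = function(e) rep(1L, n))     # degenerate centers: one cluster
      length(unique(cl))
    }, integer(1L))
    if (mean(ne) < occupancy * k)
      return(max(k - step, k_min))
    if (k >= k_max) {
      warning(sprintf("occupancy rule never tripped; returning cap k = %d", k_max))
      return(k_max)
    }
    k <- k + step
  }
}

#' Cluster centroids in the phase-2 feature space
#'
#' The centroid of each non-empty cluster is the component-wise mean of its
#' member rows; empty clusters are dropped and the surviving clusters are
#' renumbered densely (the mapping is recorded in the `cluster_map`
#' attribute and as rownames).
#'
#' @param labels Integer cluster labels of the (long) rows.
#' @param x Feature rows in the phase-2 space, aligned with `labels`.
#' @return A centroid matrix, one row per non-empty cluster.
#' @export
compute_centroids <- function(labels, x) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  keep <- sort(unique(labels))
  if (length(keep) == 0L)
    pb_stop("pb_empty_input", "no non-empty clusters")
  cent <- t(vapply(keep, function(ci)
    colMeans(x[labels == ci, , drop = FALSE]), numeric(ncol(x))))
  rownames(cent) <- keep
  attr(cent, "cluster_map") <- keep
  cent
}

#' Assign short contigs to the nearest centroid by L1 distance
#'
#' @param x Short-contig rows in the same phase-2 space as `centroids`.
#' @param centroids Centroid matrix from [compute_centroids()].
#' @return Integer labels (row index into `centroids`; ties go to the
#'   lowest index).
#' @export
assign_short_contigs <- function(x, centroids) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(centroids))
    pb_stop("pb_dim_mismatch", "feature dimension differs from centroids")
  vapply(seq_len(nrow(x)), function(i) {
    d <- rowSums(abs(sweep(centroids, 2L, x[i, ], "-")))
    which.min(d)                           # which.min ties -> lowest index
  }, integer(1L))
}
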