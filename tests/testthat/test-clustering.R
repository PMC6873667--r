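test_that("L1 and L2 distances and the norm inequality", {
  expect_equal(l1_distance(c(0, 0), c(1, 2)), 3)
  expect_equal(l2_distance(c(0, 0), c(1, 2)), sqrt(5))
  expect_equal(l1_distance(1:3, 1:3), 0)
  expect_equal(l2_distance(1:3, 1:3), 0)
  expect_error(l1_distance(1:2, 1:3), class = "pb_dim_mismatch")
  set.seed(21)
  for (i in 1:20) {
    u <- rnorm(8); v <- rnorm(8)
    expect_gte(l1_distance(u, v), l2_distance(u, v))
  }
})

test_that("k-medoids solves the well-separated toy for any seed", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  for (s in 1:5) {
    km <- kmedoids(pts, 2, seed = s)
    expect_equal(km$total_cost, 2)
    expect_identical(km$labels[1], km$labels[2])
    expect_identical(km$labels[3], km$labels[4])
    expect_false(km$labels[1] == km$labels[3])
  }
})

test_that("C = 1 returns the 1-medoid (minimum summed distance) point", {
  set.seed(31)
  x <- matrix(rnorm(30), 15, 2)
  km <- kmedoids(x, 1, seed = 1)
  D <- as.matrix(dist(x))
  expect_identical(km$medoid_indices, unname(which.min(colSums(D))))
  expect_equal(km$total_cost, min(colSums(D)))
})

test_that("identical points give zero cost; invalid C errors", {
  x <- matrix(1, 6, 3)
  km <- kmedoids(x, 3, seed = 2)
  expect_equal(km$total_cost, 0)
  expect_error(kmedoids(x, 7, seed = 1), class = "pb_bad_C")
  expect_error(kmedoids(x[0, , drop = FALSE], 1), class = "pb_empty_input")
})

test_that("k-medoids cost trace is non-increasing and runs terminate", {
  set.seed(41)
  for (i in 1:5) {
    x <- matrix(rnorm(120), 40, 3)
    km <- kmedoids(x, 4, seed = i, restarts = 2)
    expect_true(all(diff(km$cost_trace) <= 1e-12))
    expect_lte(km$iterations, 100)
  }
})

test_that("k-medoids is deterministic given a seed", {
  set.seed(51)
  x <- matrix(rnorm(200), 50, 4)
  a <- kmedoids(x, 3, seed = 99)
  b <- kmedoids(x, 3, seed = 99)
  expect_identical(a, b)
})

test_that("k-medoids agrees with PAM on clearly separated clouds", {
  skip_if_not_installed("cluster")
  set.seed(61)
  x <- rbind(matrix(rnorm(60, 0), 30, 2),
             matrix(rnorm(60, 8), 30, 2),
             matrix(rnorm(60, 16), 30, 2))
  km <- kmedoids(x, 3, seed = 1)
  pam <- cluster::pam(x, 3)
  # same partition up to label permutation
  expect_equal(length(unique(paste(km$labels, pam$clustering))), 3L)
})

test_that("cluster-number estimator recovers separated point clouds", {
  set.seed(71)
  x <- rbind(matrix(rnorm(100, 0, 0.2), 50, 2),
             matrix(rnorm(100, 5, 0.2), 50, 2),
             matrix(rnorm(100, c(0, 10), 0.2), 50, 2))
  hits <- sapply(1:10, function(s) estimate_num_clusters(x, seed = s))
  expect_gte(sum(abs(hits - 3) <= 1), 6)   # majority over 10 seeds
})

test_that("estimator boundary behavior: degenerate cloud and occupancy 0", {
  x <- matrix(1, 12, 2)          # fully degenerate single cluster
  expect_equal(estimate_num_clusters(x, k_min = 2, seed = 1), 2)
  set.seed(81)
  y <- matrix(rnorm(24), 12, 2)
  expect_warning(
    got <- estimate_num_clusters(y, occupancy = 0, seed = 1, k_max = 5),
    "cap")
  expect_equal(got, 5)
})

test_that("centroids are member means; empty clusters dropped densely", {
  x <- rbind(c(1, 1), c(3, 3), c(5, 5))
  cent <- compute_centroids(c(1L, 1L, 3L), x)
  expect_equal(unname(cent), rbind(c(2, 2), c(5, 5)), ignore_attr = TRUE)
  expect_identical(attr(cent, "cluster_map"), c(1L, 3L))
})

test_that("short-contig assignment matches a brute-force L1 scan", {
  cent <- rbind(c(0, 0), c(10, 10))
  expect_identical(assign_short_contigs(rbind(c(1, 2)), cent), 1L)
  # equidistant point goes to the lowest index
  expect_identical(assign_short_contigs(rbind(c(5, 5)), cent), 1L)

  set.seed(91)
  cents <- matrix(rnorm(40), 8, 5)
  x <- matrix(rnorm(500), 100, 5)
  expect_identical(assign_short_contigs(x, cents),
                   unname(brute_l1_assign(x, cents)))
  expect_error(assign_short_contigs(matrix(1, 1, 3), cent),
               class = "pb_dim_mismatch")
})
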