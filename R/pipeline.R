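#' Phase-2 feature space
#'
#' Coverage profile columns followed by the per-contig *relative* canonical
#' k-mer frequencies (pseudo-counted counts scaled by their row total). No
#' z-scoring and no cross-contig column normalization is applied — the
#' phase-1 standardization needs a length-stable count model that short
#' contigs cannot support — but scaling by the row total is required so
#' that L1 distances compare composition shape rather than contig length.
#'
#' @param Q Normalized coverage profile for all contigs.
#' @param Zp Pseudo-counted canonical count matrix for all contigs.
#' @return The phase-2 feature matrix `[Q | Zp / rowSums(Zp)]`.
#' @export
phase2_features <- function(Q, Zp) {
  stopifnot(nrow(Q) == nrow(Zp))
  cbind(Q, Zp / rowSums(Zp))
}

#' Bin metagenomic contigs in two phases
#'
#' Full pipeline: canonical k-mer counting, pseudo-counting, coverage
#' normalization, species-count estimation (unless `clusters` is given),
#' long/short split, self-standardized composition and k-medoids clustering
#' of the long contigs, then L1 attachment of the short contigs to the
#' phase-1 bins.
#'
#' @param contigs A named `DNAStringSet` (see [read_contigs()]).
#' @param coverage Coverage matrix aligned with `contigs` (see
#'   [read_coverage()]).
#' @param k Even k-mer size in `[2, 8]` (default 4).
#' @param clusters Number of bins `C`; `NULL` (default) estimates it with
#'   [estimate_num_clusters()].
#' @param length_threshold Long/short threshold in bp (default 2000).
#' @param split_mode `"fixed"` (default) or `"quantile"` (shortest
#'   `short_fraction` labelled short).
#' @param short_fraction Short fraction for `quantile` mode (default 0.20).
#' @param seed Integer seed controlling every random step (default 1).
#' @param two_phase If `FALSE`, cluster all contigs at once on phase-1
#'   features (the baseline the two-phase design is compared against).
#' @param strict If `TRUE`, use the literal-formula variants throughout:
#'   single-strand occurrence probabilities, signed column sums for `H`,
#'   and the unsmoothed nucleotide model.
#' @param max_iter,restarts Passed to [kmedoids()].
#' @param occupancy Occupancy fraction for the cluster-number estimator.
#' @param verbose Log each stage to stderr (default `FALSE`).
#' @return A [binning()] object covering all contigs; its `report` records
#'   every parameter, the number of clusters used and how it was obtained,
#'   the phase sizes, and the phase-1 clustering cost.
#' @export
bin_contigs <- function(contigs, coverage, k = 4L, clusters = NULL,
                        length_threshold = 2000L,
                        split_mode = c("fixed", "quantile"),
                        short_fraction = 0.20, seed = 1L, two_phase = TRUE,
                        strict = FALSE, max_iter = 100L, restarts = 10L,
                        occupancy = 0.8, verbose = FALSE) {
  split_mode <- match.arg(split_mode)
  contigs <- validate_contigs(contigs)
  if (is.null(rownames(coverage)))
    rownames(coverage) <- names(contigs)
  stopifnot(nrow(coverage) == length(contigs),
            identical(rownames(coverage), names(contigs)))
  n <- length(contigs)
  p_mode <- if (strict) "strict" else "pair"
  h_mode <- if (strict) "strict" else "abs"
  smooth <- !strict

  pb_log(verbose, "counting canonical %d-mers for %d contigs", k, n)
  Z <- count_canonical_kmers(contigs, k)
  pc <- add_pseudocounts(Z, coverage)
  Q <- normalize_coverage(pc$Y)

  c_source <- "user-supplied"
  if (is.null(clusters)) {
    pb_log(verbose, "estimating number of species")
    Xt_all <- standardize_composition(pc$Z, contigs, p_mode, smooth)
    F_all <- assemble_features(Q, normalize_columns(Xt_all, h_mode))
    clusters <- estimate_num_clusters(F_all, occupancy = occupancy,
                                      seed = seed)
    c_source <- "estimated"
  }
  pb_log(verbose, "using C = %d clusters (%s)", clusters, c_source)

  if (two_phase) {
    sp <- split_by_length(contigs, length_threshold, split_mode, short_fraction)
  } else {
    sp <- list(long = seq_len(n), short = integer(0),
               threshold = NA_integer_)
  }
  pb_log(verbose, "phase 1: %d long contigs; phase 2: %d short contigs",
         length(sp$long), length(sp$short))
  if (clusters > length(sp$long))
    pb_stop("pb_bad_C", "C = %d exceeds the %d long contigs", clusters,
            length(sp$long))

  Zp_long <- pc$Z[sp$long, , drop = FALSE]
  attr(Zp_long, "k") <- attr(pc$Z, "k")
  Xt <- standardize_composition(Zp_long, contigs[sp$long], p_mode, smooth)
  F1 <- assemble_features(Q[sp$long, , drop = FALSE],
                          normalize_columns(Xt, h_mode))
  km <- kmedoids(F1, clusters, seed = seed, max_iter = max_iter,
                 restarts = restarts)
  pb_log(verbose, "phase 1 cost %.4f after %d iterations", km$total_cost,
         km$iterations)

  labels <- integer(n)
  labels[sp$long] <- km$labels
  if (length(sp$short)) {
    P2 <- phase2_features(Q, pc$Z)
    cent <- compute_centroids(km$labels, P2[sp$long, , drop = FALSE])
    idx <- assign_short_contigs(P2[sp$short, , drop = FALSE], cent)
    labels[sp$short] <- attr(cent, "cluster_map")[idx]
  }
  # drop empty bins (possible when phase 1 leaves a cluster unused)
  used <- sort(unique(labels))
  labels <- match(labels, used)

  report <- list(k = k, clusters = length(used), clusters_requested = clusters,
                 clusters_source = c_source, length_threshold = sp$threshold,
                 split_mode = split_mode, short_fraction = short_fraction,
                 seed = seed, strict = strict, two_phase = two_phase,
                 n_long = length(sp$long), n_short = length(sp$short),
                 phase1_cost = km$total_cost,
                 phase1_iterations = km$iterations,
                 occupancy = occupancy, restarts = restarts)
  binning(names(contigs), labels, num_bins = length(used), report = report)
}
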