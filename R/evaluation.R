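#' Contingency matrix of a predicted binning against a ground truth
#'
#' Entry `A[i, j]` counts the contigs from species `j` assigned to cluster
#' `i`. Contigs without a truth label are excluded and their number is
#' recorded in the `n_excluded` attribute. Rows and columns are ordered by
#' sorted cluster / species id, so the matrix is deterministic.
#'
#' @param pred A [binning()] object (or anything with `contig_ids` and
#'   `bin_labels`).
#' @param truth Named vector mapping contig id to species label (see
#'   [read_truth()]).
#' @return An integer matrix of class `phasebin_contingency` with cluster
#'   ids as rownames and species as colnames.
#' @export
binning_contingency <- function(pred, truth) {
  ids <- pred$contig_ids
  keep <- ids %in% names(truth)
  if (!any(keep))
    pb_stop("pb_empty_input", "no predicted contig has a truth label")
  A <- table(cluster = pred$bin_labels[keep],
             species = truth[ids[keep]])
  A <- unclass(A)[order(rownames(unclass(A))), order(colnames(unclass(A))),
                  drop = FALSE]
  storage.mode(A) <- "integer"
  structure(A, n_excluded = sum(!keep),
            class = c("phasebin_contingency", class(A)))
}

#' Binning precision and recall
#'
#' Precision sums, over clusters, the count of each cluster's dominant
#' species, divided by the total number of contigs: it measures cluster
#' purity. Recall sums, over species, the count of each species' dominant
#' cluster, again over the total: it measures species completeness.
#'
#' @param A Contingency matrix (clusters x species).
#' @return A value in `[0, 1]`.
#' @export
binning_precision <- function(A) {
  if (length(A) == 0L || sum(A) == 0L)
    pb_stop("pb_empty_input", "empty contingency matrix")
  sum(apply(A, 1L, max)) / sum(A)
}

#' @rdname binning_precision
#' @export
binning_recall <- function(A) {
  if (length(A) == 0L || sum(A) == 0L)
    pb_stop("pb_empty_input", "empty contingency matrix")
  sum(apply(A, 2L, max)) / sum(A)
}

#' Per-bin precision and recall
#'
#' For each non-empty bin `i` with majority species `j*` (ties to the
#' lowest species index): precision is the majority count over the bin
#' size, recall is the majority count over the species-`j*` column total.
#'
#' @param A Contingency matrix (clusters x species).
#' @return A data frame with columns `bin`, `majority_species`, `size`,
#'   `precision`, `recall`.
#' @export
per_bin_metrics <- function(A) {
  sizes <- rowSums(A)
  keep <- which(sizes > 0)
  jstar <- apply(A[keep, , drop = FALSE], 1L, which.max)  # ties -> lowest
  data.frame(
    bin = rownames(A)[keep] %||% as.character(keep),
    majority_species = colnames(A)[jstar] %||% as.character(jstar),
    size = as.integer(sizes[keep]),
    precision = A[cbind(keep, jstar)] / sizes[keep],
    recall = A[cbind(keep, jstar)] / colSums(A)[jstar],
    stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter bins by quality and histogram the survivors
#'
#' Removes bins whose chosen metric falls below `threshold` and buckets the
#' complementary metric of the survivors into ranges (by default
#' `<80%`, `80-90%`, `90-95%`, `>=95%`), reproducing the usual bin-quality
#' summary.
#'
#' @param metrics Data frame from [per_bin_metrics()].
#' @param metric Which metric to filter on: `"precision"` (default) or
#'   `"recall"`.
#' @param threshold Filtering threshold (default 0.8).
#' @param breaks Bucket edges for the complementary metric.
#' @return A list with `survivors` (filtered data frame) and `histogram`
#'   (named counts of the complementary metric, highest bucket first).
#' @export
filter_bins <- function(metrics, metric = c("precision", "recall"),
                        threshold = 0.8, breaks = c(0, 0.8, 0.9, 0.95, 1)) {
  metric <- match.arg(metric)
  other <- if (metric == "precision") "recall" else "precision"
  surv <- metrics[metrics[[metric]] >= threshold, , drop = FALSE]
  # right = FALSE + include.lowest closes the top bucket, so a metric of
  # exactly 1 lands in the highest range
  cuts <- cut(surv[[other]], breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  hist <- rev(table(cuts))
  list(survivors = surv, histogram = hist)
}

#' Evaluate a binning against a ground truth
#'
#' @param pred A [binning()] object.
#' @param truth Named contig-to-species vector.
#' @return A list with `precision`, `recall`, the `contingency` matrix,
#'   `per_bin` metrics and `n_excluded` (contigs without a truth label).
#' @export
evaluate_binning <- function(pred, truth) {
  A <- binning_contingency(pred, truth)
  list(precision = binning_precision(A),
       recall = binning_recall(A),
       contingency = A,
       per_bin = per_bin_metrics(A),
       n_excluded = attr(A, "n_excluded"))
}
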