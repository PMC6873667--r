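#' Add pseudo-counts to the composition and coverage matrices
#'
#' Composition counts get +1 (small relative to k-mer tallies) and coverage
#' gets +0.01 (negligible in depth units), so that downstream normalization
#' and standardization never meet exact zeros.
#'
#' @param Z Integer matrix of canonical k-mer counts (contigs x classes).
#' @param Y Numeric coverage matrix (contigs x samples).
#' @return A list with elements `Z` and `Y`; the inputs are not modified.
#' @export
add_pseudocounts <- function(Z, Y) {
  stopifnot(nrow(Z) == nrow(Y))
  Zp <- Z + 1L
  attr(Zp, "k") <- attr(Z, "k")
  list(Z = Zp, Y = Y + 0.01)
}

#' Two-step normalization of the coverage matrix
#'
#' First every sample column is divided by its column total (normalization
#' across contigs, removing per-sample sequencing depth), then every row is
#' divided by its row total (normalization across samples within a contig).
#' Each row of the result sums to 1, so the profile carries the *shape* of a
#' contig's abundance across samples, not its magnitude.
#'
#' @param Yp Pseudo-counted coverage matrix; all entries must be positive.
#' @return The normalized profile matrix `Q`, same dimensions as `Yp`.
#' @export
normalize_coverage <- function(Yp) {
  if (any(Yp <= 0))
    pb_stop("pb_nonpositive_coverage",
            "normalize_coverage expects strictly positive (pseudo-counted) values")
  cs <- colSums(Yp)
  if (any(cs == 0)) pb_stop("pb_zero_column", "zero column sum in coverage")
  Ypp <- sweep(Yp, 2L, cs, "/")
  Q <- Ypp / rowSums(Ypp)
  Q
}

#' Per-contig nucleotide model
#'
#' Estimates the probability of each base from the contig itself,
#' `p_c(a) = n_c(a) / L`, where `N` bases are excluded from both numerator
#' and denominator. With `smooth = TRUE` (default) add-one smoothing,
#' `p_c(a) = (n_c(a) + 1) / (L + 4)`, guarantees strictly positive
#' probabilities so the binomial variance below never vanishes.
#'
#' @param contigs A `DNAStringSet` (one row of output per contig).
#' @param smooth Apply add-one smoothing (default `TRUE`).
#' @return A numeric matrix, contigs by `A,C,G,T`, rows summing to 1.
#' @export
nucleotide_model <- function(contigs, smooth = TRUE) {
  af <- Biostrings::alphabetFrequency(contigs)[, c("A", "C", "G", "T"),
                                               drop = FALSE]
  L <- rowSums(af)
  if (any(L == 0))
    pb_stop("pb_no_informative_bases", "contig %s has no informative bases",
            names(contigs)[which(L == 0)[1L]])
  p <- if (smooth) (af + 1) / (L + 4) else af / L
  rownames(p) <- names(contigs)
  p
}

#' Occurrence probability of a k-mer under a nucleotide model
#'
#' Under the i.i.d. model the probability that word `w` starts at a given
#' position is the product of its letter probabilities. Because counts pool
#' a word with its reverse complement, the default `pair` mode returns
#' `prod(p[w]) + prod(p[rc(w)])` for non-palindromic `w` (a palindrome is
#' its own reverse complement and is returned unpaired); `strict` mode
#' returns the single-strand product only.
#'
#' @param p Probability 4-vector named `A,C,G,T` (one nucleotide model row).
#' @param w k-mer string over A/C/G/T.
#' @param mode `"pair"` (default) or `"strict"`.
#' @return A probability.
#' @export
kmer_probability <- function(p, w, mode = c("pair", "strict")) {
  mode <- match.arg(mode)
  letters_w <- strsplit(w, "")[[1L]]
  stopifnot(all(letters_w %in% c("A", "C", "G", "T")))
  pw <- prod(p[letters_w])
  if (mode == "strict") return(unname(pw))
  rc <- revcomp(w)
  if (rc == w) unname(pw) else unname(pw + prod(p[strsplit(rc, "")[[1L]]]))
}

# vectorized occurrence probabilities: contigs x canonical classes.
# log-space product via the letter composition of each word.
kmer_class_probabilities <- function(p, k, mode = c("pair", "strict")) {
  mode <- match.arg(mode)
  ck <- canonical_kmers(k)
  comp <- vapply(c("A", "C", "G", "T"), function(a)
    vapply(strsplit(ck$kmers, ""), function(x) sum(x == a), integer(1L)),
    integer(length(ck$kmers)))
  if (any(p == 0)) {
    # avoid log(0): compute directly (only reachable with smooth = FALSE)
    P <- t(apply(p, 1L, function(pr) apply(comp, 1L, function(cc) prod(pr^cc))))
  } else {
    P <- exp(log(p) %*% t(comp))
  }
  colnames(P) <- ck$kmers
  Pc <- matrix(0, nrow(P), length(ck$classes),
               dimnames = list(rownames(p), ck$classes))
  for (j in seq_along(ck$kmers)) {
    w <- ck$kmers[j]
    if (ck$rc[j] == w) {                     # palindrome: single strand
      Pc[, w] <- P[, w]
    } else if (mode == "pair") {             # w and rc(w) each add once
      Pc[, ck$class_of[j]] <- Pc[, ck$class_of[j]] + P[, w]
    } else if (w == ck$class_of[j]) {        # strict: representative only
      Pc[, w] <- P[, w]
    }
  }
  Pc
}

#' Self-standardize canonical k-mer counts as binomial z-scores
#'
#' Treats each count as a binomial draw over the contig's positions: with
#' occurrence probability `P_cw` estimated from the contig's own nucleotide
#' composition, `mu = P_cw * L` and `sigma^2 = P_cw * (1 - P_cw) * L`, and
#' the standardized statistic is `(X - mu) / sigma`. This removes both the
#' composition bias (common words score high everywhere) and the length
#' bias (long contigs accumulate larger raw counts) of the raw tallies.
#'
#' @param Zp Pseudo-counted canonical count matrix from
#'   [count_canonical_kmers()] + [add_pseudocounts()].
#' @param contigs The matching `DNAStringSet` (row order must agree).
#' @param mode `"pair"` (default) doubles the occurrence probability for
#'   non-palindromic classes, matching the fact that counts pool both
#'   strands and centering the statistic; `"strict"` uses the single-strand
#'   product as literally printed, which leaves a systematic positive shift.
#' @param smooth Use the smoothed nucleotide model (default `TRUE`);
#'   `FALSE` can produce zero variance, which is an error.
#' @return The z-score matrix, same shape as `Zp`, finite everywhere.
#' @export
standardize_composition <- function(Zp, contigs, mode = c("pair", "strict"),
                                    smooth = TRUE) {
  mode <- match.arg(mode)
  stopifnot(nrow(Zp) == length(contigs))
  k <- attr(Zp, "k")
  if (is.null(k)) k <- nchar(colnames(Zp)[1L])
  if (any(Biostrings::width(contigs) < k))
    pb_stop("pb_contig_too_short", "all contigs must be at least k = %d bp", k)
  p <- nucleotide_model(contigs, smooth = smooth)
  P <- kmer_class_probabilities(p, k, mode)
  L <- Biostrings::width(contigs)
  mu <- P * L
  sig2 <- P * (1 - P) * L
  if (any(sig2 == 0)) {
    idx <- which(sig2 == 0, arr.ind = TRUE)[1L, ]
    pb_stop("pb_zero_variance",
            "zero variance for contig %s, k-mer class %s (use smooth = TRUE)",
            rownames(Zp)[idx[1L]], colnames(P)[idx[2L]])
  }
  Xt <- (Zp - mu) / sqrt(sig2)
  if (!all(is.finite(Xt)))
    pb_stop("pb_nonfinite", "non-finite standardized composition")
  Xt
}

#' Column-wise normalization of the standardized composition
#'
#' Divides each column (k-mer class) by a column total so that classes are
#' comparable across contigs. The default `abs` mode divides by the sum of
#' absolute values, preserving signs while giving each column unit absolute
#' mass; `strict` mode divides by the signed sum, which can be near zero for
#' well-centered columns and blow the scale up. Columns with a zero
#' denominator are left as zeros with a warning.
#'
#' @param Xt Standardized composition matrix.
#' @param mode `"abs"` (default) or `"strict"`.
#' @return The normalized matrix `H`.
#' @export
normalize_columns <- function(Xt, mode = c("abs", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(Xt)))
  den <- if (mode == "abs") colSums(abs(Xt)) else colSums(Xt)
  zero <- den == 0
  if (any(zero)) {
    warning(sprintf("%d column(s) with zero denominator set to zeros", sum(zero)))
    den[zero] <- 1
  }
  H <- sweep(Xt, 2L, den, "/")
  H[, zero] <- 0
  H
}

#' Assemble the clustering feature matrix
#'
#' Horizontal concatenation `F = [Q H]` of the coverage profile and the
#' normalized composition profile, coverage columns first.
#'
#' @param Q Normalized coverage profile (contigs x samples).
#' @param H Normalized standardized composition (contigs x classes).
#' @return A numeric matrix with attribute `column_roles` giving the number
#'   of coverage and composition columns.
#' @export
assemble_features <- function(Q, H) {
  if (nrow(Q) != nrow(H))
    pb_stop("pb_row_mismatch", "Q and H must have the same number of rows")
  if (!all(is.finite(Q)) || !all(is.finite(H)))
    pb_stop("pb_nonfinite", "feature inputs must be finite")
  FF <- cbind(Q, H)
  attr(FF, "column_roles") <- c(coverage = ncol(Q), composition = ncol(H))
  FF
}

#' Split contigs into long and short subsets
#'
#' Long contigs (length at least the threshold) carry a reliable k-mer
#' signature and are clustered in phase 1; short contigs are attached in
#' phase 2. `fixed` mode uses `threshold_bp` directly; `quantile` mode
#' labels the shortest `short_fraction` of contigs short (ties broken by
#' input order).
#'
#' @param contigs A `DNAStringSet`.
#' @param threshold_bp Length threshold in bp (default 2000, `fixed` mode).
#' @param mode `"fixed"` (default) or `"quantile"`.
#' @param short_fraction Target short fraction for `quantile` mode
#'   (default 0.20).
#' @return A list with integer index vectors `long` and `short` and the
#'   effective `threshold` used.
#' @export
split_by_length <- function(contigs, threshold_bp = 2000L,
                            mode = c("fixed", "quantile"),
                            short_fraction = 0.20) {
  mode <- match.arg(mode)
  lens <- Biostrings::width(contigs)
  n <- length(lens)
  if (mode == "fixed") {
    stopifnot(threshold_bp >= 1L)
    long <- which(lens >= threshold_bp)
    short <- which(lens < threshold_bp)
    thr <- threshold_bp
  } else {
    stopifnot(short_fraction >= 0, short_fraction < 1)
    n_short <- floor(short_fraction * n)
    ord <- order(lens)                      # stable: ties keep input order
    short <- sort(ord[seq_len(n_short)])
    long <- setdiff(seq_len(n), short)
    thr <- if (n_short > 0L) lens[ord[n_short + 1L]] else min(lens)
  }
  if (length(long) == 0L)
    pb_stop("pb_no_long_contigs", "no long contigs for phase 1")
  list(long = long, short = short, threshold = thr)
}
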