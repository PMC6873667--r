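# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: window enumeration with substring(), base-R
# arithmetic, exhaustive search.

# reverse complement by character table, no Biostrings
rc_chr <- function(w) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
}

# canonical k-mer counts by enumerating every window
brute_canonical_counts <- function(seq, k) {
  classes <- sort(unique(vapply(
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
          collapse = ""),
    function(w) min(w, rc_chr(w)), "")))
  counts <- setNames(integer(length(classes)), classes)
  L <- nchar(seq)
  if (L >= k) {
    wins <- substring(seq, 1:(L - k + 1), k:L)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    for (w in wins) {
      rep <- min(w, rc_chr(w))
      counts[rep] <- counts[rep] + 1L
    }
  }
  counts
}

# random DNA string, optionally with Ns
random_dna <- function(L, p = rep(0.25, 4), n_prob = 0) {
  letters <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p)
  if (n_prob > 0) {
    idx <- which(runif(L) < n_prob)
    letters[idx] <- "N"
  }
  paste(letters, collapse = "")
}

brute_precision <- function(A) {
  tot <- 0
  for (i in seq_len(nrow(A))) tot <- tot + max(A[i, ])
  tot / sum(A)
}

brute_recall <- function(A) {
  tot <- 0
  for (j in seq_len(ncol(A))) tot <- tot + max(A[, j])
  tot / sum(A)
}

# exhaustive k-medoids optimum: minimize over all C-subsets of rows the sum
# of each point's distance to its nearest chosen medoid
brute_kmedoids_cost <- function(x, C) {
  D <- as.matrix(dist(x))
  subsets <- utils::combn(nrow(x), C)
  best <- Inf
  for (s in seq_len(ncol(subsets))) {
    med <- subsets[, s]
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# brute-force nearest centroid by L1
brute_l1_assign <- function(x, cent) {
  apply(x, 1, function(row) {
    d <- apply(cent, 1, function(ce) sum(abs(ce - row)))
    which.min(d)
  })
}
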